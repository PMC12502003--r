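#' Synthetic participant controller
#'
#' A minimal generative model of human closed-loop control producing the
#' three phenomena the task measures: sensorimotor latency, an instability
#' threshold, and attentional drift. The control law is delayed proportional
#' feedback on the stimulus position,
#' `u[n] = -gain * x[n - d] + motor noise`, with `d` the feedback delay
#' rounded to whole samples at the task rate. Attentional lapses arrive as a
#' Poisson process (`lapse_rate_hz`) with exponentially distributed
#' durations (`lapse_duration_s` mean) during which the control output is
#' frozen at its last value. For one delay period after task start and after
#' every crash reset the controller outputs 0 (the participant re-centers;
#' no percept of the new stimulus position is available yet). The control
#' output is clamped to `[-1, 1]`.
#'
#' `disturbance_sd` is plant-side noise (device/accelerometer jitter added
#' to the stimulus position each step). It excites the loop without entering
#' the recorded user series, so a noise-free controller
#' (`motor_noise_sd = 0`, no lapses) still produces a user series that is an
#' exactly delayed, scaled mirror of the stimulus -- the ground truth used
#' to validate the latency metric. With every noise source at 0 the
#' simulation is fully deterministic.
#'
#' This is not a claim about human motor control; it is the synthetic-data
#' engine that makes the downstream pipeline testable.
#'
#' @param feedback_delay_s Sensorimotor latency in seconds (quantized to
#'   whole samples at the task rate).
#' @param gain Proportional correction strength. Values slightly above 1
#'   give mean-reverting control; at exactly 1 a constant offset is neither
#'   corrected nor amplified; 0 disables feedback entirely (open loop).
#' @param motor_noise_sd SD of Gaussian noise added to `u` each step
#'   (normalized units).
#' @param lapse_rate_hz Poisson rate of attentional lapses (1/s).
#' @param lapse_duration_s Mean lapse duration (seconds).
#' @param disturbance_sd SD of plant-side position jitter per step
#'   (normalized units).
#' @param seed Optional integer seed carried with the parameters and used as
#'   the default by the run functions.
#' @return A `cpcst_controller` list.
#' @seealso [run_continuous()], [run_calibration()], [simulate_cohort()]
#' @export
controller_params <- function(feedback_delay_s = 0.2,
                              gain = 1.1,
                              motor_noise_sd = 0.02,
                              lapse_rate_hz = 0.02,
                              lapse_duration_s = 0.4,
                              disturbance_sd = 0.005,
                              seed = NULL) {
  stopifnot(
    is.finite(feedback_delay_s), feedback_delay_s >= 0,
    is.finite(gain), gain >= 0,
    is.finite(motor_noise_sd), motor_noise_sd >= 0,
    is.finite(lapse_rate_hz), lapse_rate_hz >= 0,
    is.finite(lapse_duration_s), lapse_duration_s >= 0,
    is.finite(disturbance_sd), disturbance_sd >= 0
  )
  structure(list(feedback_delay_s = feedback_delay_s, gain = gain,
                 motor_noise_sd = motor_noise_sd,
                 lapse_rate_hz = lapse_rate_hz,
                 lapse_duration_s = lapse_duration_s,
                 disturbance_sd = disturbance_sd,
                 seed = seed),
            class = "cpcst_controller")
}

delay_samples <- function(controller, config) {
  as.integer(round(controller$feedback_delay_s * config$sampling_rate_hz))
}

#' Control signal for the current sample
#'
#' Reference (vectorized-history) form of the controller used by the
#' simulation engine: given the stimulus history so far, returns the control
#' input for the latest sample, `u = -gain * x[n - d] + noise` (frozen
#' during an active lapse; 0 while the delayed percept is unavailable).
#' The deterministic part is what the compiled engine applies at every step;
#' this function exists for single-step use and testing.
#'
#' @param history Numeric vector of stimulus positions up to and including
#'   the current sample, or a `cpcst_trace`.
#' @param params A [controller_params()].
#' @param config A [task_config()].
#' @param lapsing If `TRUE`, the controller is in an attentional lapse and
#'   `u_prev` is returned unchanged.
#' @param u_prev Previous control output (used during a lapse).
#' @return The control input `u`, clamped to `[-1, 1]`.
#' @export
#' @examples
#' control_signal(c(0.1, 0.2, 0.3), controller_params(feedback_delay_s = 0,
#'   gain = 1, motor_noise_sd = 0))  # -0.3
control_signal <- function(history, params, config = task_config(),
                           lapsing = FALSE, u_prev = 0) {
  if (inherits(history, "cpcst_trace")) history <- history$stim_x
  if (!is.numeric(history) || length(history) < 1L)
    stop("history must contain at least one stimulus sample")
  if (lapsing) return(max(-1, min(1, u_prev)))
  d <- delay_samples(params, config)
  n <- length(history)
  if (n - d < 1L) return(0)
  s <- if (config$control_sign == "plus") 1 else -1
  u <- -params$gain * history[n - d]
  if (params$motor_noise_sd > 0) u <- u + rnorm(1, 0, params$motor_noise_sd)
  max(-1, min(1, s * u))
}
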