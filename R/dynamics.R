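#' Plant state of the closed-loop task
#'
#' The stimulus position `x` (normalized units, screen edges at +/- 1), the
#' current gain `lambda_val` (1/s) and the elapsed time `t` (seconds).
#'
#' @param x Stimulus position in `[-1, 1]`.
#' @param lambda_val Nonnegative gain (1/s).
#' @param t Elapsed seconds.
#' @return A `cpcst_state` list.
#' @export
plant_state <- function(x = 0, lambda_val = 1, t = 0) {
  stopifnot(is.finite(x), is.finite(lambda_val), lambda_val >= 0, is.finite(t))
  structure(list(x = x, lambda_val = lambda_val, t = t), class = "cpcst_state")
}

#' Advance the unstable plant by one sample
#'
#' Forward-Euler step of the first-order unstable plant at the task rate:
#' `x' = x + dt * lambda * (x + u)` with `dt = 1 / sampling_rate_hz` (or
#' `lambda * (x - u)` under the `"minus"` sign convention). Lambda is left
#' unchanged; the position is clamped to `[-1, 1]`.
#'
#' The origin with `u = 0` is a fixed point, and a control input that exactly
#' cancels the position (`u = -x` under `"plus"`) freezes the stimulus.
#'
#' @param state A [plant_state()].
#' @param u User/cursor position in `[-1, 1]` (the control input).
#' @param config A [task_config()].
#' @return The updated `cpcst_state`.
#' @export
#' @examples
#' s <- plant_state(x = 0.01, lambda_val = 3)
#' cst_step(s, u = 0, task_config())$x  # open-loop growth by (1 + lambda/30)
cst_step <- function(state, u, config = task_config()) {
  stopifnot(inherits(state, "cpcst_state"))
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) ||
      !is.finite(state$x) || !is.finite(state$lambda_val))
    stop("cst_step requires finite state and control input")
  dt <- 1 / config$sampling_rate_hz
  s <- if (config$control_sign == "plus") 1 else -1
  x_new <- state$x + dt * state$lambda_val * (state$x + s * u)
  x_new <- max(-1, min(1, x_new))
  plant_state(x = x_new, lambda_val = state$lambda_val, t = state$t + dt)
}

#' Crash test for a plant state
#'
#' A crash is the stimulus reaching the boundary at `crash_fraction` of the
#' half-screen extent (80% by default, i.e. +/- 22.28 DVA); the boundary is
#' inclusive.
#'
#' @inheritParams cst_step
#' @return `TRUE` iff `|x| >= crash_fraction`.
#' @export
detect_crash <- function(state, config = task_config()) {
  stopifnot(inherits(state, "cpcst_state"), is.finite(state$x))
  abs(state$x) >= config$crash_fraction
}

## internal: assemble the engine output into a trace data frame
build_trace <- function(eng, participant_id, phase, config) {
  n <- length(eng$stim_x)
  structure(
    data.frame(participant_id = participant_id,
               phase = phase,
               sample_index = seq_len(n) - 1L,
               t_sec = (seq_len(n) - 1L) / config$sampling_rate_hz,
               stim_x = eng$stim_x,
               user_x = eng$user_x,
               lambda_val = eng$lambda_val,
               crash_flag = as.integer(eng$crash_flag),
               stringsAsFactors = FALSE),
    class = c("cpcst_trace", "data.frame"))
}

assert_trace <- function(trace) {
  need <- c("participant_id", "phase", "sample_index", "t_sec",
            "stim_x", "user_x", "lambda_val", "crash_flag")
  if (!is.data.frame(trace) || !all(need %in% names(trace)))
    stop("not a cpCST trace: expected columns ", paste(need, collapse = ", "))
  invisible(trace)
}

#' Simulate the continuous performance phase
#'
#' Runs the closed-loop plant for `continuous_duration_s` at the fixed
#' difficulty `lambda = mst_fraction * mst` (30% of the participant's motor
#' stability threshold by default), driven by a synthetic controller. On a
#' crash the stimulus resets to center and the simulation continues with
#' lambda unchanged; every sample is recorded at the task rate.
#'
#' @param controller A [controller_params()] object.
#' @param mst The participant's motor stability threshold (1/s), positive.
#' @param config A [task_config()].
#' @param seed Integer seed; the run is fully reproducible under a fixed
#'   seed. Defaults to the controller's own seed.
#' @param participant_id Identifier stored in the trace.
#' @return A `cpcst_trace` data frame with columns `participant_id, phase,
#'   sample_index, t_sec, stim_x, user_x, lambda_val, crash_flag`, of length
#'   `round(continuous_duration_s * sampling_rate_hz)`.
#' @export
#' @examples
#' tr <- run_continuous(controller_params(seed = 1), mst = 4, task_config(
#'   continuous_duration_s = 10))
#' nrow(tr)  # 300 samples at 30 Hz
run_continuous <- function(controller, mst, config = task_config(),
                           seed = controller$seed, participant_id = "p1") {
  stopifnot(inherits(controller, "cpcst_controller"))
  if (!is.numeric(mst) || length(mst) != 1L || !is.finite(mst) || mst <= 0)
    stop("mst must be a positive number")
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$continuous_duration_s * config$sampling_rate_hz)
  d <- delay_samples(controller, config)
  s <- if (config$control_sign == "plus") 1 else -1
  eng <- cst_engine_cpp(mode = 0L, n_max = as.integer(n),
                        dt = 1 / config$sampling_rate_hz,
                        lambda0 = config$mst_fraction * mst,
                        ramp_rate = 0, crash_fraction = config$crash_fraction,
                        reset_fraction = config$reset_fraction,
                        n_crashes_target = 0L, control_sign = s,
                        gain = controller$gain, delay_samples = d,
                        motor_noise_sd = controller$motor_noise_sd,
                        lapse_rate_hz = controller$lapse_rate_hz,
                        lapse_duration_s = controller$lapse_duration_s,
                        disturbance_sd = controller$disturbance_sd,
                        x0 = config$x_start_offset)
  build_trace(eng, participant_id, "continuous", config)
}

#' Write or read a trace table in the long CSV dialect
#'
#' Header `participant_id,phase,sample_index,t_sec,stim_x,user_x,lambda_val,
#' crash_flag`; positions in normalized units; `crash_flag` in `{0, 1}`.
#' A file may hold several participants and phases.
#'
#' @param trace A `cpcst_trace` (or any data frame with the trace columns).
#' @param path File path.
#' @return `read_trace()` returns a `cpcst_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  assert_trace(tr)
  class(tr) <- c("cpcst_trace", "data.frame")
  tr
}
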