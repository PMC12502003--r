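#' Default sampler of controller parameters for a synthetic cohort
#'
#' Returns a function `f(n)` drawing `n` controller parameter sets using the
#' current RNG state. The default ranges give feedback delays spanning young
#' to older adults (0.12-0.35 s), mildly over-corrective gains (mean
#' reversion), light motor noise, and a lapse process producing roughly one
#' lapse a minute -- a cohort in which most continuous runs have no crash
#' and a few have one or two, so every downstream rule has work to do.
#'
#' @param feedback_delay_s,gain,motor_noise_sd,lapse_rate_hz,lapse_duration_s
#'   Length-2 numeric ranges sampled uniformly.
#' @param disturbance_sd Scalar plant jitter used for every participant.
#' @return A function `f(n)` returning a data frame of parameters.
#' @export
default_param_sampler <- function(feedback_delay_s = c(0.12, 0.35),
                                  gain = c(1.05, 1.30),
                                  motor_noise_sd = c(0.01, 0.04),
                                  lapse_rate_hz = c(0, 0.05),
                                  lapse_duration_s = c(0.3, 0.8),
                                  disturbance_sd = 0.005) {
  force(feedback_delay_s); force(gain); force(motor_noise_sd)
  force(lapse_rate_hz); force(lapse_duration_s); force(disturbance_sd)
  function(n) {
    data.frame(
      feedback_delay_s = runif(n, feedback_delay_s[1], feedback_delay_s[2]),
      gain = runif(n, gain[1], gain[2]),
      motor_noise_sd = runif(n, motor_noise_sd[1], motor_noise_sd[2]),
      lapse_rate_hz = runif(n, lapse_rate_hz[1], lapse_rate_hz[2]),
      lapse_duration_s = runif(n, lapse_duration_s[1], lapse_duration_s[2]),
      disturbance_sd = disturbance_sd)
  }
}

#' Simulate a cohort of synthetic participants
#'
#' Per participant: draw controller parameters from `param_sampler`, run the
#' calibration phase to estimate the MST, then (optionally) run the
#' continuous phase at `mst_fraction * MST`. One master seed spawns
#' independent per-participant seeds, so the cohort is fully reproducible
#' and participants could be simulated in any order.
#'
#' @param n_participants Number of participants (>= 1).
#' @param param_sampler A function `f(n)` returning a data frame of
#'   controller parameters, e.g. from [default_param_sampler()].
#' @param config A [task_config()].
#' @param seed Master integer seed.
#' @param continuous If `FALSE`, stop after calibration.
#' @param age_range Participant ages drawn uniformly over this range
#'   (carried as an opaque covariate for validity analyses).
#' @return A `cpcst_cohort`: a list of participants, each a list with
#'   `participant_id`, `params` (`cpcst_controller`), `age_years`,
#'   `calibration` (`cpcst_calibration`), `calibration_trace` and, when
#'   requested, `trace` (the continuous-phase `cpcst_trace`).
#' @export
#' @examples
#' coh <- simulate_cohort(2, seed = 1, continuous = FALSE,
#'                        config = task_config())
#' sapply(coh, function(p) p$calibration$mst)
simulate_cohort <- function(n_participants,
                            param_sampler = default_param_sampler(),
                            config = task_config(), seed = 1L,
                            continuous = TRUE,
                            age_range = c(18, 76)) {
  stopifnot(n_participants >= 1)
  set.seed(seed)
  pars <- param_sampler(n_participants)
  if (nrow(pars) != n_participants)
    stop("param_sampler returned ", nrow(pars), " rows, expected ", n_participants)
  if (all(vapply(pars, function(col) length(unique(col)) == 1L, logical(1))) &&
      n_participants > 1)
    warning("degenerate parameter sampler: all participants share identical parameters")
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  ages <- runif(n_participants, age_range[1], age_range[2])
  ids <- sprintf("sim%03d", seq_len(n_participants))

  cohort <- lapply(seq_len(n_participants), function(i) {
    ctrl <- controller_params(
      feedback_delay_s = pars$feedback_delay_s[i], gain = pars$gain[i],
      motor_noise_sd = pars$motor_noise_sd[i],
      lapse_rate_hz = pars$lapse_rate_hz[i],
      lapse_duration_s = pars$lapse_duration_s[i],
      disturbance_sd = pars$disturbance_sd[i], seed = seeds[i])
    cal <- run_calibration(ctrl, config, seed = seeds[i], participant_id = ids[i])
    p <- list(participant_id = ids[i], params = ctrl, age_years = ages[i],
              calibration = cal$result, calibration_trace = cal$trace)
    if (continuous) {
      p$trace <- run_continuous(ctrl, mst = cal$result$mst, config = config,
                                seed = seeds[i] + 1L, participant_id = ids[i])
    }
    p
  })
  structure(cohort, class = "cpcst_cohort", seed = seed)
}

#' @export
print.cpcst_cohort <- function(x, ...) {
  msts <- vapply(x, function(p) p$calibration$mst, numeric(1))
  cat("cpCST synthetic cohort:", length(x), "participants\n")
  cat(sprintf("  MST: median %.2f /s (range %.2f-%.2f)\n",
              median(msts), min(msts), max(msts)))
  invisible(x)
}

#' Cohort manifest table
#'
#' One row per participant:
#' `participant_id,feedback_delay_s,gain,motor_noise_sd,lapse_rate_hz,
#' lapse_duration_s,seed,mst` (plus `age_years`).
#'
#' @param cohort A `cpcst_cohort`.
#' @return A data frame.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "cpcst_cohort"))
  do.call(rbind, lapply(cohort, function(p)
    data.frame(participant_id = p$participant_id,
               feedback_delay_s = p$params$feedback_delay_s,
               gain = p$params$gain,
               motor_noise_sd = p$params$motor_noise_sd,
               lapse_rate_hz = p$params$lapse_rate_hz,
               lapse_duration_s = p$params$lapse_duration_s,
               seed = p$params$seed,
               mst = p$calibration$mst,
               age_years = p$age_years)))
}

#' @importFrom stats median
NULL
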