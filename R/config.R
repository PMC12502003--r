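#' Task configuration for the cpCST
#'
#' Bundles every constant of the task: the 30 Hz recording rate, the crash
#' boundary at 80% of the center-to-edge distance (equivalently +/- 22.28
#' degrees visual angle, DVA), the 10-minute continuous phase run at 30% of
#' the participant's motor stability threshold (MST), and the calibration
#' schedule (10 crashes, lambda reset to 50% of its crash value, MST = mean
#' lambda over the final three crashes).
#'
#' Positions are in normalized units: screen edges at +/- 1, center at 0.
#' DVA is a reporting-only linear conversion (`dva_per_unit`, chosen so that
#' the 0.8 crash boundary maps to 22.28 DVA).
#'
#' @param sampling_rate_hz Recording and update rate of the task (Hz).
#' @param crash_fraction Crash boundary as a fraction of the half-screen
#'   extent; a crash is `|x| >= crash_fraction` (boundary inclusive).
#' @param continuous_duration_s Duration of the continuous phase (seconds).
#' @param mst_fraction Fraction of the MST used as the fixed continuous-phase
#'   difficulty.
#' @param n_calibration_crashes Number of crashes collected in calibration.
#' @param reset_fraction Fraction of the crash lambda that lambda is reset to
#'   after each calibration crash.
#' @param mst_last_k Number of final calibration crashes averaged into the MST.
#' @param lambda_ramp_rate Linear ramp rate of lambda during calibration
#'   (1/s per second). The default is chosen so mid-range synthetic
#'   controllers complete 10 crashes in roughly 2-5 simulated minutes.
#' @param lambda_initial Lambda at the start of calibration (1/s).
#' @param dva_per_unit Degrees visual angle per normalized unit.
#' @param control_sign Sign convention of the plant, `"plus"` for
#'   `dx/dt = lambda * (x + u)` (default; `u` is the already-mirrored control
#'   signal) or `"minus"` for `lambda * (x - u)`. The two are equivalent up
#'   to negating `u`; the bundled controllers adapt automatically.
#' @param x_start_offset Stimulus position at the start of the task and after
#'   every crash reset, in normalized units. The default (0.01, about one
#'   pixel / 0.28 DVA) is treated as "center": an exactly centered stimulus
#'   is a fixed point of the plant, so a sub-pixel nudge is required for the
#'   unstable dynamics to have any state to act on.
#' @param calibration_cap_s Hard cap on simulated calibration time; exceeding
#'   it raises a calibration-timeout error.
#' @param asymptote_tolerance Fractional band around the MST used by
#'   [time_to_asymptote()].
#'
#' @return An object of class `cpcst_config` (a named list).
#' @seealso [controller_params()], [run_calibration()], [run_continuous()]
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$crash_fraction * cfg$dva_per_unit  # crash boundary in DVA
task_config <- function(sampling_rate_hz = 30,
                        crash_fraction = 0.8,
                        continuous_duration_s = 600,
                        mst_fraction = 0.30,
                        n_calibration_crashes = 10L,
                        reset_fraction = 0.5,
                        mst_last_k = 3L,
                        lambda_ramp_rate = 0.2,
                        lambda_initial = 0.1,
                        dva_per_unit = 27.85,
                        control_sign = c("plus", "minus"),
                        x_start_offset = 0.01,
                        calibration_cap_s = 1800,
                        asymptote_tolerance = 0.10) {
  control_sign <- match.arg(control_sign)
  cfg <- list(sampling_rate_hz = sampling_rate_hz,
              crash_fraction = crash_fraction,
              continuous_duration_s = continuous_duration_s,
              mst_fraction = mst_fraction,
              n_calibration_crashes = as.integer(n_calibration_crashes),
              reset_fraction = reset_fraction,
              mst_last_k = as.integer(mst_last_k),
              lambda_ramp_rate = lambda_ramp_rate,
              lambda_initial = lambda_initial,
              dva_per_unit = dva_per_unit,
              control_sign = control_sign,
              x_start_offset = x_start_offset,
              calibration_cap_s = calibration_cap_s,
              asymptote_tolerance = asymptote_tolerance)
  class(cfg) <- "cpcst_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    "sampling_rate_hz must be > 0" = is.finite(cfg$sampling_rate_hz) && cfg$sampling_rate_hz > 0,
    "crash_fraction must be in (0, 1]" = cfg$crash_fraction > 0 && cfg$crash_fraction <= 1,
    "continuous_duration_s must be > 0" = cfg$continuous_duration_s > 0,
    "mst_fraction must be in (0, 1)" = cfg$mst_fraction > 0 && cfg$mst_fraction < 1,
    "n_calibration_crashes must be >= 1" = cfg$n_calibration_crashes >= 1L,
    "reset_fraction must be in (0, 1)" = cfg$reset_fraction > 0 && cfg$reset_fraction < 1,
    "mst_last_k must not exceed n_calibration_crashes" =
      cfg$mst_last_k >= 1L && cfg$mst_last_k <= cfg$n_calibration_crashes,
    "lambda_ramp_rate must be > 0" = cfg$lambda_ramp_rate > 0,
    "lambda_initial must be >= 0" = cfg$lambda_initial >= 0,
    "dva_per_unit must be > 0" = cfg$dva_per_unit > 0,
    "x_start_offset must lie inside the crash boundary" =
      abs(cfg$x_start_offset) < cfg$crash_fraction
  )
  invisible(cfg)
}

#' @export
print.cpcst_config <- function(x, ...) {
  cat("cpCST task configuration\n")
  cat(sprintf("  sampling rate:      %g Hz\n", x$sampling_rate_hz))
  cat(sprintf("  crash boundary:     |x| >= %g (%.2f DVA)\n",
              x$crash_fraction, x$crash_fraction * x$dva_per_unit))
  cat(sprintf("  continuous phase:   %g s at %g%% of MST\n",
              x$continuous_duration_s, 100 * x$mst_fraction))
  cat(sprintf("  calibration:        %d crashes, reset to %g%%, MST = mean of last %d\n",
              x$n_calibration_crashes, 100 * x$reset_fraction, x$mst_last_k))
  cat(sprintf("  lambda ramp:        %g /s per s from %g /s\n",
              x$lambda_ramp_rate, x$lambda_initial))
  invisible(x)
}

#' Write or read a task configuration as a key/value text file
#'
#' One `key = value` pair per line; unknown keys are rejected on read.
#'
#' @param cfg A [task_config()] object.
#' @param path File path.
#' @return `read_task_config()` returns a `cpcst_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
write_task_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cpcst_config"))
  fields <- unclass(cfg)
  lines <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  allowed <- names(formals(task_config))
  bad <- setdiff(keys, allowed)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "control_sign") vals[i] else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(task_config, args)
}
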