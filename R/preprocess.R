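#' Excise crashes and reconstruct by PCHIP interpolation
#'
#' Continuous-phase cleaning: samples at or beyond the crash boundary are
#' removed, together with the instantaneous reset jump back to center (any
#' adjacent sample reached through a position step larger than
#' `jump_threshold`, an artifact of the reset rather than behavior). Both
#' the stimulus and the user series are then refilled over the removed
#' samples by monotone piecewise-cubic Hermite (PCHIP) interpolation over
#' time, so downstream alignment sees aligned, smoothly continuous pairs.
#' The cleaned trace has the same length as the input.
#'
#' A crash event is a maximal run of consecutive boundary-exceeding samples
#' (plus its reset transient); the returned count is the number of such
#' events, the quantity the participant-level outlier rule is applied to.
#'
#' @param trace A continuous-phase `cpcst_trace`.
#' @param config A [task_config()].
#' @param jump_threshold Position step (normalized units) identifying the
#'   reset discontinuity.
#' @return A list with `trace` (cleaned, `interpolated_flag` column added)
#'   and `n_crashes` (integer count of crash events).
#' @section Errors: a crash gap touching the first or last sample cannot be
#'   interpolated (no anchor on one side) and raises an error.
#' @export
excise_and_interpolate <- function(trace, config = task_config(),
                                   jump_threshold = 0.5) {
  assert_trace(trace)
  x <- trace$stim_x
  n <- length(x)
  bad <- abs(x) >= config$crash_fraction

  ## count events before extending: maximal runs of boundary-exceeding samples
  r <- rle(bad)
  n_crashes <- sum(r$values)

  if (n_crashes > 0) {
    ## absorb the reset jump: samples adjacent to a > jump_threshold step
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      e <- ends[k]
      while (e < n && abs(x[e + 1] - x[e]) > jump_threshold) {
        e <- e + 1L
        bad[e] <- TRUE
      }
      s <- starts[k]
      while (s > 1 && abs(x[s] - x[s - 1]) > jump_threshold) {
        s <- s - 1L
        bad[s] <- TRUE
      }
    }
    if (bad[1] || bad[n])
      stop("crash gap touches the trace boundary; cannot interpolate without extrapolating")
    keep <- which(!bad)
    gap <- which(bad)
    out <- trace
    out$stim_x[gap] <- pracma::pchip(trace$t_sec[keep], trace$stim_x[keep],
                                     trace$t_sec[gap])
    out$user_x[gap] <- pracma::pchip(trace$t_sec[keep], trace$user_x[keep],
                                     trace$t_sec[gap])
    out$crash_flag[gap] <- 0L
    out$interpolated_flag <- as.integer(bad)
    trace <- out
  } else if (is.null(trace$interpolated_flag)) {
    trace$interpolated_flag <- 0L
  }
  class(trace) <- c("cpcst_trace", "data.frame")
  list(trace = trace, n_crashes = as.integer(n_crashes))
}

#' Participant-level crash outlier rule
#'
#' Participants with two or more crashes in the continuous phase are
#' classified as outliers and removed; zero or one crash is retained.
#'
#' @param n_crashes Named integer vector (or list of
#'   [excise_and_interpolate()] results) of per-participant crash counts.
#' @param max_crashes Largest crash count retained (default 1).
#' @return A data frame `participant_id, n_crashes, excluded`.
#' @export
#' @examples
#' apply_outlier_rule(c(a = 0L, b = 1L, c = 2L))
apply_outlier_rule <- function(n_crashes, max_crashes = 1L) {
  if (is.list(n_crashes) && !is.data.frame(n_crashes)) {
    ids <- names(n_crashes)
    n_crashes <- vapply(n_crashes, function(x)
      if (is.list(x)) x$n_crashes else as.integer(x), integer(1))
    names(n_crashes) <- ids
  }
  ids <- if (is.null(names(n_crashes))) as.character(seq_along(n_crashes))
         else names(n_crashes)
  data.frame(participant_id = ids,
             n_crashes = as.integer(n_crashes),
             excluded = n_crashes > max_crashes,
             row.names = NULL)
}

#' Task-compliance summary: mean stimulus position
#'
#' Mean signed stimulus position over a cleaned continuous trace, reported
#' in degrees visual angle. The cohort version reports the across-
#' participant mean and SD of the per-participant means (the form in which
#' task compliance is usually quoted).
#'
#' @param trace A cleaned continuous `cpcst_trace`.
#' @param config A [task_config()].
#' @return `compliance_summary()`: mean position in signed DVA.
#' @export
compliance_summary <- function(trace, config = task_config()) {
  assert_trace(trace)
  mean(trace$stim_x) * config$dva_per_unit
}

#' @rdname compliance_summary
#' @param traces List of cleaned continuous traces.
#' @return `compliance_cohort()`: list with `mean_dva`, `sd_dva` and the
#'   per-participant means.
#' @export
compliance_cohort <- function(traces, config = task_config()) {
  per <- vapply(traces, compliance_summary, numeric(1), config = config)
  list(mean_dva = mean(per), sd_dva = sd(per), per_participant_dva = per)
}
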