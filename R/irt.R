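#' Prepare stimulus and user series for alignment
#'
#' The user series is mirrored (negated) so corrective movements point in
#' the direction of the stimulus drift they answer, then both series are
#' z-scored with their own mean and SD. A perfectly mirroring user
#' (`user_x = -stim_x`) yields two identical standardized series.
#'
#' @param trace A cleaned continuous `cpcst_trace`.
#' @return List with `a` (standardized stimulus) and `b` (standardized
#'   mirrored user series).
#' @section Errors: a zero-variance series (frozen controller) cannot be
#'   standardized and raises a degenerate-series error.
#' @export
prepare_series <- function(trace) {
  assert_trace(trace)
  zs <- function(v, lab) {
    s <- sd(v)
    if (!is.finite(s) || s <= 0)
      stop("degenerate ", lab, " series: zero variance, cannot z-score")
    (v - mean(v)) / s
  }
  list(a = zs(trace$stim_x, "stimulus"), b = zs(-trace$user_x, "user"))
}

#' Dynamic-time-warping alignment of two series
#'
#' Dynamic-programming minimization of the cumulative pointwise cost
#' `|a_i - b_j|` (optionally squared) with steps `{(1,1), (1,0), (0,1)}`,
#' anchored at both boundaries. An optional Sakoe-Chiba band constrains
#' `|i - j| <= band`. One optimal path is returned; ties are broken by
#' preferring the diagonal step, then the step advancing `i`. Exact
#' (unbanded) alignment is the reference behavior; the band is a speed
#' option for long traces.
#'
#' @param a,b Numeric series (typically from [prepare_series()]).
#' @param band Optional window half-width in samples (`NULL` for exact DTW).
#' @param cost Pointwise cost, `"l1"` (default) or `"squared"`.
#' @return A `cpcst_warp` list: `index_a`, `index_b` (1-based, monotone,
#'   starting at (1,1) and ending at (N,M)) and `total_cost`.
#' @export
#' @examples
#' p <- dtw_align(c(0, 1, 2), c(0, 1, 2))
#' p$total_cost  # identical series align along the diagonal at zero cost
dtw_align <- function(a, b, band = NULL, cost = c("l1", "squared")) {
  cost <- match.arg(cost)
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 1L || length(b) < 1L)
    stop("both series must be non-empty numeric vectors")
  if (anyNA(a) || anyNA(b)) stop("series must not contain missing values")
  if (!is.null(band)) {
    band <- as.integer(band)
    if (band < abs(length(a) - length(b)))
      stop("DTW band is too narrow to connect the endpoints")
  }
  res <- dtw_cpp(as.numeric(a), as.numeric(b),
                 if (is.null(band)) -1L else band, cost == "squared")
  structure(list(index_a = res$index_a, index_b = res$index_b,
                 total_cost = res$total_cost),
            class = "cpcst_warp")
}

#' Instantaneous reaction time from a warp path
#'
#' Converts the warp path into a signed per-timepoint latency: for each
#' stimulus index `i`, the mean over its matched user indices `j` of
#' `(j - i) / sampling_rate_hz`. Positive latency means the user lags the
#' stimulus; an anticipatory response gives negative latency. `mean_irt_s`
#' is the mean over stimulus timepoints.
#'
#' @param path A `cpcst_warp` from [dtw_align()].
#' @param config A [task_config()] (supplies the sampling rate).
#' @param aggregate Per-timepoint aggregation over matched partners,
#'   `"mean"` (default) or `"median"`.
#' @return A `cpcst_irt` list: `latency_s` (one value per stimulus
#'   timepoint) and `mean_irt_s`.
#' @export
path_to_latency <- function(path, config = task_config(),
                            aggregate = c("mean", "median")) {
  stopifnot(inherits(path, "cpcst_warp"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else median
  off <- (path$index_b - path$index_a) / config$sampling_rate_hz
  lat <- as.numeric(tapply(off, path$index_a, agg))
  structure(list(latency_s = lat, mean_irt_s = mean(lat)),
            class = "cpcst_irt")
}

#' @export
print.cpcst_irt <- function(x, ...) {
  cat(sprintf("cpCST iRT series: %d timepoints, mean iRT %.4f s\n",
              length(x$latency_s), x$mean_irt_s))
  invisible(x)
}

#' Instantaneous reaction time of a cleaned trace
#'
#' Convenience wrapper: [prepare_series()], [dtw_align()],
#' [path_to_latency()], with an optional trim of the boundary-anchored path
#' edges (where DTW is forced to (1,1) and (N,M) regardless of the true
#' lag) before the mean is taken.
#'
#' @inheritParams dtw_align
#' @param trace A cleaned continuous `cpcst_trace`.
#' @param config A [task_config()].
#' @param trim_edges_s Seconds excluded from each end of the latency series
#'   when computing `mean_irt_s` (default 0; the full series is always
#'   returned).
#' @param aggregate Passed to [path_to_latency()].
#' @return A `cpcst_irt` list: `latency_s`, `mean_irt_s` (over the trimmed
#'   range) and `n_valid_samples`.
#' @export
compute_irt <- function(trace, config = task_config(), band = NULL,
                        cost = c("l1", "squared"), trim_edges_s = 0,
                        aggregate = c("mean", "median")) {
  ser <- prepare_series(trace)
  path <- dtw_align(ser$a, ser$b, band = band, cost = match.arg(cost))
  irt <- path_to_latency(path, config, aggregate = match.arg(aggregate))
  n <- length(irt$latency_s)
  k <- round(trim_edges_s * config$sampling_rate_hz)
  keep <- if (k > 0 && n > 2 * k) (k + 1):(n - k) else seq_len(n)
  irt$mean_irt_s <- mean(irt$latency_s[keep])
  irt$n_valid_samples <- length(keep)
  irt
}

#' Residual structure lost to discrete sampling
#'
#' Emulates a discrete reaction-time paradigm probing behavior every
#' `probe_interval_s` seconds: the 30 Hz stimulus series is resampled by
#' zero-order hold at the probe interval and subtracted from the full-rate
#' series. The exceedance fraction reports how often the unexplained
#' residual exceeds two SDs of the full-rate series -- behavioral variation
#' a discrete-sampling task would miss.
#'
#' @param trace A `cpcst_trace` or numeric stimulus series.
#' @param probe_interval_s Probe interval in seconds (>= one sample).
#' @param config A [task_config()].
#' @return List with `residual`, `exceed_fraction`, `rms` and
#'   `probe_interval_s`.
#' @export
discrete_sampling_residual <- function(trace, probe_interval_s,
                                       config = task_config()) {
  x <- if (inherits(trace, "cpcst_trace") || is.data.frame(trace)) {
    assert_trace(trace)
    trace$stim_x
  } else as.numeric(trace)
  dt <- 1 / config$sampling_rate_hz
  stopifnot(probe_interval_s >= dt)
  n <- length(x)
  t <- (seq_len(n) - 1L) * dt
  ## small epsilon guards against t/probe landing just under an integer
  probe_t <- floor(t / probe_interval_s + 1e-9) * probe_interval_s
  idx <- pmin(n, round(probe_t / dt) + 1L)
  residual <- x - x[idx]
  s <- sd(x)
  list(residual = residual,
       exceed_fraction = if (s > 0) mean(abs(residual) > 2 * s) else 0,
       rms = sqrt(mean(residual^2)),
       probe_interval_s = probe_interval_s)
}

#' iRT output tables
#'
#' Long per-timepoint table `participant_id,sample_index,t_sec,latency_s`
#' and the participant summary `participant_id,mean_irt_s,n_valid_samples`.
#'
#' @param irt A `cpcst_irt` from [compute_irt()].
#' @param participant_id Identifier for the tables.
#' @param config A [task_config()].
#' @return List with `series` and `summary` data frames.
#' @export
irt_tables <- function(irt, participant_id, config = task_config()) {
  stopifnot(inherits(irt, "cpcst_irt"))
  n <- length(irt$latency_s)
  list(series = data.frame(participant_id = participant_id,
                           sample_index = seq_len(n) - 1L,
                           t_sec = (seq_len(n) - 1L) / config$sampling_rate_hz,
                           latency_s = irt$latency_s),
       summary = data.frame(participant_id = participant_id,
                            mean_irt_s = irt$mean_irt_s,
                            n_valid_samples = irt$n_valid_samples %||% n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats median
NULL
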