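#' Spearman-Brown prophecy correction
#'
#' Predicts full-test reliability from a half-test correlation:
#' `2 r / (1 + r)`. Monotone increasing on `(-1, 1]` and mapping `[0, 1]`
#' into itself; undefined at `r = -1`.
#'
#' @param r Correlation between the two half-scores.
#' @return The corrected correlation.
#' @export
#' @examples
#' spearman_brown(0.5)  # 2/3
spearman_brown <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)), all(r <= 1))
  if (any(r == -1)) stop("Spearman-Brown correction is undefined at r = -1")
  2 * r / (1 + r)
}

## validate a trial table and return it ordered by participant
check_trial_table <- function(table, min_participants = 3L, min_trials = 2L) {
  if (!is.data.frame(table) || !all(c("participant_id", "value") %in% names(table)))
    stop("trial table needs columns participant_id and value")
  if (anyNA(table$value)) stop("trial values must not be missing")
  counts <- table(table$participant_id)
  if (length(counts) < min_participants)
    stop("insufficient sample: need at least ", min_participants, " participants")
  if (any(counts < min_trials))
    stop("every participant needs at least ", min_trials, " trial units")
  table[order(table$participant_id), , drop = FALSE]
}

split_layout <- function(table) {
  ids <- table$participant_id
  lens <- as.integer(table(factor(ids, levels = unique(ids))))
  list(values = as.numeric(table$value),
       start = c(0L, cumsum(lens))[seq_along(lens)],
       len = lens)
}

#' One permutation split-half estimate
#'
#' Each participant's trial units are randomly permuted and split into two
#' halves (the first half takes the extra unit when the count is odd); the
#' half means are correlated across participants (Pearson) and the
#' Spearman-Brown correction applied. Uses the current RNG state.
#'
#' @param table Trial table with columns `participant_id` and `value`
#'   (an iRT bin mean in seconds, or a flanker RT in ms); at least 2 units
#'   per participant and 3 participants.
#' @return The corrected split-half correlation.
#' @export
split_half_once <- function(table) {
  table <- check_trial_table(table)
  halves <- vapply(split(table$value, factor(table$participant_id,
                                             levels = unique(table$participant_id))),
                   function(v) {
                     v <- sample(v)
                     k1 <- ceiling(length(v) / 2)
                     c(mean(v[seq_len(k1)]), mean(v[-seq_len(k1)]))
                   }, numeric(2))
  spearman_brown(cor(halves[1, ], halves[2, ]))
}

#' Permutation-averaged split-half reliability
#'
#' Mean corrected split-half correlation over `n_perm` random permutation
#' splits (1,000 by default).
#'
#' @inheritParams split_half_once
#' @param n_perm Number of permutation splits.
#' @param seed Optional integer seed.
#' @return The mean corrected split-half correlation.
#' @export
split_half_reliability <- function(table, n_perm = 1000L, seed = NULL) {
  table <- check_trial_table(table)
  if (!is.null(seed)) set.seed(seed)
  lay <- split_layout(table)
  est <- splithalf_boot_cpp(lay$values, lay$start, lay$len,
                            numeric(0), integer(0), integer(0),
                            n_boot = 1L, n_perm = as.integer(n_perm),
                            resample = FALSE, diff_mode = FALSE)
  est[1]
}

#' Bootstrap split-half reliability with percentile confidence interval
#'
#' Each bootstrap draw resamples participants with replacement and computes
#' the permutation-averaged corrected split-half correlation (`n_perm`
#' permutations per draw; reduced from the headline 1,000 for tractability
#' inside the bootstrap). The point estimate is the mean across draws and
#' the 95% CI the 2.5th/97.5th percentiles of the bootstrap distribution.
#'
#' For difference-score measures (the flanker congruency effect), supply
#' `table2`: trials are permuted and halved within each table separately
#' and the half-difference scores (`table2` minus `table`) are correlated.
#'
#' @inheritParams split_half_once
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param n_perm Permutation splits per draw (default 100).
#' @param seed Optional integer seed; the estimate is reproducible under a
#'   fixed seed.
#' @param table2 Optional second trial table (same participants) for
#'   difference scores.
#' @return A `cpcst_reliability` list: `point`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_perm`, `boot_estimates`.
#' @export
bootstrap_reliability <- function(table, n_boot = 1000L, n_perm = 100L,
                                  seed = NULL, table2 = NULL) {
  table <- check_trial_table(table)
  diff_mode <- !is.null(table2)
  if (diff_mode) {
    table2 <- check_trial_table(table2)
    if (!identical(unique(table$participant_id), unique(table2$participant_id)))
      stop("table and table2 must cover the same participants in the same order")
  }
  if (!is.null(seed)) set.seed(seed)
  lay <- split_layout(table)
  lay2 <- if (diff_mode) split_layout(table2)
          else list(values = numeric(0), start = integer(0), len = integer(0))
  boots <- splithalf_boot_cpp(lay$values, lay$start, lay$len,
                              lay2$values, lay2$start, lay2$len,
                              n_boot = as.integer(n_boot),
                              n_perm = as.integer(n_perm),
                              resample = TRUE, diff_mode = diff_mode)
  ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  structure(list(point = mean(boots, na.rm = TRUE),
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 boot_estimates = boots),
            class = "cpcst_reliability")
}

#' @export
print.cpcst_reliability <- function(x, ...) {
  cat(sprintf("split-half reliability r = %.4f; 95%% CI (%.4f, %.4f); %d bootstrap draws x %d permutations\n",
              x$point, x$ci_low, x$ci_high, x$n_boot, x$n_perm))
  invisible(x)
}

#' Write a reliability estimate as a structured (JSON) report
#'
#' @param est A `cpcst_reliability`.
#' @param path Output file.
#' @param measure Label of the measure (e.g. `"irt"`, `"conRT"`).
#' @param seed Seed used, recorded for provenance.
#' @param trial_unit Free-text definition of the trial unit.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(est, path, measure = "irt",
                                     seed = NA_integer_,
                                     trial_unit = "1 s latency bin") {
  stopifnot(inherits(est, "cpcst_reliability"))
  jsonlite::write_json(
    list(measure = measure, point = est$point, ci_low = est$ci_low,
         ci_high = est$ci_high, n_boot = est$n_boot, n_perm = est$n_perm,
         seed = seed, trial_unit = trial_unit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trial units for the cpCST: fixed-width latency bins
#'
#' The cpCST has no discrete trials; for split-half purposes the latency
#' series is cut into non-overlapping fixed-width bins (1 s = 30 samples by
#' default) whose means are the trial units, balancing unit count against
#' serial dependence. Each unit also carries the task minute it ends in,
#' for stability curves.
#'
#' @param latency_s Numeric latency series (or a `cpcst_irt`).
#' @param participant_id Identifier.
#' @param config A [task_config()].
#' @param bin_s Bin width in seconds.
#' @return Data frame `participant_id, trial_unit_index, minute, value`.
#' @export
irt_trial_table <- function(latency_s, participant_id = "p1",
                            config = task_config(), bin_s = 1) {
  if (inherits(latency_s, "cpcst_irt")) latency_s <- latency_s$latency_s
  w <- round(bin_s * config$sampling_rate_hz)
  stopifnot(w >= 1)
  n_bins <- floor(length(latency_s) / w)
  stopifnot(n_bins >= 1)
  idx <- rep(seq_len(n_bins), each = w)
  vals <- as.numeric(tapply(latency_s[seq_len(n_bins * w)], idx, mean))
  data.frame(participant_id = participant_id,
             trial_unit_index = seq_len(n_bins),
             minute = ceiling(seq_len(n_bins) * bin_s / 60),
             value = vals)
}

#' Temporal-efficiency stability curve
#'
#' For each `n` in `1..full_duration_min`, the participant means computed
#' from only the first `n` minutes of data are correlated (Pearson) with
#' the means from the full duration. By construction the curve reaches
#' `r = 1` at the full duration. Participants without data inside a window
#' are dropped pairwise with a warning.
#'
#' @param table Trial table with columns `participant_id`, `minute`
#'   (integer task minute of each trial unit) and `value`.
#' @param full_duration_min Full task duration in minutes (`K`).
#' @return A `cpcst_stability` data frame: `minutes, r, n_pairs`.
#' @export
stability_curve <- function(table, full_duration_min) {
  stopifnot(all(c("participant_id", "minute", "value") %in% names(table)))
  K <- as.integer(full_duration_min)
  ids <- unique(table$participant_id)
  if (length(ids) < 3) stop("insufficient sample: need at least 3 participants")
  mean_upto <- function(n) {
    sub <- table[table$minute <= n, ]
    m <- tapply(sub$value, factor(sub$participant_id, levels = ids), mean)
    as.numeric(m)
  }
  full <- mean_upto(K)
  rows <- lapply(seq_len(K), function(n) {
    m <- mean_upto(n)
    ok <- !is.na(m) & !is.na(full)
    if (any(!ok))
      warning("minute ", n, ": ", sum(!ok),
              " participant(s) without data excluded pairwise")
    data.frame(minutes = n, r = cor(m[ok], full[ok]), n_pairs = sum(ok))
  })
  structure(do.call(rbind, rows), class = c("cpcst_stability", "data.frame"))
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests `H0: rho_jk = rho_jh` given the correlation `r_kh` between the two
#' non-shared variables, with the pooled-estimate variant: Fisher-transform
#' both correlations and refer
#' `Z = (z_jk - z_jh) * sqrt((n - 3) / (2 (1 - r_kh) h))` to the standard
#' normal, where `h = (1 - f rbar^2) / (1 - rbar^2)`,
#' `f = (1 - r_kh) / (2 (1 - rbar^2))` (capped at 1) and
#' `rbar = (r_jk + r_jh) / 2`.
#'
#' @param r_jk,r_jh The two dependent correlations (shared variable `j`),
#'   each in `(-1, 1)`.
#' @param r_kh Correlation between the non-shared variables, in `(-1, 1)`.
#' @param n Sample size (>= 4).
#' @return List with `z` and two-sided `p`.
#' @export
#' @examples
#' steiger_z(0.9, 0.7, 0.6, n = 150)
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n >= 4)
  for (r in c(r_jk, r_jh, r_kh)) {
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations must lie strictly inside (-1, 1); Fisher transform overflows at |r| = 1")
  }
  rbar <- (r_jk + r_jh) / 2
  f <- min(1, (1 - r_kh) / (2 * (1 - rbar^2)))
  h <- (1 - f * rbar^2) / (1 - rbar^2)
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare two stability curves minute by minute
#'
#' Applies [steiger_z()] at each minute with the full-task measure as the
#' shared variable: `r_jk` is curve A's truncated-vs-full correlation,
#' `r_jh` curve B's, and `r_between` the correlation between the two
#' truncated measures at that minute. Correlations equal to 1 in magnitude
#' (a stability curve is exactly 1 at the full duration by construction)
#' are clamped to `+/- (1 - 1e-12)` before the transform.
#'
#' @param curve_a,curve_b `cpcst_stability` curves on the same minute grid.
#' @param r_between Numeric vector, per-minute correlation between the two
#'   truncated measures.
#' @param n Sample size the correlations were computed on.
#' @param alpha Flagging threshold for `p` (default 0.05).
#' @return Data frame `minutes, r_a, r_b, z, p, flagged`.
#' @export
compare_stability_curves <- function(curve_a, curve_b, r_between, n,
                                     alpha = 0.05) {
  if (!identical(curve_a$minutes, curve_b$minutes))
    stop("stability curves must share the same minute grid")
  if (length(r_between) != nrow(curve_a))
    stop("r_between must supply one correlation per minute")
  clamp <- function(r) pmax(-1 + 1e-12, pmin(1 - 1e-12, r))
  out <- lapply(seq_len(nrow(curve_a)), function(i) {
    st <- steiger_z(clamp(curve_a$r[i]), clamp(curve_b$r[i]),
                    clamp(r_between[i]), n)
    data.frame(minutes = curve_a$minutes[i], r_a = curve_a$r[i],
               r_b = curve_b$r[i], z = st$z, p = st$p,
               flagged = st$p < alpha)
  })
  do.call(rbind, out)
}
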