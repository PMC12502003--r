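#' Ex-Gaussian condition specification for the flanker generator
#'
#' Reaction times are drawn from an ex-Gaussian (Gaussian plus exponential)
#' per condition, with a Gaussian participant random effect on the mean.
#' Defaults give a 60 ms congruency effect (incongruent minus congruent)
#' with realistic spread and accuracy: fast, accurate congruent trials and
#' slower, more error-prone incongruent trials.
#'
#' @param mu_ms Named numeric: Gaussian mean per condition (ms).
#' @param sigma_ms Gaussian SD (ms); 0 allowed for deterministic limits.
#' @param tau_ms Exponential mean (ms); 0 disables the exponential tail.
#' @param participant_sd_ms SD of the per-participant shift of all means.
#' @param p_correct Named numeric: probability of a correct response per
#'   condition.
#' @return A `cpcst_flanker_spec` list.
#' @export
flanker_spec <- function(mu_ms = c(congruent = 430, neutral = 450,
                                   incongruent = 490),
                         sigma_ms = 40, tau_ms = 80,
                         participant_sd_ms = 40,
                         p_correct = c(congruent = 0.98, neutral = 0.97,
                                       incongruent = 0.93)) {
  conds <- c("congruent", "neutral", "incongruent")
  stopifnot(all(conds %in% names(mu_ms)), all(conds %in% names(p_correct)),
            sigma_ms >= 0, tau_ms >= 0, participant_sd_ms >= 0,
            all(p_correct >= 0 & p_correct <= 1))
  structure(list(mu_ms = mu_ms[conds], sigma_ms = sigma_ms, tau_ms = tau_ms,
                 participant_sd_ms = participant_sd_ms,
                 p_correct = p_correct[conds]),
            class = "cpcst_flanker_spec")
}

## A condition sequence with exactly equal counts and first-order
## counterbalancing: an Eulerian circuit on the complete 3-node multigraph
## (self-loops included) with n_trials/9 copies of each ordered transition.
balanced_condition_sequence <- function(n_trials) {
  conds <- c("congruent", "neutral", "incongruent")
  stopifnot(n_trials %% 9 == 0)
  m <- n_trials / 9
  ## adjacency: for each node, the multiset of destinations, shuffled
  adj <- lapply(1:3, function(i) sample(rep(1:3, each = m)))
  ptr <- rep(1L, 3)
  stack <- c(sample(1:3, 1))
  circuit <- integer(0)
  while (length(stack) > 0) {           # Hierholzer's algorithm
    v <- stack[length(stack)]
    if (ptr[v] <= length(adj[[v]])) {
      w <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, w)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  circuit <- rev(circuit)               # closed walk of n_trials + 1 nodes
  conds[circuit[seq_len(n_trials)]]
}

#' Simulate a flanker-task cohort
#'
#' Trial-level generator for the comparison task: `n_trials` (360 = 3
#' blocks of 120) per participant with exactly equal condition counts and a
#' first-order counterbalanced condition order (every ordered transition
#' between conditions occurs equally often, within one). RTs are
#' ex-Gaussian per condition with a per-participant random shift of all
#' means (optionally supplied, e.g. to couple the flanker to a latent
#' attentional trait); accuracy is Bernoulli per condition. Trial onsets
#' are spread evenly over the nominal session (about 1.72 s per trial).
#'
#' @param n_participants Number of participants.
#' @param spec A [flanker_spec()].
#' @param n_trials Trials per participant; must be divisible by 9 so the
#'   transition counts can be exactly balanced.
#' @param seed Integer seed.
#' @param participant_shift_ms Optional numeric vector (length
#'   `n_participants`) of per-participant mean shifts; drawn from
#'   `N(0, participant_sd_ms)` when omitted.
#' @param ids Participant identifiers.
#' @return Data frame `participant_id, block, trial_index, t_sec,
#'   condition, rt_ms, correct`.
#' @export
simulate_flanker_cohort <- function(n_participants, spec = flanker_spec(),
                                    n_trials = 360L, seed = 1L,
                                    participant_shift_ms = NULL,
                                    ids = sprintf("sim%03d", seq_len(n_participants))) {
  stopifnot(inherits(spec, "cpcst_flanker_spec"), n_participants >= 1)
  set.seed(seed)
  if (is.null(participant_shift_ms))
    participant_shift_ms <- rnorm(n_participants, 0, spec$participant_sd_ms)
  stopifnot(length(participant_shift_ms) == n_participants)
  session_s <- n_trials * 618 / 360     # nominal session length scales with trials
  out <- lapply(seq_len(n_participants), function(i) {
    cond <- balanced_condition_sequence(n_trials)
    mu <- spec$mu_ms[cond] + participant_shift_ms[i]
    rt <- mu
    if (spec$sigma_ms > 0) rt <- rt + rnorm(n_trials, 0, spec$sigma_ms)
    if (spec$tau_ms > 0) rt <- rt + rexp(n_trials, rate = 1 / spec$tau_ms)
    rt <- pmax(rt, 1)                   # RTs are positive
    correct <- runif(n_trials) < spec$p_correct[cond]
    data.frame(participant_id = ids[i],
               block = rep(seq_len(3), length.out = n_trials,
                           each = ceiling(n_trials / 3)),
               trial_index = seq_len(n_trials),
               t_sec = (seq_len(n_trials) - 0.5) * session_s / n_trials,
               condition = unname(cond),
               rt_ms = unname(rt),
               correct = correct)
  })
  do.call(rbind, out)
}

#' Trim flanker trials and summarize one participant
#'
#' Applies the trimming pipeline in its stated order: (1) a participant
#' with overall accuracy below `accuracy_cutoff` (80%) across all trial
#' conditions is flagged as excluded; (2) incorrect trials are dropped;
#' (3) anticipatory RTs faster than `anticipatory_ms` (200 ms) are dropped;
#' (4) RTs more than `sd_mult` (2.5) SDs above the participant's mean --
#' mean and SD pooled over the remaining correct trials of all conditions
#' by default, or per condition with `sd_scope = "condition"` -- are
#' dropped. Condition means, the congruency effect (incongruent minus
#' congruent) and accuracy are computed from the survivors.
#'
#' @param trials Data frame of one participant's trials (`condition`,
#'   `rt_ms`, `correct`).
#' @param accuracy_cutoff Minimum overall accuracy for inclusion.
#' @param anticipatory_ms Anticipatory threshold (ms).
#' @param sd_mult Upper trim multiplier.
#' @param sd_scope `"pooled"` (default) or `"condition"`.
#' @return A `cpcst_flanker_summary` list: `conRT`, `incRT`, `neuRT`,
#'   `ic_effect`, `accuracy`, `included`, `n_retained`. A condition emptied
#'   by trimming yields `NA` for its mean with a warning.
#' @export
trim_and_summarize <- function(trials, accuracy_cutoff = 0.80,
                               anticipatory_ms = 200, sd_mult = 2.5,
                               sd_scope = c("pooled", "condition")) {
  sd_scope <- match.arg(sd_scope)
  stopifnot(all(c("condition", "rt_ms", "correct") %in% names(trials)))
  accuracy <- mean(trials$correct)
  included <- accuracy >= accuracy_cutoff
  kept <- trimmed_trials(trials, accuracy_cutoff, anticipatory_ms, sd_mult,
                         sd_scope)
  cond_mean <- function(cond) {
    v <- kept$rt_ms[kept$condition == cond]
    if (length(v) == 0) {
      warning("condition ", cond, " emptied by trimming")
      return(NA_real_)
    }
    mean(v)
  }
  conRT <- cond_mean("congruent")
  incRT <- cond_mean("incongruent")
  neuRT <- if (any(trials$condition == "neutral")) cond_mean("neutral") else NA_real_
  structure(list(conRT = conRT, incRT = incRT, neuRT = neuRT,
                 ic_effect = incRT - conRT, accuracy = accuracy,
                 included = included, n_retained = nrow(kept)),
            class = "cpcst_flanker_summary")
}

#' Trim and summarize every participant of a flanker table
#'
#' @param trials Flanker trial table from [simulate_flanker_cohort()] (or
#'   the same columns read from CSV).
#' @param ... Passed to [trim_and_summarize()].
#' @return Data frame `participant_id, conRT, incRT, neuRT, ic_effect,
#'   accuracy, included, n_retained`.
#' @export
flanker_summaries <- function(trials, ...) {
  stopifnot("participant_id" %in% names(trials))
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    s <- trim_and_summarize(trials[trials$participant_id == id, ], ...)
    data.frame(participant_id = id, conRT = s$conRT, incRT = s$incRT,
               neuRT = s$neuRT, ic_effect = s$ic_effect,
               accuracy = s$accuracy, included = s$included,
               n_retained = s$n_retained)
  })
  do.call(rbind, out)
}

#' Flanker trial table for split-half analyses
#'
#' Reshapes trimmed correct trials of one condition into the
#' `participant_id, value, minute` trial-unit format used by the
#' reliability and stability machinery. Trials surviving the
#' [trim_and_summarize()] rules are retained.
#'
#' @inheritParams flanker_summaries
#' @param condition `"congruent"`, `"incongruent"` or `"neutral"`.
#' @param ... Passed to [trim_and_summarize()] (trimming thresholds).
#' @return Data frame `participant_id, trial_unit_index, minute, value`.
#' @export
flanker_trial_table <- function(trials, condition, ...) {
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    keep <- trimmed_trials(tr, ...)
    keep <- keep[keep$condition == condition, ]
    if (nrow(keep) == 0) return(NULL)
    data.frame(participant_id = id,
               trial_unit_index = seq_len(nrow(keep)),
               minute = ceiling(keep$t_sec / 60),
               value = keep$rt_ms)
  })
  do.call(rbind, out)
}

## survivors of the trimming pipeline (helper shared with the summaries)
trimmed_trials <- function(trials, accuracy_cutoff = 0.80,
                           anticipatory_ms = 200, sd_mult = 2.5,
                           sd_scope = c("pooled", "condition")) {
  sd_scope <- match.arg(sd_scope)
  kept <- trials[trials$correct & trials$rt_ms >= anticipatory_ms, ]
  if (sd_scope == "pooled") {
    cutoff <- mean(kept$rt_ms) + sd_mult * sd(kept$rt_ms)
    if (is.na(cutoff)) cutoff <- Inf
    kept[kept$rt_ms <= cutoff, ]
  } else {
    do.call(rbind, lapply(split(kept, kept$condition), function(g) {
      cutoff <- mean(g$rt_ms) + sd_mult * sd(g$rt_ms)
      if (is.na(cutoff)) cutoff <- Inf
      g[g$rt_ms <= cutoff, ]
    }))
  }
}
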