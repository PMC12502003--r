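## Shared fixtures and independent oracles, all built in code.

## Exhaustive enumeration of every monotone boundary-anchored warp path
## (steps (1,1), (1,0), (0,1)); returns the minimum cumulative L1 cost.
## Independent of the dynamic-programming implementation.
dtw_brute_force <- function(a, b) {
  N <- length(a)
  M <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == N && j == M) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    if (i < N && j < M) rec(i + 1, j + 1, acc)
    if (i < N) rec(i + 1, j, acc)
    if (j < M) rec(i, j + 1, acc)
    invisible(NULL)
  }
  rec(1, 1, 0)
  best
}

## Literal application of the flanker trimming rules, written directly from
## their statement: accuracy gate, drop incorrect, drop < 200 ms, drop
## > pooled mean + 2.5 SD, then condition means.
flanker_brute_force <- function(trials, accuracy_cutoff = 0.80,
                                anticipatory_ms = 200, sd_mult = 2.5) {
  included <- mean(trials$correct) >= accuracy_cutoff
  t1 <- trials[trials$correct, ]
  t2 <- t1[t1$rt_ms >= anticipatory_ms, ]
  cutoff <- mean(t2$rt_ms) + sd_mult * sd(t2$rt_ms)
  t3 <- if (is.na(cutoff)) t2 else t2[t2$rt_ms <= cutoff, ]
  cm <- function(cond) {
    v <- t3$rt_ms[t3$condition == cond]
    if (length(v)) mean(v) else NA_real_
  }
  list(conRT = cm("congruent"), incRT = cm("incongruent"),
       ic_effect = cm("incongruent") - cm("congruent"),
       included = included, n_retained = nrow(t3))
}

## Steiger (1980) Z via the Dunn & Clark covariance with the pooled
## correlation -- an algebraically independent route to the same statistic.
steiger_oracle <- function(r_jk, r_jh, r_kh, n) {
  rb <- (r_jk + r_jh) / 2
  cv <- (r_kh * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_kh^2)) /
    ((1 - rb^2)^2)
  sqrt(n - 3) * (atanh(r_jk) - atanh(r_jh)) / sqrt(2 - 2 * cv)
}

## True-score trial table: value = mu_i + noise, between-participant SD sb,
## within-participant SD sw, k parallel trials. Analytic reliability of the
## mean of a half is such that the corrected split-half reliability equals
## sb^2 / (sb^2 + sw^2 / k).
true_score_table <- function(n = 100, k = 8, sb = 1, sw = 1) {
  mu <- rnorm(n, 0, sb)
  data.frame(participant_id = rep(sprintf("p%03d", seq_len(n)), each = k),
             trial_unit_index = rep(seq_len(k), n),
             value = rep(mu, each = k) + rnorm(n * k, 0, sw))
}

## Pure-delay synthetic participant: no motor noise, no lapses; the plant is
## excited by seeded device jitter so the user series is an exactly delayed,
## scaled mirror of the stimulus.
pure_delay_trace <- function(d_samples, duration_s = 120, seed = 5,
                             mst = 4, disturbance_sd = 0.01) {
  ctrl <- controller_params(feedback_delay_s = d_samples / 30, gain = 1.1,
                            motor_noise_sd = 0, lapse_rate_hz = 0,
                            disturbance_sd = disturbance_sd, seed = seed)
  run_continuous(ctrl, mst = mst,
                 config = task_config(continuous_duration_s = duration_s))
}

## Trivariate normal sample with common correlation rho.
rmvn3 <- function(n, rho) {
  Sig <- matrix(rho, 3, 3)
  diag(Sig) <- 1
  matrix(rnorm(n * 3), n) %*% chol(Sig)
}

## Minimal hand-built trace data frame.
make_trace <- function(stim, user = -stim, rate = 30, id = "t1",
                       phase = "continuous") {
  n <- length(stim)
  structure(data.frame(participant_id = id, phase = phase,
                       sample_index = seq_len(n) - 1L,
                       t_sec = (seq_len(n) - 1L) / rate,
                       stim_x = stim, user_x = user,
                       lambda_val = 1, crash_flag = as.integer(abs(stim) >= 0.8)),
            class = c("cpcst_trace", "data.frame"))
}
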