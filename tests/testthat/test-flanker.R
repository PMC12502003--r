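flanker_rows <- function(rt, condition = "congruent", correct = TRUE) {
  data.frame(participant_id = "p1", block = 1L,
             trial_index = seq_along(rt),
             t_sec = seq_along(rt) * 1.7,
             condition = rep(condition, length.out = length(rt)),
             rt_ms = rt, correct = rep(correct, length.out = length(rt)))
}

test_that("anticipatory responses are trimmed before the condition mean", {
  tr <- flanker_rows(c(150, 400, 450))
  s <- suppressWarnings(trim_and_summarize(tr))  # only congruent trials supplied
  expect_equal(s$conRT, 425, tolerance = 1e-12)
  expect_identical(s$n_retained, 2L)
})

test_that("identical RTs survive the SD trim and give a null congruency effect", {
  tr <- rbind(flanker_rows(rep(500, 10), "congruent"),
              flanker_rows(rep(500, 10), "incongruent"),
              flanker_rows(rep(500, 10), "neutral"))
  s <- trim_and_summarize(tr)
  expect_identical(s$conRT, 500)
  expect_identical(s$incRT, 500)
  expect_identical(s$ic_effect, 0)
  expect_identical(s$n_retained, 30L)
})

test_that("a long outlier is cut at the pooled mean + 2.5 SD", {
  set.seed(5)
  rts <- c(runif(19, 400, 600), 5000)
  tr <- flanker_rows(rts, c("congruent", "incongruent"))
  s <- trim_and_summarize(tr)
  o <- flanker_brute_force(tr)
  expect_identical(s$n_retained, 19L)
  expect_equal(s$conRT, o$conRT, tolerance = 1e-12)
  expect_equal(s$incRT, o$incRT, tolerance = 1e-12)
})

test_that("the pipeline matches brute-force trimming on random trial tables", {
  set.seed(6)
  for (rep in 1:30) {
    n <- sample(30:80, 1)
    tr <- data.frame(participant_id = "p1", block = 1L, trial_index = 1:n,
                     t_sec = 1:n,
                     condition = sample(c("congruent", "incongruent", "neutral"),
                                        n, replace = TRUE),
                     rt_ms = c(runif(n - 3, 150, 900), runif(3, 900, 4000)),
                     correct = runif(n) < 0.9)
    s <- suppressWarnings(trim_and_summarize(tr))
    o <- flanker_brute_force(tr)
    expect_equal(s$conRT, o$conRT, tolerance = 1e-12)
    expect_equal(s$incRT, o$incRT, tolerance = 1e-12)
    expect_identical(s$included, o$included)
    expect_identical(s$n_retained, o$n_retained)
  }
})

test_that("the accuracy gate flags participants below 80%", {
  tr <- flanker_rows(rep(500, 10), correct = c(rep(TRUE, 7), rep(FALSE, 3)))
  s <- suppressWarnings(trim_and_summarize(tr))
  expect_false(s$included)
  expect_equal(s$accuracy, 0.7, tolerance = 1e-12)
})

test_that("trimming removes no more than the rules dictate", {
  ## with no trial beyond the recomputed cutoff, re-trimming changes nothing
  set.seed(9)
  tight <- rbind(flanker_rows(runif(60, 400, 600), "congruent"),
                 flanker_rows(runif(60, 400, 600), "incongruent"))
  s1 <- trim_and_summarize(tight)
  s2 <- trim_and_summarize(cpcst:::trimmed_trials(tight))
  expect_identical(s1$n_retained, nrow(tight))
  expect_identical(s2$n_retained, s1$n_retained)
  expect_equal(s2$conRT, s1$conRT, tolerance = 1e-12)

  ## on heavy-tailed data the single-pass rule keeps exactly the trials at
  ## or below its one pooled cutoff -- survivors of a re-application are a
  ## subset, dropped only for exceeding the recomputed cutoff
  tr <- simulate_flanker_cohort(1, seed = 9)
  kept <- cpcst:::trimmed_trials(tr)
  expect_true(all(kept$trial_index %in% tr$trial_index[tr$correct]))
  cutoff <- mean(kept$rt_ms) + 2.5 * sd(kept$rt_ms)
  kept2 <- cpcst:::trimmed_trials(kept)
  dropped <- setdiff(kept$trial_index, kept2$trial_index)
  expect_true(all(kept$rt_ms[kept$trial_index %in% dropped] > cutoff))

  ## the congruency effect is invariant to a constant shift of all RTs
  ## (when no trial crosses the anticipatory boundary)
  shifted <- tight
  shifted$rt_ms <- shifted$rt_ms + 250
  expect_equal(trim_and_summarize(shifted)$ic_effect, s1$ic_effect,
               tolerance = 1e-10)
})

test_that("generated cohorts are balanced, counterbalanced and reproducible", {
  t1 <- simulate_flanker_cohort(3, seed = 4)
  t2 <- simulate_flanker_cohort(3, seed = 4)
  expect_identical(t1, t2)
  for (id in unique(t1$participant_id)) {
    cond <- t1$condition[t1$participant_id == id]
    expect_true(all(table(cond) == 120L))
    trans <- table(head(cond, -1), tail(cond, -1))
    expect_lte(max(trans) - min(trans), 1)
  }
})

test_that("the deterministic limit reproduces the generating congruency effect", {
  spec <- flanker_spec(sigma_ms = 0, tau_ms = 0, participant_sd_ms = 0,
                       p_correct = c(congruent = 1, neutral = 1, incongruent = 1))
  tr <- simulate_flanker_cohort(3, spec, seed = 2)
  s <- flanker_summaries(tr)
  expect_equal(s$ic_effect, rep(60, 3), tolerance = 1e-12)
})

test_that("condition trial tables carry minutes for stability analyses", {
  tr <- simulate_flanker_cohort(4, seed = 12)
  tab <- flanker_trial_table(tr, "congruent")
  expect_true(all(tab$minute >= 1))
  expect_true(all(tab$value >= 200))
  cv <- stability_curve(tab, full_duration_min = 11)
  expect_equal(cv$r[11], 1, tolerance = 1e-12)
})
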