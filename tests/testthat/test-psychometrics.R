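test_that("Spearman-Brown closed form and monotonicity", {
  expect_identical(spearman_brown(1), 1)
  expect_identical(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.5), 2 / 3, tolerance = 1e-15)
  expect_error(spearman_brown(-1), "undefined")
  r <- seq(-0.95, 1, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0))
  expect_true(all(spearman_brown(seq(0, 1, 0.01)) >= 0 &
                    spearman_brown(seq(0, 1, 0.01)) <= 1))
})

test_that("split-half correlation on degenerate and null tables", {
  ## constant within participant, distinct across: halves identical, r = 1
  perf <- data.frame(participant_id = rep(letters[1:6], each = 4),
                     value = rep(c(1, 3, 5, 7, 9, 11), each = 4))
  set.seed(1)
  expect_equal(split_half_once(perf), 1, tolerance = 1e-12)
  ## i.i.d. noise with 2 trials each: corrected r near zero in expectation
  set.seed(2)
  ests <- replicate(200, {
    noise <- data.frame(participant_id = rep(sprintf("p%02d", 1:40), each = 2),
                        value = rnorm(80))
    split_half_once(noise)
  })
  expect_lt(abs(mean(ests)), 0.1)
  expect_error(split_half_once(data.frame(participant_id = c("a", "a", "b", "b"),
                                          value = 1:4)),
               "insufficient")
  expect_error(split_half_once(data.frame(participant_id = c("a", "b", "c"),
                                          value = 1:3)),
               "at least 2")
})

test_that("permutation split-half recovers the analytic true-score reliability", {
  set.seed(11)
  tab <- true_score_table(n = 100, k = 8, sb = 1, sw = 1)
  est <- split_half_reliability(tab, n_perm = 1000, seed = 12)
  expect_lt(abs(est - 8 / 9), 0.06)
})

test_that("bootstrap reliability: degeneracy, determinism, relabeling, trial-count ordering", {
  perf <- data.frame(participant_id = rep(letters[1:8], each = 4),
                     value = rep(seq(2, 16, by = 2), each = 4))
  est <- bootstrap_reliability(perf, n_boot = 50, n_perm = 10, seed = 3)
  expect_equal(est$point, 1, tolerance = 1e-12)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1), tolerance = 1e-12)

  set.seed(21)
  tab <- true_score_table(n = 60, k = 8)
  e1 <- bootstrap_reliability(tab, n_boot = 100, n_perm = 20, seed = 5)
  e2 <- bootstrap_reliability(tab, n_boot = 100, n_perm = 20, seed = 5)
  expect_identical(e1$boot_estimates, e2$boot_estimates)
  expect_true(e1$ci_low <= e1$point && e1$point <= e1$ci_high)

  ## invariance to relabeling of trial-unit indices (values unchanged)
  tab_rev <- tab[order(tab$participant_id, -tab$trial_unit_index), ]
  tab_rev$trial_unit_index <- tab$trial_unit_index
  e3 <- bootstrap_reliability(tab_rev, n_boot = 100, n_perm = 20, seed = 5)
  expect_lt(abs(e3$point - e1$point), 0.01)

  ## reliability grows with the trial count k
  set.seed(31)
  pts <- vapply(c(2, 8, 32), function(k)
    bootstrap_reliability(true_score_table(n = 80, k = k),
                          n_boot = 100, n_perm = 20, seed = 6)$point,
    numeric(1))
  expect_true(all(diff(pts) > 0))
})

test_that("iRT trial tables bin the latency series", {
  lat <- rep(c(0.1, 0.3), each = 30)        # two 1 s bins at 30 Hz
  tab <- irt_trial_table(lat, "p1", task_config(), bin_s = 1)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$value, c(0.1, 0.3), tolerance = 1e-15)
  expect_identical(tab$minute, c(1, 1))
})

test_that("stability curves end at unity and rise with more data", {
  ## constant distinct participant means: r = 1 at every truncation
  flat <- data.frame(participant_id = rep(letters[1:5], each = 6),
                     minute = rep(1:6, 5),
                     value = rep(c(1, 2, 3, 4, 5), each = 6))
  cv <- stability_curve(flat, 6)
  expect_equal(cv$r, rep(1, 6), tolerance = 1e-12)
  ## r at the full duration is 1 by construction
  set.seed(8)
  noisy <- data.frame(participant_id = rep(sprintf("p%02d", 1:30), each = 5),
                      minute = rep(1:5, 30),
                      value = rep(rnorm(30), each = 5) + rnorm(150, 0, 3))
  cvn <- stability_curve(noisy, 5)
  expect_equal(cvn$r[5], 1, tolerance = 1e-12)
  ## attenuation shrinks as the truncated mean converges (mean over cohorts)
  set.seed(9)
  K <- 5
  rbar <- rowMeans(replicate(60, {
    tab <- data.frame(participant_id = rep(sprintf("p%02d", 1:40), each = K),
                      minute = rep(1:K, 40),
                      value = rep(rnorm(40), each = K) + rnorm(40 * K, 0, 3))
    stability_curve(tab, K)$r
  }))
  expect_true(all(diff(rbar) > 0))
})

test_that("a participant missing early data is dropped pairwise with a warning", {
  tab <- data.frame(participant_id = rep(c("a", "b", "c", "d"), each = 3),
                    minute = rep(1:3, 4), value = rnorm(12))
  tab <- tab[!(tab$participant_id == "a" & tab$minute == 1), ]
  expect_warning(cv <- stability_curve(tab, 3), "pairwise")
  expect_identical(cv$n_pairs, c(3L, 4L, 4L))
})

test_that("Steiger's Z matches an independent formulation and behaves at its edges", {
  expect_identical(steiger_z(0.6, 0.6, 0.3, 100)$z, 0)
  expect_identical(steiger_z(0.6, 0.6, 0.3, 100)$p, 1)
  a <- steiger_z(0.8, 0.5, 0.4, 80)
  b <- steiger_z(0.5, 0.8, 0.4, 80)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_error(steiger_z(1, 0.5, 0.4, 80), "overflow|inside")
  expect_error(steiger_z(0.5, 0.5, 0.5, 3))
  set.seed(14)
  for (i in 1:50) {
    R <- cor(rmvn3(40, runif(1, -0.3, 0.7)))
    n <- sample(10:500, 1)
    expect_equal(steiger_z(R[1, 2], R[1, 3], R[2, 3], n)$z,
                 steiger_oracle(R[1, 2], R[1, 3], R[2, 3], n),
                 tolerance = 1e-10)
  }
})

test_that("stability-curve comparison flags dominated curves and survives r = 1", {
  cv <- structure(data.frame(minutes = 1:4, r = c(0.80, 0.85, 0.90, 0.95),
                             n_pairs = 150L),
                  class = c("cpcst_stability", "data.frame"))
  same <- compare_stability_curves(cv, cv, r_between = rep(0.5, 4), n = 150)
  expect_true(all(same$z == 0))
  expect_false(any(same$flagged))

  top <- cv; top$r <- rep(1, 4)                 # curve pinned at unity
  cmp <- compare_stability_curves(top, cv, r_between = rep(0.5, 4), n = 150)
  expect_true(all(cmp$flagged))

  tiny <- compare_stability_curves(
    structure(data.frame(minutes = 1, r = 0.9, n_pairs = 4L), class = c("cpcst_stability", "data.frame")),
    structure(data.frame(minutes = 1, r = 0.3, n_pairs = 4L), class = c("cpcst_stability", "data.frame")),
    r_between = 0.2, n = 4)
  expect_true(is.finite(tiny$z))

  expect_error(compare_stability_curves(cv, cv[1:3, ], rep(0.5, 4), 150),
               "grid")
  expect_error(compare_stability_curves(cv, cv, rep(0.5, 3), 150),
               "per minute")
})

test_that("reliability reports serialize to JSON", {
  perf <- data.frame(participant_id = rep(letters[1:6], each = 4),
                     value = rep(1:6, each = 4))
  est <- bootstrap_reliability(perf, n_boot = 20, n_perm = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_reliability_report(est, path, measure = "irt", seed = 2)
  rep_back <- jsonlite::read_json(path)
  expect_identical(rep_back$measure, "irt")
  expect_equal(rep_back$point, est$point, tolerance = 1e-12)
})
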