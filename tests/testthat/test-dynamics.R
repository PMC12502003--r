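test_that("plant fixed points: origin and exact counteraction", {
  cfg <- task_config()
  s0 <- plant_state(x = 0, lambda_val = 7)
  expect_identical(cst_step(s0, u = 0, cfg)$x, 0)
  s1 <- plant_state(x = 0.2, lambda_val = 5)
  expect_identical(cst_step(s1, u = -0.2, cfg)$x, 0.2)
})

test_that("open-loop growth matches the closed form to machine precision", {
  cfg <- task_config()
  dt <- 1 / cfg$sampling_rate_hz
  for (lam in c(1, 2, 5)) {
    expected <- 0.01 * (1 + lam * dt)^(1:40)
    n_free <- sum(expected < 1)       # clamping at the screen edge kicks in later
    s <- plant_state(x = 0.01, lambda_val = lam)
    xs <- numeric(n_free)
    for (n in seq_len(n_free)) {
      s <- cst_step(s, u = 0, cfg)
      xs[n] <- s$x
    }
    expect_equal(xs, expected[seq_len(n_free)], tolerance = 1e-12)
  }
})

test_that("first open-loop crash step matches the analytic ceiling", {
  cfg <- task_config()
  dt <- 1 / cfg$sampling_rate_hz
  ## x[n] = x0 (1 + lam dt)^n; crash at the first n with x >= 0.8
  for (lam in c(1, 2, 5)) {
    for (x0 in c(0.001, 0.01, 0.1)) {
      n_pred <- ceiling(log(cfg$crash_fraction / x0) / log(1 + lam * dt))
      s <- plant_state(x = x0, lambda_val = lam)
      n <- 0
      while (!detect_crash(s, cfg)) {
        s <- cst_step(s, u = 0, cfg)
        n <- n + 1
      }
      expect_identical(n, n_pred)
    }
  }
  ## the worked case: x0 = 0.01, lambda = 3 gives growth factor 1.1
  expect_identical(ceiling(log(80) / log(1.1)), 46)
})

test_that("crash detection is boundary-inclusive", {
  cfg <- task_config()
  expect_false(detect_crash(plant_state(x = 0.79), cfg))
  expect_true(detect_crash(plant_state(x = -0.80), cfg))
  expect_true(detect_crash(plant_state(x = 0.81), cfg))
})

test_that("non-finite state or input is rejected", {
  cfg <- task_config()
  expect_error(cst_step(plant_state(0.1), u = NaN, cfg), "finite")
  expect_error(cst_step(plant_state(0.1), u = Inf, cfg), "finite")
  expect_error(plant_state(x = NA_real_))
})

test_that("continuous phase: length, lambda, determinism, crash flags", {
  cfg <- task_config(continuous_duration_s = 60)
  ctrl <- controller_params(feedback_delay_s = 0.2, seed = 11)
  tr <- run_continuous(ctrl, mst = 2.0, cfg)
  expect_identical(nrow(tr), 60L * 30L)
  expect_true(all(tr$lambda_val == 0.6))  # 30% of MST, held throughout
  expect_identical(tr$crash_flag, as.integer(abs(tr$stim_x) >= 0.8))
  tr2 <- run_continuous(ctrl, mst = 2.0, cfg)
  expect_identical(tr, tr2)
  expect_error(run_continuous(ctrl, mst = 0, cfg), "positive")
  expect_error(run_continuous(ctrl, mst = -1, cfg), "positive")
})

test_that("a perfect mirroring controller keeps a centered stimulus at zero", {
  cfg <- task_config(continuous_duration_s = 5, x_start_offset = 0)
  ctrl <- controller_params(feedback_delay_s = 0, gain = 1, motor_noise_sd = 0,
                            lapse_rate_hz = 0, disturbance_sd = 0, seed = 1)
  tr <- run_continuous(ctrl, mst = 5, cfg)
  expect_true(all(tr$stim_x == 0))
  expect_true(all(tr$user_x == 0))
  expect_identical(sum(tr$crash_flag), 0L)
})

test_that("engine trace equals stepwise composition of cst_step", {
  cfg <- task_config(continuous_duration_s = 3)
  ctrl <- controller_params(feedback_delay_s = 0.1, gain = 1.2,
                            motor_noise_sd = 0, lapse_rate_hz = 0,
                            disturbance_sd = 0, seed = 1)
  tr <- run_continuous(ctrl, mst = 4, cfg)
  s <- plant_state(x = cfg$x_start_offset, lambda_val = cfg$mst_fraction * 4)
  d <- round(0.1 * cfg$sampling_rate_hz)
  for (n in seq_len(nrow(tr) - 1)) {
    u <- if (n <= d) 0 else -1.2 * tr$stim_x[n - d]
    expect_equal(tr$user_x[n], max(-1, min(1, u)), tolerance = 1e-12)
    s <- cst_step(s, tr$user_x[n], cfg)
    expect_equal(tr$stim_x[n + 1], s$x, tolerance = 1e-12)
  }
})

test_that("the two control-sign conventions generate the same stimulus path", {
  ctrl <- controller_params(feedback_delay_s = 0.2, seed = 21)
  tr_plus <- run_continuous(ctrl, mst = 4,
                            task_config(continuous_duration_s = 30))
  tr_minus <- run_continuous(ctrl, mst = 4,
                             task_config(continuous_duration_s = 30,
                                         control_sign = "minus"))
  expect_equal(tr_plus$stim_x, tr_minus$stim_x, tolerance = 1e-15)
  expect_equal(tr_plus$user_x, -tr_minus$user_x, tolerance = 1e-15)
})

test_that("trace CSV round-trips through the long dialect", {
  tr <- run_continuous(controller_params(seed = 3), mst = 3,
                       task_config(continuous_duration_s = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "participant_id,phase,sample_index,t_sec,stim_x,user_x,lambda_val,crash_flag")
  rt <- read_trace(path)
  expect_equal(rt$stim_x, tr$stim_x, tolerance = 1e-12)
  expect_identical(rt$crash_flag, tr$crash_flag)
})

test_that("task configuration round-trips through the key/value file", {
  cfg <- task_config(lambda_ramp_rate = 0.35, mst_fraction = 0.25)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_task_config(cfg, path)
  cfg2 <- read_task_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  writeLines(c("sampling_rate_hz = 30", "bogus_key = 1"), path)
  expect_error(read_task_config(path), "unknown configuration key")
})
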