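test_that("prime dilution of perfusate hemoglobin", {
  expect_equal(dilution_hb(14, 1200, 0, 0), 14)
  expect_equal(dilution_hb(14, 1200, 500, 100), 14 * 1200 / 1800)
  expect_equal(dilution_hb(14, 1200, 500, 100), 9.33, tolerance = 1e-2)
  expect_equal(dilution_hb(0, 1200, 500, 100), 0)
  expect_error(dilution_hb(14, 0, 500, 100), "blood_volume")
})

test_that("noise-free simulation round-trips the Fick relation exactly", {
  cfg <- noise_free_config(seed = 7)
  log <- simulate_run(cfg, perfusion_settings(cbf_setting = 700))
  s <- add_samples_from_log(perfusion_session(male80()), log)
  truth <- attr(log, "truth")
  expect_equal(truth$true_mvo2, 34.056)        # 0.10 ml/min/g * 340.56 g
  expect_equal(s$snapshots$mvo2, rep(34.056, nrow(s$snapshots)),
               tolerance = 1e-6)
})

test_that("identical seeds reproduce byte-identical sample logs", {
  cfg <- synthetic_run_config(male80(), seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sample_log(simulate_run(cfg), f1)
  write_sample_log(simulate_run(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different run
  f3 <- tempfile(fileext = ".csv")
  write_sample_log(simulate_run(synthetic_run_config(male80(), seed = 43)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_run(synthetic_run_config(male80(), seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("scenario shapes the lactate trajectory", {
  viable <- simulate_run(noise_free_config(seed = 2, scenario = "viable"))
  lac_v <- viable$lactate_mmol_l[viable$site == "arterial"]
  t_v <- viable$time_min[viable$site == "arterial"]
  expect_true(all(diff(lac_v[t_v >= 60]) <= 0))   # non-increasing after 1 h
  expect_true(all(lac_v >= 1.5))
  failing <- simulate_run(noise_free_config(seed = 2, scenario = "failing"))
  lac_f <- failing$lactate_mmol_l[failing$site == "arterial"]
  expect_gt(lac_f[length(lac_f)], lac_f[1])
  expect_equal(max(lac_f), 8, tolerance = 1e-6)
})

test_that("generated venous content never exceeds arterial content", {
  for (seed in c(1, 23, 456)) {
    log <- simulate_run(synthetic_run_config(male80(), seed = seed))
    a <- log[log$site == "arterial", ]; v <- log[log$site == "venous", ]
    ca <- oxygen_content(a$hb_g_dl, a$so2, a$po2_mmhg)
    cv <- oxygen_content(v$hb_g_dl, v$so2, v$po2_mmhg)
    expect_true(all(cv <= ca))
  }
})

test_that("an infeasible oxygen budget is refused, naming the bound", {
  cfg <- synthetic_run_config(male80(), true_mvo2_per_gram = 0.13,
                              perfusate_hb = 1, seed = 1)
  expect_error(simulate_run(cfg, perfusion_settings(cbf_setting = 100)),
               "exceeds")
  expect_error(synthetic_run_config(male80(), duration = 10,
                                    sampling_interval = 12),
               "twice the sampling interval")
})

test_that("pipeline recovers the true consumption from a noisy run", {
  cfg <- synthetic_run_config(male80(), duration = 240, sampling_interval = 12,
                              measurement_noise_sd = 0.03, seed = 42)
  log <- simulate_run(cfg)
  s <- add_samples_from_log(perfusion_session(male80()), log)
  expect_equal(nrow(s$snapshots), 20)
  truth <- attr(log, "truth")$true_mvo2
  expect_lt(abs(mean(s$snapshots$mvo2) - truth) / truth, 0.05)
})

test_that("estimated and measured recommendation pathways agree on noise-free data", {
  cfg <- noise_free_config(seed = 11)
  log <- simulate_run(cfg)
  s <- add_samples_from_log(perfusion_session(male80()), log)
  a1 <- log[log$site == "arterial", ][1, ]
  base <- personalize_cbf(male80(), a1$hb_g_dl, a1$so2, a1$po2_mmhg)
  for (i in seq_len(nrow(s$snapshots))) {
    upd <- recalibrate_cbf(s$snapshots[i, ], male80())
    expect_lt(abs(upd$recommended_cbf - base$recommended_cbf), 1)
  }
})
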