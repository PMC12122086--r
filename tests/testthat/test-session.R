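test_that("unit normalization at ingestion: percent saturation, mmol/L hemoglobin", {
  s <- perfusion_session(male80())
  s <- ingest_sample(s, list(time = 0, site = "arterial", po2 = 350,
                             so2 = 98, hb = 5.6),
                     unit_hints = list(hb = "mmol_l"))
  expect_equal(s$samples$so2, 0.98)              # percent -> fraction when > 1
  expect_equal(s$samples$hb, 5.6 * 1.6113)       # 9.02 g/dL
  expect_equal(s$samples$hb, 9.02, tolerance = 1e-2)
  # out-of-range after conversion is an input error
  expect_error(ingest_sample(s, list(time = 10, site = "arterial", po2 = 350,
                                     so2 = 120, hb = 9),
                             unit_hints = list(so2 = "fraction")),
               "so2")
})

test_that("unit conversions round-trip to numerical identity", {
  hb <- c(3.1, 5.6, 9.9)
  expect_equal(hb * 1.6113 / 1.6113, hb, tolerance = 1e-12)
  pct <- c(48, 98, 100)
  expect_equal((pct / 100) * 100, pct, tolerance = 1e-12)
})

test_that("pairing within tolerance creates a midpoint snapshot", {
  s <- perfusion_session(male80())
  s <- ingest_sample(s, baseline_arterial(60))
  expect_equal(nrow(s$snapshots), 0)
  s <- ingest_sample(s, blood_gas_sample(62, "venous", 120, 0.48, 9))
  expect_equal(nrow(s$snapshots), 1)
  expect_equal(s$snapshots$time, 61)            # midpoint of 60 and 62
  # beyond tolerance: no pairing
  s <- ingest_sample(s, baseline_arterial(90))
  s <- ingest_sample(s, blood_gas_sample(96, "venous", 120, 0.48, 9))
  expect_equal(nrow(s$snapshots), 1)
})

test_that("duplicate samples are rejected and ingestion is idempotent", {
  s <- perfusion_session(male80())
  s <- ingest_sample(s, baseline_arterial(0))
  expect_error(ingest_sample(s, baseline_arterial(0)),
               class = "eshp_duplicate_error")
  # re-ingesting an identical log leaves the serialized state unchanged
  cfg <- noise_free_config(seed = 3)
  log <- simulate_run(cfg)
  s1 <- add_samples_from_log(perfusion_session(male80()), log)
  s2 <- suppressWarnings(add_samples_from_log(s1, log))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_session(s1, f1); write_session(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("snapshot derivation matches the hand-computed pair", {
  snap <- compute_snapshot(baseline_arterial(60), baseline_venous(60),
                           perfusion_settings(cbf_setting = 700,
                                              mean_aortic_pressure = 75))
  expect_equal(snap$cao2, 13.145)
  expect_equal(snap$cvo2, 6.1608)
  expect_equal(snap$mvo2, 48.89, tolerance = 1e-3)
  expect_equal(snap$mdo2, 700 * 13.145 / 100)
  expect_equal(snap$delta_po2, 230)
  expect_equal(snap$cvr, 75 / 700)
  expect_equal(snap$lactate, 3.0)              # carried from the arterial side
  expect_false(snap$negative_extraction)
})

test_that("degenerate and swapped pairs are flagged, not hidden", {
  a <- baseline_arterial(10)
  # identical arterial and venous values: zero extraction everywhere
  v_same <- blood_gas_sample(10, "venous", a$po2, a$so2, a$hb)
  snap <- compute_snapshot(a, v_same)
  expect_equal(snap$mvo2, 0)
  expect_equal(snap$meo2, 0)
  expect_equal(snap$delta_po2, 0)
  # venous saturation above arterial: negative extraction flag
  v_hi <- blood_gas_sample(10, "venous", 400, 1.0, 9)
  snap2 <- compute_snapshot(a, v_hi)
  expect_true(snap2$negative_extraction)
  expect_true(snap2$mvo2 < 0)
})

test_that("snapshot conservation holds across a whole simulated session", {
  log <- simulate_run(synthetic_run_config(male80(), seed = 21))
  s <- add_samples_from_log(perfusion_session(male80()), log)
  sn <- s$snapshots
  expect_gt(nrow(sn), 0)
  resid <- sn$mdo2 - sn$mvo2 - sn$cbf_used * sn$cvo2 / 100
  expect_true(all(abs(resid) <= 1e-9 * pmax(sn$mdo2, 1)))
})

test_that("snapshots use the pump setting active at their time", {
  s <- perfusion_session(male80())   # default pump 750 ml/min
  s <- set_settings(s, 30, cbf_ml_min = 600)
  s <- ingest_sample(s, baseline_arterial(10))
  s <- ingest_sample(s, baseline_venous(10))
  s <- ingest_sample(s, baseline_arterial(40))
  s <- ingest_sample(s, baseline_venous(40))
  expect_equal(s$snapshots$cbf_used, c(750, 600))
  expect_equal(s$snapshots$mvo2, c(750, 600) * (13.145 - 6.1608) / 100)
})

test_that("lactate trend classification by least-squares slope", {
  mk <- function(times, lac) {
    s <- perfusion_session(male80())
    for (i in seq_along(times)) {
      s <- ingest_sample(s, blood_gas_sample(times[i], "arterial", 350, 1, 9,
                                             lactate = lac[i]))
    }
    s
  }
  expect_equal(lactate_trend(mk(c(0, 60, 120), c(3.0, 2.5, 2.0)))$direction,
               "falling")
  tr <- lactate_trend(mk(c(0, 60, 120), c(2.0, 2.0, 2.0)))
  expect_equal(tr$direction, "stable")
  expect_equal(tr$slope_per_h, 0)
  tr2 <- lactate_trend(mk(c(0, 60, 120, 180), c(2, 4, 6, 8)))
  expect_equal(tr2$direction, "rising")
  expect_equal(tr2$slope_per_h, 2)             # least-squares slope, mmol/L/h
  # fewer than three points: direction absent
  expect_true(is.na(lactate_trend(mk(c(0, 60), c(2, 3)))$direction))
})

test_that("electrolyte advisories fire only outside the configured bounds", {
  ok <- blood_gas_sample(0, "arterial", 350, 1, 9, ionized_ca = 1.25,
                         hco3 = 24, k = 4.2)
  expect_equal(nrow(advise_electrolytes(ok)), 0)
  low_ca <- blood_gas_sample(0, "arterial", 350, 1, 9, ionized_ca = 0.9)
  adv <- advise_electrolytes(low_ca)
  expect_equal(adv$analyte, "ionized_calcium")
  expect_equal(adv$threshold_low, 1.1)
  low_bic <- blood_gas_sample(0, "arterial", 350, 1, 9, hco3 = 18)
  expect_equal(advise_electrolytes(low_bic)$analyte, "bicarbonate")
  # acidosis triggers the bicarbonate advisory even with bicarbonate absent
  acidotic <- blood_gas_sample(0, "arterial", 350, 1, 9, ph = 7.25)
  expect_equal(advise_electrolytes(acidotic)$analyte, "bicarbonate")
  hyperk <- blood_gas_sample(0, "arterial", 350, 1, 9, k = 6.0)
  expect_equal(advise_electrolytes(hyperk)$analyte, "potassium")
  # all three at once
  bad <- blood_gas_sample(0, "arterial", 350, 1, 9, ionized_ca = 0.9,
                          hco3 = 18, k = 3.0)
  expect_equal(nrow(advise_electrolytes(bad)), 3)
})

test_that("pairing totality: alternating samples at equal cadence all pair", {
  s <- perfusion_session(male80())
  for (t in seq(0, 180, by = 20)) {
    s <- ingest_sample(s, baseline_arterial(t))
    s <- ingest_sample(s, blood_gas_sample(t + 2, "venous", 120, 0.48, 9))
  }
  expect_equal(nrow(s$snapshots), 10)          # one snapshot per complete pair
  expect_true(all(diff(s$snapshots$time) > 0))
})
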