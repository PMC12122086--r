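test_that("unnormalized required flow matches hand evaluations", {
  expect_equal(cbf_unnormalized(100, 12.5), 100)
  expect_equal(cbf_unnormalized(340.56, 13.145), 340.56 / 13.145 * 12.5)
  expect_equal(cbf_unnormalized(340.56, 13.145), 323.87, tolerance = 1e-4)
  expect_equal(cbf_unnormalized(255.31, 13.145), 242.79, tolerance = 1e-4)
  expect_error(cbf_unnormalized(300, 0), "cao2")
})

test_that("required flow at mid-range physiologic inputs lands near 350 ml/min", {
  # typical donor on the machine: male ~80 kg, diluted perfusate Hb ~9,
  # saturated, hyperoxic PaO2 ~350 -> equilibrium flow in the physiologic
  # 300-400 ml/min band, well below the 700-800 protocol flow
  x_mid <- cbf_unnormalized(estimate_heart_weight("male", 80),
                            oxygen_content(9, 1.0, 350))
  expect_gte(x_mid, 300)
  expect_lte(x_mid, 400)
})

test_that("personalized recommendation reproduces the worked example", {
  rec <- personalize_cbf(male80(), hb = 9, so2 = 1.0, po2 = 350)
  expect_s3_class(rec, "cbf_recommendation")
  expect_equal(rec$heart_weight_used, 340.56)
  expect_equal(rec$unnormalized_cbf, 323.8494, tolerance = 1e-6)
  expect_equal(rec$normalized_fraction, (323.8494 - 178) / 431, tolerance = 1e-6)
  expect_equal(rec$recommended_cbf, 601.5, tolerance = 1e-3)
  expect_false(rec$clamped)
  expect_equal(recommendation_display(rec), 600L)
})

test_that("normalization anchors map exactly onto the window bounds", {
  # x at the sex minimum -> floor; x at min + range -> ceiling; neither clamped
  cst <- normalization_constants()
  # drive x just inside the anchors analytically via cao2 (so2 = 1, po2 = 0);
  # landing a hair inside keeps the clamp flag deterministic under rounding
  x_floor <- cst$female_min * (1 + 1e-9)
  hb_f <- 255.31 * 12.5 / x_floor / 1.34
  rec <- personalize_cbf(donor_profile("female", 70), hb_f, 1.0, 0)
  expect_equal(rec$recommended_cbf, 500, tolerance = 1e-5)
  expect_false(rec$clamped)
  x_ceil <- (cst$male_min + cst$male_range) * (1 - 1e-9)  # just under 609
  hb_m <- 340.56 * 12.5 / x_ceil / 1.34
  rec2 <- personalize_cbf(male80(), hb_m, 1.0, 0)
  expect_equal(rec2$recommended_cbf, 800, tolerance = 1e-5)
  expect_false(rec2$clamped)
})

test_that("measured heart weight overrides the estimate", {
  d <- donor_profile("female", 70, measured_heart_weight = 300)
  expect_equal(heart_weight(d), 300)
  rec <- personalize_cbf(d, 9, 1.0, 350)
  expect_equal(rec$heart_weight_used, 300)
  expect_equal(rec$unnormalized_cbf, cbf_unnormalized(300, 13.145))
})

test_that("closed-form normalization agrees with the brute-force oracle", {
  set.seed(99)
  cst <- normalization_constants()
  x <- runif(10000, -200, 1500)
  for (sex in c("female", "male")) {
    m <- if (sex == "female") cst$female_min else cst$male_min
    r <- if (sex == "female") cst$female_range else cst$male_range
    oracle <- piecewise_normalize(x, m, r)
    got <- eshpflow:::normalize_cbf(x, sex, cst)$recommended
    expect_true(all(abs(got - oracle) <= 1e-12))
  }
})

test_that("unclamped recommendations invert back to the required flow", {
  set.seed(5)
  cst <- normalization_constants()
  x <- runif(500, cst$male_min, cst$male_min + cst$male_range)
  nz <- eshpflow:::normalize_cbf(x, "male", cst)
  expect_true(all(!nz$clamped))
  x_back <- cst$male_min + cst$male_range *
    (nz$recommended - cst$offset) / cst$scale
  expect_true(all(abs(x_back - x) <= 1e-9 * abs(x)))
})

test_that("recommendation is monotone in oxygen content and body weight", {
  hb <- seq(5, 15, by = 0.5)
  rec_hb <- personalize_cbf(male80(), hb, 0.95, 250)$recommended_cbf
  expect_true(all(diff(rec_hb) <= 0))
  so2 <- seq(0.7, 1.0, by = 0.01)
  rec_so2 <- personalize_cbf(male80(), 9, so2, 250)$recommended_cbf
  expect_true(all(diff(rec_so2) <= 0))
  po2 <- seq(100, 500, by = 20)
  rec_po2 <- personalize_cbf(male80(), 9, 0.95, po2)$recommended_cbf
  expect_true(all(diff(rec_po2) <= 0))
  bw <- seq(40, 140, by = 5)
  rec_bw <- vapply(bw, function(b)
    personalize_cbf(donor_profile("male", b), 9, 0.95, 250)$recommended_cbf,
    numeric(1))
  expect_true(all(diff(rec_bw) >= 0))
})

test_that("serial recalibration from measured consumption", {
  d <- male80()
  # consistency: measured MVO2 equal to the prior assumption reproduces the
  # baseline recommendation
  snap <- list(time = 60, mvo2 = 340.56 * 0.10, cao2 = 13.145)
  rec_m <- recalibrate_cbf(snap, d)
  rec_e <- personalize_cbf(d, 9, 1.0, 350)
  expect_equal(rec_m$recommended_cbf, rec_e$recommended_cbf, tolerance = 1e-12)
  expect_equal(rec_m$basis, "measured_mvo2")

  # hand-computed update at a lower measured consumption
  rec25 <- recalibrate_cbf(list(time = 90, mvo2 = 25, cao2 = 13.145), d)
  expect_equal(rec25$unnormalized_cbf, 237.7, tolerance = 1e-3)
  expect_equal(rec25$recommended_cbf, 541.6, tolerance = 1e-3)

  # zero consumption clamps onto the floor
  rec0 <- recalibrate_cbf(list(time = 10, mvo2 = 0, cao2 = 13.145), d)
  expect_equal(rec0$recommended_cbf, 500)
  expect_true(rec0$clamped)

  # negative consumption withholds the recommendation with a diagnostic
  expect_warning(
    out <- recalibrate_cbf(list(time = 10, mvo2 = -5, cao2 = 13.145), d),
    "withheld")
  expect_null(out)
})

test_that("display rounding goes to the nearest 10 ml/min", {
  expect_identical(recommendation_display(601.5), 600L)
  expect_identical(recommendation_display(541.6), 540L)
  expect_identical(recommendation_display(800.0), 800L)
  expect_identical(recommendation_display(547), 550L)
})
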