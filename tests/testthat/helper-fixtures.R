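# Shared fixtures: a typical 80 kg male donor whose heart weight estimate is
# 340.56 g, and the corresponding baseline blood gas (diluted perfusate
# hemoglobin 9 g/dL, fully saturated, hyperoxic PO2 350 -> CaO2 13.145).

male80 <- function() donor_profile("male", 80)
female70 <- function() donor_profile("female", 70)

baseline_arterial <- function(time = 0) {
  blood_gas_sample(time, "arterial", po2 = 350, so2 = 1.0, hb = 9,
                   lactate = 3.0)
}

# venous counterpart with measured extraction ~0.53 at CBF 700
baseline_venous <- function(time = 0) {
  blood_gas_sample(time, "venous", po2 = 120, so2 = 0.48, hb = 9)
}

noise_free_config <- function(donor = male80(), seed = 7, ...) {
  synthetic_run_config(donor, measurement_noise_sd = 0, arterial_po2_sd = 0,
                       seed = seed, ...)
}

# Independent brute-force implementation of the clamped min-max
# normalization, used as the oracle for the closed-form path.
piecewise_normalize <- function(x, sex_min, sex_range, offset = 500, scale = 300) {
  vapply(x, function(xi) {
    f <- (xi - sex_min) / sex_range
    if (f < 0) offset
    else if (f > 1) offset + scale
    else offset + scale * f
  }, numeric(1))
}
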