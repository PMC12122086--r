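#' Hemodilution of the perfusate prime
#'
#' The machine perfusate is donor blood diluted by the crystalloid prime and
#' albumin: `hb_perfusate = hb_donor * V_blood / (V_blood + V_crystalloid +
#' V_albumin)`. At the protocol minimum prime (1200 ml blood, 500 ml
#' crystalloid, 100 ml albumin) a 14 g/dL donor dilutes to ~9.3 g/dL.
#'
#' @param donor_hb Donor hemoglobin, g/dL.
#' @param blood_volume Donor blood volume in the circuit, ml, > 0.
#' @param crystalloid,albumin Prime volumes, ml, >= 0.
#' @return Perfusate hemoglobin, g/dL.
#' @export
#' @examples
#' dilution_hb(14, 1200, 500, 100)  # ~9.33
dilution_hb <- function(donor_hb, blood_volume, crystalloid = 500, albumin = 100) {
  stopifnot(is.numeric(donor_hb), is.numeric(blood_volume))
  if (any(!is.finite(c(donor_hb, blood_volume, crystalloid, albumin))) ||
      any(c(crystalloid, albumin) < 0) || any(donor_hb < 0)) {
    stop("volumes must be finite and non-negative", call. = FALSE)
  }
  if (any(blood_volume <= 0)) stop("blood_volume must be > 0 ml", call. = FALSE)
  donor_hb * blood_volume / (blood_volume + crystalloid + albumin)
}

#' Configuration of a synthetic perfusion run
#'
#' States the ground truth of a simulated machine-perfusion session: the
#' donor, the sampling plan, the true per-gram oxygen consumption the venous
#' values are constructed to encode, the perfusate composition, measurement
#' noise and the lactate scenario. Defaults describe a standard run: a 4 h
#' perfusion sampled every 12 minutes, perfusate hemoglobin at the protocol
#' minimum prime (~9.33 g/dL), hyperoxic arterial PO2 around 350 mmHg
#' (85% oxygen sweep gas), consumption 0.10 ml/min/g, 3% analyzer noise.
#'
#' @param donor A [donor_profile()].
#' @param duration Run length, minutes; must be at least
#'   `2 * sampling_interval`. Default 240.
#' @param sampling_interval Minutes between arterial/venous sample pairs.
#'   Default 12.
#' @param true_mvo2_per_gram Ground-truth consumption, ml O2/min per gram.
#'   Default 0.10.
#' @param perfusate_hb Perfusate hemoglobin, g/dL. Default
#'   `dilution_hb(14, 1200, 500, 100)`.
#' @param arterial_po2_mean,arterial_po2_sd Latent arterial PO2 distribution,
#'   mmHg. Defaults 350 and 25 (between-sample oxygenator drift; set the sd
#'   to 0 for a constant-PO2 run).
#' @param measurement_noise_sd Fractional (multiplicative) analyzer noise
#'   applied to measured saturation, PO2 and hemoglobin. Default 0.03.
#' @param scenario `"viable"` (lactate decays 3.0 toward 1.5 mmol/L) or
#'   `"failing"` (lactate rises linearly 2.0 to 8.0 over the run).
#' @param seed Integer seed; identical seeds reproduce identical runs.
#' @return An object of class `synthetic_run_config`.
#' @export
synthetic_run_config <- function(donor, duration = 240, sampling_interval = 12,
                                 true_mvo2_per_gram = 0.10,
                                 perfusate_hb = dilution_hb(14, 1200, 500, 100),
                                 arterial_po2_mean = 350, arterial_po2_sd = 25,
                                 measurement_noise_sd = 0.03,
                                 scenario = c("viable", "failing"),
                                 seed = 1L) {
  stopifnot(inherits(donor, "donor_profile"))
  scenario <- match.arg(scenario)
  if (!is.finite(duration) || !is.finite(sampling_interval) ||
      sampling_interval <= 0 || duration < 2 * sampling_interval) {
    stop("duration must be at least twice the sampling interval", call. = FALSE)
  }
  if (!is.finite(measurement_noise_sd) || measurement_noise_sd < 0) {
    stop("measurement_noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.finite(true_mvo2_per_gram) || true_mvo2_per_gram <= 0) {
    stop("true_mvo2_per_gram must be > 0", call. = FALSE)
  }
  if (!is.finite(perfusate_hb) || perfusate_hb <= 0) {
    stop("perfusate_hb must be > 0 g/dL", call. = FALSE)
  }
  if (!is.finite(arterial_po2_sd) || arterial_po2_sd < 0) {
    stop("arterial_po2_sd must be >= 0", call. = FALSE)
  }
  structure(list(donor = donor, duration = duration,
                 sampling_interval = sampling_interval,
                 true_mvo2_per_gram = true_mvo2_per_gram,
                 perfusate_hb = perfusate_hb,
                 arterial_po2_mean = arterial_po2_mean,
                 arterial_po2_sd = arterial_po2_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 scenario = scenario, seed = as.integer(seed)),
            class = "synthetic_run_config")
}

# Crude monotone venous saturation -> tension lookup (pseudo-dissociation
# shape; not a physiologic ODC — see the methods vignette). Used only to
# assign a venous PO2 consistent with the venous content the oxygen budget
# dictates, and its inverse direction when solving for saturation.
.sat_po2_table <- data.frame(
  so2 = c(0, 0.10, 0.25, 0.50, 0.60, 0.75, 0.85, 0.90, 0.95, 0.97, 0.99, 1.00),
  po2 = c(1, 10, 18, 27, 32, 40, 50, 60, 80, 100, 150, 250))

po2_from_so2 <- function(so2) {
  stats::approx(.sat_po2_table$so2, .sat_po2_table$po2, xout = so2,
                rule = 2)$y
}

# Solve 1.34*hb*s + 0.0031*po2(s) = content for s; monotone, so uniroot.
solve_venous_so2 <- function(content, hb, params) {
  f <- function(s) params$huefner * hb * s +
    params$dissolved_coeff * po2_from_so2(s) - content
  if (f(1) < 0) stop("venous content exceeds fully saturated content", call. = FALSE)
  if (f(0) >= 0) return(0)
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

viable_lactate <- function(t) 1.5 + 1.5 * exp(-t / 90)
failing_lactate <- function(t, duration) 2 + 6 * t / duration

#' Simulate a synthetic machine-perfusion run
#'
#' Generates the blood-gas sample log of an ex situ perfusion session with a
#' known ground truth. At each sampling time an arterial sample (hyperoxic
#' PO2, near-saturated hemoglobin at the diluted perfusate concentration) and
#' a venous sample are emitted; the venous saturation/PO2 are back-computed
#' from the oxygen budget so that the Fick consumption at the pump flow
#' equals `true_mvo2_per_gram * heart_weight` exactly in the latent truth.
#' Analyzer noise is applied multiplicatively to the measured saturation,
#' PO2 and hemoglobin afterwards, so noise never violates conservation in the
#' latent run. Lactate follows the scenario; electrolytes hover near normal
#' with occasional below-threshold excursions so the advisory path is
#' exercised.
#'
#' The run errors out (naming the bound) if the requested consumption exceeds
#' the oxygen delivery at the given flow — a physically impossible request.
#'
#' @param config A [synthetic_run_config()].
#' @param settings [perfusion_settings()] of the simulated pump.
#' @return Data frame in the sample-log schema (see [write_sample_log()]),
#'   with attributes `truth` (list: `true_mvo2`, `heart_weight`,
#'   `true_cvo2_mean`) describing the ground truth.
#' @export
#' @examples
#' cfg <- synthetic_run_config(donor_profile("male", 80), seed = 42,
#'                             measurement_noise_sd = 0)
#' log <- simulate_run(cfg)
#' head(log)
simulate_run <- function(config, settings = perfusion_settings()) {
  stopifnot(inherits(config, "synthetic_run_config"),
            inherits(settings, "perfusion_settings"))
  # private RNG stream: never clobbers the caller's
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  params <- oxygen_parameters()
  hw <- heart_weight(config$donor)
  true_mvo2 <- config$true_mvo2_per_gram * hw
  cbf <- settings$cbf_setting
  times <- seq(config$sampling_interval, config$duration,
               by = config$sampling_interval)
  n <- length(times)

  so2_a_lat <- 0.997   # near-saturated at hyperoxic PO2
  hb_lat <- config$perfusate_hb
  po2_a_lat <- pmax(100, stats::rnorm(n, config$arterial_po2_mean,
                                      config$arterial_po2_sd))
  cao2_lat <- oxygen_content(hb_lat, so2_a_lat, po2_a_lat, params)
  delivery <- mdo2(cbf, cao2_lat)
  if (any(true_mvo2 > delivery)) {
    stop(sprintf(paste0("infeasible oxygen budget: true MVO2 %.1f ml/min exceeds ",
                        "delivery %.1f ml/min at CBF %.0f ml/min"),
                 true_mvo2, min(delivery), cbf), call. = FALSE)
  }
  cvo2_lat <- cao2_lat - 100 * true_mvo2 / cbf
  so2_v_lat <- vapply(cvo2_lat, solve_venous_so2, numeric(1),
                      hb = hb_lat, params = params)
  po2_v_lat <- po2_from_so2(so2_v_lat)

  noisy <- function(x, lo = 0, hi = Inf) {
    if (config$measurement_noise_sd == 0) return(pmin(pmax(x, lo), hi))
    pmin(pmax(x * (1 + stats::rnorm(length(x), 0, config$measurement_noise_sd)),
              lo), hi)
  }
  po2_a <- noisy(po2_a_lat, lo = 1)
  so2_a <- noisy(rep(so2_a_lat, n), hi = 1)
  hb_a <- noisy(rep(hb_lat, n))
  po2_v <- noisy(po2_v_lat, lo = 1)
  so2_v <- noisy(so2_v_lat, hi = 1)
  hb_v <- noisy(rep(hb_lat, n))
  # generator-side constraint: measured venous content never exceeds arterial
  over <- oxygen_content(hb_v, so2_v, po2_v, params) >
    oxygen_content(hb_a, so2_a, po2_a, params)
  so2_v[over] <- pmin(so2_v[over], so2_a[over] * 0.98)
  hb_v[over] <- pmin(hb_v[over], hb_a[over])

  lac <- switch(config$scenario,
                viable = viable_lactate(times),
                failing = failing_lactate(times, config$duration))
  ica <- stats::rnorm(n, 1.22, 0.04)
  hco3 <- stats::rnorm(n, 24, 0.8)
  kv <- stats::rnorm(n, 4.3, 0.15)
  ph <- stats::rnorm(n, 7.38, 0.02)
  # occasional excursions below the advisory thresholds
  dip <- stats::runif(n) < 0.08
  ica[dip] <- stats::runif(sum(dip), 0.90, 1.05)
  dip2 <- stats::runif(n) < 0.08
  hco3[dip2] <- stats::runif(sum(dip2), 17, 20)

  blank <- rep(NA_real_, n)
  art <- data.frame(time_min = times, site = "arterial", po2_mmhg = po2_a,
                    so2 = so2_a, hb_g_dl = hb_a, lactate_mmol_l = lac,
                    ph = ph, hco3_mmol_l = hco3, ica_mmol_l = ica,
                    k_mmol_l = kv, cbf_ml_min = cbf,
                    map_mmhg = settings$mean_aortic_pressure,
                    temp_c = settings$temperature, stringsAsFactors = FALSE)
  ven <- data.frame(time_min = times, site = "venous", po2_mmhg = po2_v,
                    so2 = so2_v, hb_g_dl = hb_v, lactate_mmol_l = blank,
                    ph = blank, hco3_mmol_l = blank, ica_mmol_l = blank,
                    k_mmol_l = blank, cbf_ml_min = NA_real_,
                    map_mmhg = NA_real_, temp_c = NA_real_,
                    stringsAsFactors = FALSE)
  out <- rbind(art, ven)
  out <- out[order(out$time_min, out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(true_mvo2 = true_mvo2, heart_weight = hw,
                             true_cvo2_mean = mean(cvo2_lat),
                             scenario = config$scenario, seed = config$seed)
  out
}
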