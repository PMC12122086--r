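#' Donor profile
#'
#' Donor characteristics that drive the heart-weight estimate. When a
#' measured heart weight is supplied it overrides the sex/body-weight
#' regression everywhere downstream.
#'
#' @param sex `"female"` or `"male"`.
#' @param body_weight Donor body weight, kg; must lie in (0, 400).
#' @param measured_heart_weight Optional measured heart weight, g (> 0).
#' @return An object of class `donor_profile`.
#' @export
#' @examples
#' donor_profile("male", 80)
#' donor_profile("female", 70, measured_heart_weight = 300)
donor_profile <- function(sex, body_weight, measured_heart_weight = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0 || body_weight >= 400) {
    stop("body_weight must be a single finite number in (0, 400) kg", call. = FALSE)
  }
  if (!is.null(measured_heart_weight)) {
    if (!is.numeric(measured_heart_weight) || length(measured_heart_weight) != 1L ||
        !is.finite(measured_heart_weight) || measured_heart_weight <= 0) {
      stop("measured_heart_weight must be a single positive number (grams)",
           call. = FALSE)
    }
  }
  structure(list(sex = sex, body_weight = body_weight,
                 measured_heart_weight = measured_heart_weight),
            class = "donor_profile")
}

#' @export
print.donor_profile <- function(x, ...) {
  hw <- if (is.null(x$measured_heart_weight)) {
    sprintf("estimated %.1f g", estimate_heart_weight(x$sex, x$body_weight))
  } else sprintf("measured %.1f g", x$measured_heart_weight)
  cat(sprintf("Donor: %s, %.1f kg, heart weight %s\n", x$sex, x$body_weight, hw))
  invisible(x)
}

#' Heart weight used for a donor
#'
#' The measured heart weight when present, otherwise the sex-specific
#' regression estimate from body weight.
#'
#' @param donor A [donor_profile()].
#' @return Heart weight, g.
#' @export
heart_weight <- function(donor) {
  stopifnot(inherits(donor, "donor_profile"))
  if (!is.null(donor$measured_heart_weight)) donor$measured_heart_weight
  else estimate_heart_weight(donor$sex, donor$body_weight)
}

#' Blood-gas sample
#'
#' One timed arterial or venous perfusate measurement, stored in canonical
#' units: PO2 in mmHg, saturation as a fraction in \[0, 1\], hemoglobin in
#' g/dL. Unit conversion (percent saturation, mmol/L hemoglobin) happens at
#' ingestion, not here: this constructor is strict.
#'
#' @param time Minutes since perfusion start, >= 0.
#' @param site `"arterial"` or `"venous"`.
#' @param po2 Oxygen partial pressure, mmHg, > 0.
#' @param so2 Oxygen saturation, fraction in \[0, 1\].
#' @param hb Hemoglobin, g/dL, >= 0.
#' @param lactate,ph,hco3,ionized_ca,k Optional chemistry values
#'   (mmol/L except pH); `NA` when unmeasured.
#' @return An object of class `blood_gas_sample`.
#' @export
blood_gas_sample <- function(time, site, po2, so2, hb,
                             lactate = NA_real_, ph = NA_real_,
                             hco3 = NA_real_, ionized_ca = NA_real_,
                             k = NA_real_) {
  site <- match.arg(site, c("arterial", "venous"))
  chk <- function(x, nm, lo = -Inf, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L) stop(nm, " must be a single number", call. = FALSE)
    if (!is.finite(x)) stop(nm, " must be finite", call. = FALSE)
    if (x < lo || x > hi || (lo_open && x == lo)) {
      stop(sprintf("%s = %g outside the allowed range %s%g, %g]",
                   nm, x, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
    }
    as.numeric(x)
  }
  opt <- function(x, nm, lo = 0) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_real_)
    chk(x, nm, lo)
  }
  structure(list(
    time = chk(time, "time", 0),
    site = site,
    po2 = chk(po2, "po2", 0, lo_open = TRUE),
    so2 = chk(so2, "so2", 0, 1),
    hb = chk(hb, "hb", 0),
    lactate = opt(lactate, "lactate"),
    ph = opt(ph, "ph"),
    hco3 = opt(hco3, "hco3"),
    ionized_ca = opt(ionized_ca, "ionized_ca"),
    k = opt(k, "k")), class = "blood_gas_sample")
}

#' @export
print.blood_gas_sample <- function(x, ...) {
  cat(sprintf("[%6.1f min] %-8s PO2 %.0f mmHg, SO2 %.2f, Hb %.2f g/dL%s\n",
              x$time, x$site, x$po2, x$so2, x$hb,
              if (is.na(x$lactate)) "" else sprintf(", lactate %.2f mmol/L", x$lactate)))
  invisible(x)
}

#' Perfusion machine settings
#'
#' The pump flow, target mean aortic pressure and perfusate temperature in
#' effect. Defaults are the midpoints of the standard machine protocol
#' (CBF 700-800 ml/min, pressure 75-80 mmHg) and its 34 °C set point.
#'
#' @param cbf_setting Pump coronary blood flow, ml/min, > 0. Default 750.
#' @param mean_aortic_pressure mmHg, > 0. Default 77.5.
#' @param temperature Perfusate temperature, Celsius. Default 34.
#' @return An object of class `perfusion_settings`.
#' @export
perfusion_settings <- function(cbf_setting = 750, mean_aortic_pressure = 77.5,
                               temperature = 34) {
  if (!is.finite(cbf_setting) || cbf_setting <= 0) {
    stop("cbf_setting must be a positive flow in ml/min", call. = FALSE)
  }
  if (!is.finite(mean_aortic_pressure) || mean_aortic_pressure <= 0) {
    stop("mean_aortic_pressure must be positive (mmHg)", call. = FALSE)
  }
  if (!is.finite(temperature)) stop("temperature must be finite", call. = FALSE)
  structure(list(cbf_setting = cbf_setting,
                 mean_aortic_pressure = mean_aortic_pressure,
                 temperature = temperature),
            class = "perfusion_settings")
}
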