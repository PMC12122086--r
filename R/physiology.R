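#' Estimate heart weight from donor sex and body weight
#'
#' Sex-specific linear regressions of heart weight on body weight:
#' female `2.153 * BW + 104.6`, male `2.492 * BW + 141.2` (grams, BW in kg).
#' Vectorized over `body_weight` and `sex`.
#'
#' @param sex `"female"` or `"male"` (recycled against `body_weight`).
#' @param body_weight Body weight, kg, > 0.
#' @return Estimated heart weight, g.
#' @export
#' @examples
#' estimate_heart_weight("female", 70)  # 255.31
#' estimate_heart_weight("male", 80)    # 340.56
estimate_heart_weight <- function(sex, body_weight) {
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (!is.numeric(body_weight) || any(!is.finite(body_weight)) ||
      any(body_weight < 0)) {
    stop("body_weight must be finite and non-negative (kg)", call. = FALSE)
  }
  slope <- ifelse(sex == "female", 2.153, 2.492)
  intercept <- ifelse(sex == "female", 104.6, 141.2)
  slope * body_weight + intercept
}

#' Oxygen content of perfusate
#'
#' `CaO2 = huefner * Hb * SO2 + dissolved_coeff * PO2`: hemoglobin-bound plus
#' dissolved oxygen, ml O2 per dL. Linear in each argument; applies equally to
#' arterial and venous samples. Vectorized.
#'
#' @param hb Hemoglobin, g/dL, >= 0.
#' @param so2 Oxygen saturation, fraction in \[0, 1\].
#' @param po2 Oxygen partial pressure, mmHg, >= 0.
#' @param params An [oxygen_parameters()].
#' @return Oxygen content, ml O2/dL.
#' @export
#' @examples
#' oxygen_content(10, 1.0, 100)  # 13.71
#' oxygen_content(9, 1.0, 350)   # 13.145
oxygen_content <- function(hb, so2, po2, params = oxygen_parameters()) {
  if (!is.numeric(hb) || any(!is.finite(hb)) || any(hb < 0)) {
    stop("hb must be finite and >= 0 (g/dL)", call. = FALSE)
  }
  if (!is.numeric(so2) || any(!is.finite(so2)) || any(so2 < 0 | so2 > 1)) {
    stop("so2 must be a fraction in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(po2) || any(!is.finite(po2)) || any(po2 < 0)) {
    stop("po2 must be finite and >= 0 (mmHg)", call. = FALSE)
  }
  params$huefner * hb * so2 + params$dissolved_coeff * po2
}

#' Measured myocardial oxygen consumption (Fick)
#'
#' `MVO2 = CBF * (CaO2 - CvO2) / 100`. Contents are per dL and flow per ml,
#' hence the explicit /100 bridging the two. A negative arteriovenous
#' difference (venous content above arterial) is returned as-is, never
#' clipped, so swapped-site data-entry errors stay visible; the session layer
#' flags it.
#'
#' @param cbf Coronary blood flow, ml/min, > 0.
#' @param cao2 Arterial oxygen content, ml O2/dL, > 0.
#' @param cvo2 Venous oxygen content, ml O2/dL, >= 0.
#' @return Oxygen consumption, ml O2/min.
#' @export
#' @examples
#' mvo2_measured(500, 14, 4)  # 50
mvo2_measured <- function(cbf, cao2, cvo2) {
  stopifnot(is.numeric(cbf), is.numeric(cao2), is.numeric(cvo2))
  if (any(!is.finite(cbf)) || any(cbf <= 0)) stop("cbf must be > 0", call. = FALSE)
  if (any(!is.finite(cao2)) || any(cao2 <= 0)) stop("cao2 must be > 0", call. = FALSE)
  if (any(!is.finite(cvo2)) || any(cvo2 < 0)) stop("cvo2 must be >= 0", call. = FALSE)
  cbf * (cao2 - cvo2) / 100
}

#' Myocardial oxygen delivery
#'
#' `MDO2 = CBF * CaO2 / 100`, ml O2/min.
#'
#' @inheritParams mvo2_measured
#' @return Oxygen delivery, ml O2/min.
#' @export
mdo2 <- function(cbf, cao2) {
  stopifnot(is.numeric(cbf), is.numeric(cao2))
  if (any(!is.finite(cbf)) || any(cbf <= 0)) stop("cbf must be > 0", call. = FALSE)
  if (any(!is.finite(cao2)) || any(cao2 < 0)) stop("cao2 must be >= 0", call. = FALSE)
  cbf * cao2 / 100
}

#' Myocardial oxygen extraction fraction
#'
#' `MEO2 = MVO2 / MDO2`; by construction this equals the measured extraction
#' ratio `(CaO2 - CvO2) / CaO2`. Undefined (NA) when delivery is zero.
#'
#' @param mvo2 Oxygen consumption, ml O2/min.
#' @param mdo2 Oxygen delivery, ml O2/min, > 0.
#' @return Extraction fraction.
#' @export
meo2 <- function(mvo2, mdo2) {
  stopifnot(is.numeric(mvo2), is.numeric(mdo2))
  ifelse(is.finite(mdo2) & mdo2 > 0, mvo2 / mdo2, NA_real_)
}

#' Coronary vascular resistance
#'
#' Mean aortic pressure over coronary flow, mmHg·min/ml. Coronary venous
#' pressure is taken as zero: the preparation drains freely and the ventricle
#' is unloaded. Undefined (NA) at zero flow.
#'
#' @param mean_aortic_pressure mmHg.
#' @param cbf Coronary blood flow, ml/min, > 0.
#' @return Resistance, mmHg·min/ml.
#' @export
#' @examples
#' cvr(75, 750)  # 0.1
cvr <- function(mean_aortic_pressure, cbf) {
  stopifnot(is.numeric(mean_aortic_pressure), is.numeric(cbf))
  ifelse(is.finite(cbf) & cbf > 0, mean_aortic_pressure / cbf, NA_real_)
}

#' Arteriovenous oxygen-tension gradient
#'
#' Arterial minus venous PO2, mmHg. Negative values are allowed (and flagged
#' at the session layer): they indicate swapped sites or analyzer error.
#'
#' @param pao2 Arterial PO2, mmHg, >= 0.
#' @param pvo2 Venous PO2, mmHg, >= 0.
#' @return Gradient, mmHg.
#' @export
delta_po2 <- function(pao2, pvo2) {
  stopifnot(is.numeric(pao2), is.numeric(pvo2))
  if (any(!is.finite(pao2)) || any(pao2 < 0) ||
      any(!is.finite(pvo2)) || any(pvo2 < 0)) {
    stop("pao2 and pvo2 must be finite and >= 0 (mmHg)", call. = FALSE)
  }
  pao2 - pvo2
}
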