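#' Unnormalized required coronary blood flow
#'
#' The flow at which delivery exactly covers the expected consumption of
#' `heart_weight` grams of myocardium at the target extraction ratio:
#' `CBF = HW * mvo2_per_gram * 100 / (CaO2 * oer_target)` ml/min.
#' At the default parameters this is `(HW / CaO2) * 12.5`. Vectorized over
#' `heart_weight` and `cao2`.
#'
#' @param heart_weight Myocardial mass, g, > 0.
#' @param cao2 Arterial oxygen content, ml O2/dL, > 0.
#' @param params An [oxygen_parameters()].
#' @return Required flow, ml/min (unnormalized; may fall outside 500-800).
#' @export
#' @examples
#' cbf_unnormalized(340.56, 13.145)  # ~323.85, a typical 80 kg male donor
cbf_unnormalized <- function(heart_weight, cao2, params = oxygen_parameters()) {
  stopifnot(is.numeric(heart_weight), is.numeric(cao2))
  if (any(!is.finite(heart_weight)) || any(heart_weight <= 0)) {
    stop("heart_weight must be > 0 (grams)", call. = FALSE)
  }
  if (any(!is.finite(cao2)) || any(cao2 <= 0)) {
    stop("cao2 must be > 0 (ml O2/dL); zero oxygen content has no defined flow",
         call. = FALSE)
  }
  heart_weight * params$mvo2_per_gram * 100 / (cao2 * params$oer_target)
}

# Sex-specific min-max normalization onto [offset, offset + scale], clamped.
# Returns fraction (pre-clamp), recommended flow and clamp indicator.
normalize_cbf <- function(x, sex, constants = normalization_constants()) {
  m <- ifelse(sex == "female", constants$female_min, constants$male_min)
  r <- ifelse(sex == "female", constants$female_range, constants$male_range)
  f <- (x - m) / r
  list(fraction = f,
       recommended = constants$offset + constants$scale * pmin(pmax(f, 0), 1),
       clamped = f < 0 | f > 1)
}

new_cbf_recommendation <- function(recommended, unnormalized, fraction, clamped,
                                   basis, heart_weight_used, hb, so2, po2, cao2,
                                   time = NA_real_) {
  structure(list(recommended_cbf = recommended,
                 unnormalized_cbf = unnormalized,
                 normalized_fraction = fraction,
                 clamped = clamped,
                 basis = basis,
                 heart_weight_used = heart_weight_used,
                 inputs_echo = list(hb = hb, so2 = so2, po2 = po2, cao2 = cao2),
                 time = time),
            class = "cbf_recommendation")
}

#' @export
print.cbf_recommendation <- function(x, ...) {
  cat(sprintf("Recommended CBF: %d ml/min (raw %.1f, basis: %s%s)\n",
              recommendation_display(x), x$recommended_cbf,
              gsub("_", " ", x$basis),
              if (x$clamped) ", clamped" else ""))
  cat(sprintf("  heart weight %.1f g | CaO2 %.2f ml O2/dL | unnormalized %.1f ml/min\n",
              x$heart_weight_used, x$inputs_echo$cao2, x$unnormalized_cbf))
  invisible(x)
}

#' Personalized coronary blood flow recommendation
#'
#' Computes the required flow for this donor heart from the baseline arterial
#' blood gas ([cbf_unnormalized()]), then maps it onto the 500-800 ml/min
#' protocol window with the sex-specific min-max normalization, clamping
#' values that fall outside the window. The measured heart weight is used
#' when the donor profile carries one; otherwise the sex/body-weight estimate.
#'
#' With scalar blood-gas inputs the result is a single `cbf_recommendation`;
#' with vector inputs (recycled to a common length) a data frame with one row
#' per input combination, which is how large parameter grids are evaluated.
#'
#' @param donor A [donor_profile()].
#' @param hb Perfusate hemoglobin, g/dL.
#' @param so2 Arterial oxygen saturation, fraction.
#' @param po2 Arterial PO2, mmHg.
#' @param params An [oxygen_parameters()].
#' @param constants A [normalization_constants()].
#' @return A `cbf_recommendation` (scalar inputs) or data frame (vector inputs).
#' @export
#' @examples
#' rec <- personalize_cbf(donor_profile("male", 80), hb = 9, so2 = 1.0, po2 = 350)
#' rec$recommended_cbf          # ~601.5
#' recommendation_display(rec)  # 600
personalize_cbf <- function(donor, hb, so2, po2,
                            params = oxygen_parameters(),
                            constants = normalization_constants()) {
  stopifnot(inherits(donor, "donor_profile"))
  hw <- heart_weight(donor)
  cao2 <- oxygen_content(hb, so2, po2, params)
  x <- cbf_unnormalized(hw, cao2, params)
  nz <- normalize_cbf(x, donor$sex, constants)
  n <- length(x)
  if (n == 1L) {
    new_cbf_recommendation(nz$recommended, x, nz$fraction, nz$clamped,
                           basis = "estimated_mvo2", heart_weight_used = hw,
                           hb = hb, so2 = so2, po2 = po2, cao2 = cao2)
  } else {
    data.frame(recommended_cbf = nz$recommended, unnormalized_cbf = x,
               normalized_fraction = nz$fraction, clamped = nz$clamped,
               basis = "estimated_mvo2", heart_weight_used = hw,
               hb = hb, so2 = so2, po2 = po2, cao2 = cao2)
  }
}

#' Recalibrate the flow recommendation from a measured snapshot
#'
#' Serial update: the expected consumption term `HW * mvo2_per_gram` in the
#' required-flow equation is replaced by the actually measured MVO2 of the
#' latest arterial/venous pair, so `x = MVO2 * 100 / (CaO2 * oer_target)`;
#' the same sex-specific normalization and clamp then apply. The target
#' extraction ratio stays in the denominator (rather than the measured one)
#' because the recommendation's purpose is to drive extraction toward the
#' physiologic target.
#'
#' A snapshot flagged for negative extraction (venous content above arterial)
#' withholds the recommendation: the function returns `NULL` with a warning,
#' since the measurement is more likely a site swap than physiology.
#'
#' @param snapshot A one-row snapshot as produced by [compute_snapshot()]
#'   (or a list with `mvo2`, `cao2`, optionally `time`).
#' @param donor A [donor_profile()] (supplies the sex for normalization).
#' @param params An [oxygen_parameters()].
#' @param constants A [normalization_constants()].
#' @return A `cbf_recommendation` with `basis = "measured_mvo2"`, or `NULL`
#'   when the recommendation is withheld.
#' @export
recalibrate_cbf <- function(snapshot, donor,
                            params = oxygen_parameters(),
                            constants = normalization_constants()) {
  stopifnot(inherits(donor, "donor_profile"))
  snapshot <- as.list(snapshot)
  mvo2 <- snapshot$mvo2
  cao2 <- snapshot$cao2
  if (!is.finite(cao2) || cao2 <= 0) stop("snapshot cao2 must be > 0", call. = FALSE)
  if (!is.finite(mvo2)) stop("snapshot mvo2 must be finite", call. = FALSE)
  if (mvo2 < 0) {
    warning("recommendation withheld: measured MVO2 is negative ",
            "(venous oxygen content exceeds arterial; check sample sites)",
            call. = FALSE)
    return(NULL)
  }
  x <- mvo2 * 100 / (cao2 * params$oer_target)
  nz <- normalize_cbf(x, donor$sex, constants)
  new_cbf_recommendation(nz$recommended, x, nz$fraction, nz$clamped,
                         basis = "measured_mvo2",
                         heart_weight_used = heart_weight(donor),
                         hb = NA_real_, so2 = NA_real_, po2 = NA_real_,
                         cao2 = cao2,
                         time = if (is.null(snapshot$time)) NA_real_ else snapshot$time)
}

#' Display rounding of a flow recommendation
#'
#' Operators set the pump in 10 ml/min steps, so the displayed value is the
#' raw recommendation rounded to the nearest 10 (round-half-even); the raw
#' value stays in the record.
#'
#' @param rec A `cbf_recommendation` or a numeric flow in ml/min.
#' @return Integer flow, ml/min.
#' @export
recommendation_display <- function(rec) {
  v <- if (inherits(rec, "cbf_recommendation")) rec$recommended_cbf else rec
  stopifnot(is.numeric(v), all(is.finite(v)))
  as.integer(round(v / 10) * 10)
}
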