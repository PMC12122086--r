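#' Oxygen-handling parameters
#'
#' Physiologic constants used throughout the oxygen calculations.
#' The Hüfner constant (1.34 ml O2 per g Hb) and the solubility coefficient
#' (0.0031 ml O2/dL/mmHg) define oxygen content; `mvo2_per_gram` is the
#' expected myocardial oxygen consumption per gram of myocardium of an
#' unloaded beating heart at 34 °C, and `oer_target` the oxygen extraction
#' ratio the flow recommendation drives the myocardium toward. At the
#' defaults, `100 * mvo2_per_gram / oer_target = 12.5`, the multiplier that
#' appears in the sex-specific flow equations.
#'
#' @param huefner Oxygen-binding capacity of hemoglobin, ml O2 per g. Default 1.34.
#' @param dissolved_coeff Solubility of oxygen in perfusate, ml O2/dL per mmHg.
#'   Default 0.0031.
#' @param mvo2_per_gram Expected oxygen consumption, ml O2/min per gram of
#'   myocardium. Default 0.10; the physiologic range under subnormothermic
#'   resting conditions is 0.08-0.13.
#' @param oer_target Target oxygen extraction ratio, a fraction. Default 0.80;
#'   cardiomyocyte extraction is physiologically 0.70-0.80.
#' @return An object of class `oxygen_parameters`.
#' @export
#' @examples
#' p <- oxygen_parameters()
#' 100 * p$mvo2_per_gram / p$oer_target   # 12.5
oxygen_parameters <- function(huefner = 1.34, dissolved_coeff = 0.0031,
                              mvo2_per_gram = 0.10, oer_target = 0.80) {
  vals <- c(huefner = huefner, dissolved_coeff = dissolved_coeff,
            mvo2_per_gram = mvo2_per_gram, oer_target = oer_target)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all oxygen parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (mvo2_per_gram < 0.08 || mvo2_per_gram > 0.13) {
    warning(sprintf("mvo2_per_gram = %g is outside the physiologic range [0.08, 0.13]",
                    mvo2_per_gram), call. = FALSE)
  }
  if (oer_target < 0.70 || oer_target > 0.80) {
    warning(sprintf("oer_target = %g is outside the physiologic range [0.70, 0.80]",
                    oer_target), call. = FALSE)
  }
  structure(list(huefner = huefner, dissolved_coeff = dissolved_coeff,
                 mvo2_per_gram = mvo2_per_gram, oer_target = oer_target),
            class = "oxygen_parameters")
}

#' Normalization constants for the personalized flow window
#'
#' The unnormalized required flow is mapped onto the protocol window
#' \[offset, offset + scale\] = \[500, 800\] ml/min by sex-specific min-max
#' normalization: `rec = offset + scale * clamp((x - sex_min) / sex_range, 0, 1)`.
#' The sex-specific anchors derive from the extreme values observed across
#' donor/perfusate combinations; they are configurable because they are
#' center-specific calibrations, not physical constants.
#'
#' @param scale Width of the recommendation window, ml/min. Default 300.
#' @param offset Floor of the recommendation window, ml/min. Default 500
#'   (the lowest flow with demonstrated adequate perfusion preclinically).
#' @param female_min,female_range Min-max anchors for female donors (133, 333).
#' @param male_min,male_range Min-max anchors for male donors (178, 431).
#' @return An object of class `normalization_constants`.
#' @export
normalization_constants <- function(scale = 300, offset = 500,
                                    female_min = 133, female_range = 333,
                                    male_min = 178, male_range = 431) {
  vals <- c(scale, offset, female_min, female_range, male_min, male_range)
  if (!all(is.finite(vals))) stop("normalization constants must be finite", call. = FALSE)
  if (scale <= 0 || female_range <= 0 || male_range <= 0) {
    stop("scale and sex ranges must be strictly positive", call. = FALSE)
  }
  structure(list(scale = scale, offset = offset,
                 female_min = female_min, female_range = female_range,
                 male_min = male_min, male_range = male_range),
            class = "normalization_constants")
}

#' Electrolyte advisory thresholds
#'
#' Standard clinical reference bounds used to trigger supplementation
#' advisories. A bicarbonate advisory is raised when bicarbonate falls below
#' `bicarbonate_low` or pH below `ph_low`; a potassium advisory when potassium
#' leaves \[`potassium_low`, `potassium_high`\]; a calcium advisory when
#' ionized calcium falls below `ionized_calcium_low`. All bounds are
#' overridable because supplementation policy is center-specific.
#'
#' @param ionized_calcium_low mmol/L, default 1.1.
#' @param bicarbonate_low mmol/L, default 21.
#' @param ph_low unitless, default 7.30.
#' @param potassium_low,potassium_high mmol/L, defaults 3.5 and 5.5.
#' @return An object of class `advisory_thresholds`.
#' @export
advisory_thresholds <- function(ionized_calcium_low = 1.1,
                                bicarbonate_low = 21, ph_low = 7.30,
                                potassium_low = 3.5, potassium_high = 5.5) {
  vals <- c(ionized_calcium_low, bicarbonate_low, ph_low,
            potassium_low, potassium_high)
  if (!all(is.finite(vals))) stop("advisory thresholds must be finite", call. = FALSE)
  if (potassium_high <= potassium_low) {
    stop("potassium_high must exceed potassium_low", call. = FALSE)
  }
  structure(list(ionized_calcium_low = ionized_calcium_low,
                 bicarbonate_low = bicarbonate_low, ph_low = ph_low,
                 potassium_low = potassium_low, potassium_high = potassium_high),
            class = "advisory_thresholds")
}

# g/dL of hemoglobin per mmol/L (monomer convention); lab conventions differ,
# so sessions carry their own copy.
HB_GDL_PER_MMOLL <- 1.6113

#' Tool configuration
#'
#' Bundles every tunable the pipeline consumes: oxygen parameters,
#' normalization constants, advisory thresholds, pairing tolerance, the
#' hemoglobin unit-conversion factor and the standard machine settings.
#' `read_tool_config()` builds one from a JSON or YAML override file.
#'
#' @param params [oxygen_parameters()] overrides.
#' @param constants [normalization_constants()] overrides.
#' @param thresholds [advisory_thresholds()] overrides.
#' @param pairing_tolerance Minutes; arterial and venous samples at most this
#'   far apart are paired into one snapshot. Default 5.
#' @param hb_gdl_per_mmoll Conversion factor g/dL per mmol/L (monomer
#'   convention). Default 1.6113.
#' @param settings Default [perfusion_settings()].
#' @param gas_flow Sweep-gas flow, ml/min. Default 150.
#' @param gas_o2_fraction,gas_co2_fraction Sweep-gas composition. Defaults
#'   0.85 and 0.01.
#' @return An object of class `tool_config`.
#' @export
tool_config <- function(params = oxygen_parameters(),
                        constants = normalization_constants(),
                        thresholds = advisory_thresholds(),
                        pairing_tolerance = 5,
                        hb_gdl_per_mmoll = HB_GDL_PER_MMOLL,
                        settings = perfusion_settings(),
                        gas_flow = 150,
                        gas_o2_fraction = 0.85, gas_co2_fraction = 0.01) {
  stopifnot(inherits(params, "oxygen_parameters"),
            inherits(constants, "normalization_constants"),
            inherits(thresholds, "advisory_thresholds"),
            inherits(settings, "perfusion_settings"))
  if (!is.finite(pairing_tolerance) || pairing_tolerance < 0) {
    stop("pairing_tolerance must be a non-negative number of minutes", call. = FALSE)
  }
  if (!is.finite(hb_gdl_per_mmoll) || hb_gdl_per_mmoll <= 0) {
    stop("hb_gdl_per_mmoll must be positive", call. = FALSE)
  }
  structure(list(params = params, constants = constants, thresholds = thresholds,
                 pairing_tolerance = pairing_tolerance,
                 hb_gdl_per_mmoll = hb_gdl_per_mmoll,
                 settings = settings, gas_flow = gas_flow,
                 gas_o2_fraction = gas_o2_fraction,
                 gas_co2_fraction = gas_co2_fraction),
            class = "tool_config")
}

#' Read a tool configuration from a JSON or YAML file
#'
#' The file holds any subset of the constructor arguments of
#' [oxygen_parameters()], [normalization_constants()],
#' [advisory_thresholds()], [perfusion_settings()] under the keys
#' `params`, `constants`, `thresholds`, `settings`, plus top-level
#' `pairing_tolerance`, `hb_gdl_per_mmoll`, `gas_flow`,
#' `gas_o2_fraction`, `gas_co2_fraction`. Absent keys keep their defaults;
#' every override is validated by the corresponding constructor.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A [tool_config()].
#' @export
read_tool_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(ctor, overrides) do.call(ctor, as.list(overrides))
  top <- raw[intersect(names(raw),
                       c("pairing_tolerance", "hb_gdl_per_mmoll", "gas_flow",
                         "gas_o2_fraction", "gas_co2_fraction"))]
  do.call(tool_config, c(
    list(params = build(oxygen_parameters, raw$params),
         constants = build(normalization_constants, raw$constants),
         thresholds = build(advisory_thresholds, raw$thresholds),
         settings = build(perfusion_settings, raw$settings)),
    top))
}
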