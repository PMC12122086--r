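# Canonical in-memory schemas. Samples and snapshots live in data frames so
# trend fits and reports are plain column operations.
.sample_schema <- function() {
  data.frame(time = numeric(0), site = character(0), po2 = numeric(0),
             so2 = numeric(0), hb = numeric(0), lactate = numeric(0),
             ph = numeric(0), hco3 = numeric(0), ionized_ca = numeric(0),
             k = numeric(0), stringsAsFactors = FALSE)
}

.snapshot_schema <- function() {
  data.frame(time = numeric(0), cao2 = numeric(0), cvo2 = numeric(0),
             mdo2 = numeric(0), mvo2 = numeric(0), meo2 = numeric(0),
             delta_po2 = numeric(0), cvr = numeric(0), lactate = numeric(0),
             cbf_used = numeric(0), map_used = numeric(0),
             negative_extraction = logical(0),
             arterial_time = numeric(0), venous_time = numeric(0),
             stringsAsFactors = FALSE)
}

.recommendation_schema <- function() {
  data.frame(time = numeric(0), recommended_cbf = numeric(0),
             display_cbf = integer(0), unnormalized_cbf = numeric(0),
             normalized_fraction = numeric(0), clamped = logical(0),
             basis = character(0), stringsAsFactors = FALSE)
}

.settings_schema <- function() {
  data.frame(time = numeric(0), cbf_ml_min = numeric(0), map_mmhg = numeric(0),
             temp_c = numeric(0), stringsAsFactors = FALSE)
}

#' Start a perfusion session
#'
#' A perfusion session holds everything recorded during one machine run: the
#' donor profile, the history of pump settings, every ingested blood-gas
#' sample, the derived metabolic snapshots (one per paired arterial/venous
#' sample set) and the serial flow recommendations. The baseline
#' recommendation from donor characteristics is computed the moment the first
#' arterial sample arrives; later snapshots append measured-MVO2
#' recalibrations.
#'
#' @param donor A [donor_profile()].
#' @param config A [tool_config()]; carries parameters, normalization
#'   constants, advisory thresholds, pairing tolerance and unit conversions.
#' @return An object of class `perfusion_session`.
#' @export
#' @examples
#' s <- perfusion_session(donor_profile("male", 80))
#' s <- ingest_sample(s, list(time = 0, site = "arterial", po2 = 350,
#'                            so2 = 1.0, hb = 9))
perfusion_session <- function(donor, config = tool_config()) {
  stopifnot(inherits(donor, "donor_profile"), inherits(config, "tool_config"))
  st <- .settings_schema()
  st[1, ] <- list(0, config$settings$cbf_setting,
                  config$settings$mean_aortic_pressure,
                  config$settings$temperature)
  structure(list(donor = donor, config = config,
                 settings_history = st,
                 samples = .sample_schema(),
                 snapshots = .snapshot_schema(),
                 recommendations = .recommendation_schema()),
            class = "perfusion_session")
}

#' @export
print.perfusion_session <- function(x, ...) {
  cat(sprintf("Perfusion session: %s donor, %.0f kg | %d samples, %d snapshots, %d recommendations\n",
              x$donor$sex, x$donor$body_weight, nrow(x$samples),
              nrow(x$snapshots), nrow(x$recommendations)))
  if (nrow(x$recommendations)) {
    last <- x$recommendations[nrow(x$recommendations), ]
    cat(sprintf("  latest CBF advice: %d ml/min (%s) at t = %.0f min\n",
                last$display_cbf, gsub("_", " ", last$basis), last$time))
  }
  invisible(x)
}

#' Record a pump-settings change
#'
#' Appends (or overwrites, at an identical time) an entry in the settings
#' history. Snapshots use the last settings at or before their timestamp.
#'
#' @param session A [perfusion_session()].
#' @param time Minutes since perfusion start.
#' @param cbf_ml_min,map_mmhg,temp_c New values; `NA` keeps the previous one.
#' @return The updated session.
#' @export
set_settings <- function(session, time, cbf_ml_min = NA, map_mmhg = NA,
                         temp_c = NA) {
  stopifnot(inherits(session, "perfusion_session"), is.finite(time), time >= 0)
  st <- session$settings_history
  prev <- st[max(which(st$time <= time)), ]
  row <- list(time,
              if (is.na(cbf_ml_min)) prev$cbf_ml_min else cbf_ml_min,
              if (is.na(map_mmhg)) prev$map_mmhg else map_mmhg,
              if (is.na(temp_c)) prev$temp_c else temp_c)
  hit <- which(st$time == time)
  if (length(hit)) st[hit, ] <- row else st[nrow(st) + 1L, ] <- row
  session$settings_history <- st[order(st$time), , drop = FALSE]
  rownames(session$settings_history) <- NULL
  session
}

# Pump settings in force at a given time (last change at or before t).
active_settings <- function(session, time) {
  st <- session$settings_history
  i <- which(st$time <= time)
  row <- st[if (length(i)) max(i) else 1L, ]
  perfusion_settings(cbf_setting = row$cbf_ml_min,
                     mean_aortic_pressure = row$map_mmhg,
                     temperature = row$temp_c)
}

# Unit normalization applied at ingestion. so2 > 1 is read as percent; hb in
# mmol/L (monomer convention) converts at hb_gdl_per_mmoll. Explicit hints
# override the heuristics.
normalize_units <- function(raw, unit_hints = list(),
                            hb_gdl_per_mmoll = HB_GDL_PER_MMOLL) {
  so2 <- raw$so2
  if (identical(unit_hints$so2, "percent") ||
      (is.null(unit_hints$so2) && is.finite(so2) && so2 > 1)) {
    so2 <- so2 / 100
  }
  if (is.finite(so2) && (so2 < 0 || so2 > 1)) {
    stop(sprintf("so2 = %g is not a valid fraction after unit normalization", so2),
         call. = FALSE)
  }
  hb <- raw$hb
  if (identical(unit_hints$hb, "mmol_l")) hb <- hb * hb_gdl_per_mmoll
  raw$so2 <- so2
  raw$hb <- hb
  raw
}

as_sample_row <- function(s) {
  data.frame(time = s$time, site = s$site, po2 = s$po2, so2 = s$so2, hb = s$hb,
             lactate = s$lactate, ph = s$ph, hco3 = s$hco3,
             ionized_ca = s$ionized_ca, k = s$k, stringsAsFactors = FALSE)
}

#' Ingest one blood-gas sample into a session
#'
#' Normalizes units to canonical (saturation fraction, hemoglobin g/dL, PO2
#' mmHg), validates, inserts the sample in (time, site) order, and — when an
#' unpaired counterpart sample of the opposite site lies within the pairing
#' tolerance — computes a metabolic snapshot at the pair's midpoint time using
#' the pump settings in force there, followed by an updated flow
#' recommendation. The first arterial sample additionally triggers the
#' baseline donor-characteristics recommendation.
#'
#' A duplicate (time, site) combination is rejected with an error of class
#' `eshp_duplicate_error`, which keeps re-ingestion of the same log
#' idempotent.
#'
#' @param session A [perfusion_session()].
#' @param raw_sample A [blood_gas_sample()] or a list/one-row data frame with
#'   at least `time`, `site`, `po2`, `so2`, `hb`.
#' @param unit_hints Optional list, e.g. `list(hb = "mmol_l", so2 = "percent")`.
#' @return The updated session.
#' @export
ingest_sample <- function(session, raw_sample, unit_hints = list()) {
  stopifnot(inherits(session, "perfusion_session"))
  if (!inherits(raw_sample, "blood_gas_sample")) {
    raw <- as.list(raw_sample)
    required <- c("time", "site", "po2", "so2", "hb")
    missing <- setdiff(required, names(raw)[!vapply(raw, function(x)
      is.null(x) || (length(x) == 1L && is.na(x)), logical(1))])
    if (length(missing)) {
      stop("sample is missing required fields: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    raw <- normalize_units(raw, unit_hints, session$config$hb_gdl_per_mmoll)
    opt <- function(nm) if (is.null(raw[[nm]])) NA_real_ else as.numeric(raw[[nm]])
    raw_sample <- blood_gas_sample(raw$time, raw$site, raw$po2, raw$so2, raw$hb,
                                   lactate = opt("lactate"), ph = opt("ph"),
                                   hco3 = opt("hco3"),
                                   ionized_ca = opt("ionized_ca"), k = opt("k"))
  }
  s <- raw_sample
  dup <- session$samples$time == s$time & session$samples$site == s$site
  if (any(dup)) {
    stop(structure(class = c("eshp_duplicate_error", "error", "condition"),
                   list(message = sprintf(
                     "duplicate sample rejected: %s at t = %g min already ingested",
                     s$site, s$time), call = NULL)))
  }
  first_arterial <- s$site == "arterial" && !any(session$samples$site == "arterial")
  session$samples <- rbind(session$samples, as_sample_row(s))
  ord <- order(session$samples$time, session$samples$site)
  session$samples <- session$samples[ord, , drop = FALSE]
  rownames(session$samples) <- NULL

  if (first_arterial) {
    base <- personalize_cbf(session$donor, s$hb, s$so2, s$po2,
                            session$config$params, session$config$constants)
    base$time <- s$time
    session <- append_recommendation(session, base)
  }
  try_pair(session, s)
}

# Attempt to pair the newly ingested sample with the nearest unpaired
# counterpart within tolerance; on success append a snapshot plus a
# measured-MVO2 recommendation.
try_pair <- function(session, s) {
  tol <- session$config$pairing_tolerance
  other_site <- if (s$site == "arterial") "venous" else "arterial"
  used_times <- if (other_site == "arterial") session$snapshots$arterial_time
                else session$snapshots$venous_time
  cand <- session$samples[session$samples$site == other_site &
                            abs(session$samples$time - s$time) <= tol &
                            !(session$samples$time %in% used_times), ,
                          drop = FALSE]
  if (!nrow(cand)) return(session)
  cand <- cand[order(abs(cand$time - s$time), cand$time), , drop = FALSE]
  mate <- cand[1, ]
  art <- if (s$site == "arterial") s else row_to_sample(mate)
  ven <- if (s$site == "venous") s else row_to_sample(mate)
  mid <- (art$time + ven$time) / 2
  snap <- compute_snapshot(art, ven, active_settings(session, mid),
                           session$config$params)
  if (is.null(snap)) return(session)
  session$snapshots <- rbind(session$snapshots, snap)
  session$snapshots <- session$snapshots[order(session$snapshots$time), ,
                                         drop = FALSE]
  rownames(session$snapshots) <- NULL
  if (!snap$negative_extraction) {
    rec <- recalibrate_cbf(snap, session$donor, session$config$params,
                           session$config$constants)
    if (!is.null(rec)) session <- append_recommendation(session, rec)
  }
  session
}

row_to_sample <- function(row) {
  blood_gas_sample(row$time, row$site, row$po2, row$so2, row$hb,
                   lactate = row$lactate, ph = row$ph, hco3 = row$hco3,
                   ionized_ca = row$ionized_ca, k = row$k)
}

append_recommendation <- function(session, rec) {
  r <- data.frame(time = if (is.null(rec$time) || is.na(rec$time)) NA_real_ else rec$time,
                  recommended_cbf = rec$recommended_cbf,
                  display_cbf = recommendation_display(rec),
                  unnormalized_cbf = rec$unnormalized_cbf,
                  normalized_fraction = rec$normalized_fraction,
                  clamped = rec$clamped, basis = rec$basis,
                  stringsAsFactors = FALSE)
  session$recommendations <- rbind(session$recommendations, r)
  session
}

#' Derive a metabolic snapshot from a paired arterial/venous sample
#'
#' Oxygen contents on both sides via [oxygen_content()], consumption by the
#' Fick principle at the pump's actual flow, delivery, extraction fraction,
#' arteriovenous PO2 gradient and coronary vascular resistance. Lactate is
#' carried over from the arterial sample. The snapshot is timestamped at the
#' midpoint of the two sample times. Venous content above arterial sets the
#' `negative_extraction` flag; the values are kept, never clipped.
#'
#' Returns `NULL` (snapshot withheld) when the venous saturation or PO2 is
#' missing.
#'
#' @param arterial,venous [blood_gas_sample()]s of the respective sites.
#' @param settings The [perfusion_settings()] in force.
#' @param params An [oxygen_parameters()].
#' @return One-row data frame (see [perfusion_session()]), or `NULL`.
#' @export
compute_snapshot <- function(arterial, venous, settings = perfusion_settings(),
                             params = oxygen_parameters()) {
  stopifnot(inherits(arterial, "blood_gas_sample"),
            inherits(venous, "blood_gas_sample"))
  if (arterial$site != "arterial" || venous$site != "venous") {
    stop("compute_snapshot needs one arterial and one venous sample", call. = FALSE)
  }
  if (!is.finite(venous$so2) || !is.finite(venous$po2)) return(NULL)
  cao2 <- oxygen_content(arterial$hb, arterial$so2, arterial$po2, params)
  cvo2 <- oxygen_content(venous$hb, venous$so2, venous$po2, params)
  cbf <- settings$cbf_setting
  vo2 <- mvo2_measured(cbf, cao2, cvo2)
  do2 <- mdo2(cbf, cao2)
  data.frame(time = (arterial$time + venous$time) / 2,
             cao2 = cao2, cvo2 = cvo2, mdo2 = do2, mvo2 = vo2,
             meo2 = meo2(vo2, do2),
             delta_po2 = delta_po2(arterial$po2, venous$po2),
             cvr = cvr(settings$mean_aortic_pressure, cbf),
             lactate = arterial$lactate,
             cbf_used = cbf, map_used = settings$mean_aortic_pressure,
             negative_extraction = cvo2 > cao2,
             arterial_time = arterial$time, venous_time = venous$time,
             stringsAsFactors = FALSE)
}

#' Lactate trend over the most recent samples
#'
#' Least-squares slope of perfusate lactate against time over the last
#' `window` lactate-bearing samples of one site. Rising lactate is the
#' classical indicator against transplantation; the slope is classified as
#' `rising` above +0.1 mmol/L/h, `falling` below -0.1, `stable` between.
#' At least three points are required; otherwise the direction is `NA`.
#'
#' @param session A [perfusion_session()].
#' @param window Number of most recent points to fit. Default 5.
#' @param site Which site's lactate to use; arterial by default.
#' @param upto Optional time cutoff (minutes): use only samples at or before it.
#' @return An object of class `trend_series`: metric name, the fitted points,
#'   `slope_per_h` and `direction`.
#' @export
lactate_trend <- function(session, window = 5, site = "arterial", upto = Inf) {
  stopifnot(inherits(session, "perfusion_session"))
  site <- match.arg(site, c("arterial", "venous"))
  d <- session$samples
  d <- d[d$site == site & is.finite(d$lactate) & d$time <= upto, , drop = FALSE]
  trend_series("lactate", d$time, d$lactate, window)
}

#' Trend of a derived snapshot metric
#'
#' Same least-squares classification as [lactate_trend()], applied to any
#' snapshot column (`mvo2`, `mdo2`, `meo2`, `delta_po2`, `cvr`, ...), in
#' units of that metric per hour.
#'
#' @inheritParams lactate_trend
#' @param metric Snapshot column name.
#' @return A `trend_series`.
#' @export
snapshot_trend <- function(session, metric, window = 5, upto = Inf) {
  stopifnot(inherits(session, "perfusion_session"))
  d <- session$snapshots
  if (!metric %in% names(d)) stop("unknown snapshot metric: ", metric, call. = FALSE)
  d <- d[is.finite(d[[metric]]) & d$time <= upto, , drop = FALSE]
  trend_series(metric, d$time, d[[metric]], window)
}

# slope threshold for rising/falling, in metric units per hour
TREND_SLOPE_THRESHOLD <- 0.1

trend_series <- function(metric, time, value, window,
                         threshold = TREND_SLOPE_THRESHOLD) {
  if (length(time) > window) {
    keep <- utils::tail(order(time), window)
    time <- time[sort(keep)]; value <- value[sort(keep)]
  }
  n <- length(time)
  slope_h <- NA_real_
  direction <- NA_character_
  if (n >= 3) {
    slope_min <- stats::cov(time, value) / stats::var(time)  # per minute
    slope_h <- slope_min * 60
    direction <- if (slope_h > threshold) "rising"
                 else if (slope_h < -threshold) "falling" else "stable"
  }
  structure(list(metric = metric,
                 points = data.frame(time = time, value = value),
                 slope_per_h = slope_h, direction = direction),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("%s trend over %d points: %s", x$metric, nrow(x$points),
              if (is.na(x$direction)) "insufficient data (need >= 3 points)"
              else sprintf("%s (%+.2f per hour)", x$direction, x$slope_per_h)), "\n")
  invisible(x)
}

#' Electrolyte supplementation advisories
#'
#' Checks a sample's ionized calcium, bicarbonate (with pH as an acidosis
#' fallback) and potassium against the configured clinical bounds and emits
#' one advisory per analyte out of range. Absent analytes are skipped
#' silently. Free-text actions only; dosing is out of scope.
#'
#' @param sample A [blood_gas_sample()] (or list with the analyte fields).
#' @param thresholds An [advisory_thresholds()].
#' @return Data frame with columns `analyte`, `measured`, `threshold_low`,
#'   `threshold_high`, `action`; zero rows when everything is in range.
#' @export
#' @examples
#' s <- blood_gas_sample(60, "arterial", 350, 0.98, 9, ionized_ca = 0.9)
#' advise_electrolytes(s)
advise_electrolytes <- function(sample, thresholds = advisory_thresholds()) {
  s <- as.list(sample)
  out <- list()
  add <- function(analyte, measured, lo, hi, action) {
    out[[length(out) + 1L]] <<- data.frame(
      analyte = analyte, measured = measured, threshold_low = lo,
      threshold_high = hi, action = action, stringsAsFactors = FALSE)
  }
  ica <- s$ionized_ca
  if (!is.null(ica) && is.finite(ica) && ica < thresholds$ionized_calcium_low) {
    add("ionized_calcium", ica, thresholds$ionized_calcium_low, NA_real_,
        "ionized calcium low: consider calcium supplementation")
  }
  hco3 <- s$hco3; ph <- s$ph
  low_hco3 <- !is.null(hco3) && is.finite(hco3) && hco3 < thresholds$bicarbonate_low
  low_ph <- !is.null(ph) && is.finite(ph) && ph < thresholds$ph_low
  if (low_hco3 || low_ph) {
    add("bicarbonate",
        if (low_hco3) hco3 else ph,
        thresholds$bicarbonate_low, NA_real_,
        "metabolic acidosis: consider bicarbonate supplementation")
  }
  kv <- s$k
  if (!is.null(kv) && is.finite(kv) &&
      (kv < thresholds$potassium_low || kv > thresholds$potassium_high)) {
    add("potassium", kv, thresholds$potassium_low, thresholds$potassium_high,
        if (kv < thresholds$potassium_low)
          "potassium low: consider potassium supplementation"
        else "potassium high: consider dilution/correction")
  }
  if (!length(out)) {
    return(data.frame(analyte = character(0), measured = numeric(0),
                      threshold_low = numeric(0), threshold_high = numeric(0),
                      action = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tidy per-snapshot report of a session
#'
#' One row per metabolic snapshot carrying every derived metric, the
#' recommendation active at that snapshot and the lactate trend direction
#' using only data available up to that time.
#'
#' @param session A [perfusion_session()].
#' @param trend_window Points in the trend fit (see [lactate_trend()]).
#' @return Data frame, one row per snapshot.
#' @export
session_report <- function(session, trend_window = 5) {
  stopifnot(inherits(session, "perfusion_session"))
  sn <- session$snapshots
  if (!nrow(sn)) stop("no snapshots in session: nothing to report", call. = FALSE)
  recs <- session$recommendations
  rec_at <- function(t) {
    i <- which(!is.na(recs$time) & recs$time <= t)
    if (!length(i)) return(c(NA_real_, NA_real_))
    r <- recs[max(i), ]
    c(r$recommended_cbf, r$display_cbf)
  }
  rec_cols <- t(vapply(sn$time, rec_at, numeric(2)))
  trend <- vapply(sn$time, function(t) {
    tr <- lactate_trend(session, window = trend_window, upto = t)
    if (is.na(tr$direction)) NA_character_ else tr$direction
  }, character(1))
  out <- cbind(sn[, c("time", "cao2", "cvo2", "mdo2", "mvo2", "meo2",
                      "delta_po2", "cvr", "lactate", "cbf_used", "map_used",
                      "negative_extraction")],
               data.frame(recommended_cbf = rec_cols[, 1],
                          display_cbf = rec_cols[, 2],
                          lactate_trend = trend, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
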