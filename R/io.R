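# Fixed interchange schema: perfusionists export spreadsheets, and a fixed
# lower-snake header makes parsing bit-exact.
SAMPLE_LOG_COLUMNS <- c("time_min", "site", "po2_mmhg", "so2", "hb_g_dl",
                        "lactate_mmol_l", "ph", "hco3_mmol_l", "ica_mmol_l",
                        "k_mmol_l", "cbf_ml_min", "map_mmhg", "temp_c")

#' Write a blood-gas sample log
#'
#' CSV with the fixed header `time_min, site, po2_mmhg, so2, hb_g_dl,
#' lactate_mmol_l, ph, hco3_mmol_l, ica_mmol_l, k_mmol_l, cbf_ml_min,
#' map_mmhg, temp_c`; blank cells mean missing. Values are written with 15
#' significant digits so a write-then-read round trip reproduces the
#' in-memory state to numerical precision.
#'
#' @param log Data frame in the sample-log schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_log <- function(log, path) {
  missing_cols <- setdiff(SAMPLE_LOG_COLUMNS, names(log))
  if (length(missing_cols)) {
    stop("sample log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- log[, SAMPLE_LOG_COLUMNS, drop = FALSE]
  num <- setdiff(SAMPLE_LOG_COLUMNS, "site")
  for (cn in num) {
    v <- out[[cn]]
    out[[cn]] <- ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a blood-gas sample log
#'
#' Strict reader for the schema of [write_sample_log()]: the header must
#' match exactly, `site` must be `arterial`/`venous`, and all numeric cells
#' must parse as finite numbers or be blank. Malformed rows are dropped with
#' a warning naming the line number (header = line 1).
#'
#' @param path CSV path.
#' @return Data frame in the sample-log schema.
#' @export
read_sample_log <- function(path) {
  if (!file.exists(path)) stop("sample log not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), SAMPLE_LOG_COLUMNS)) {
    stop("sample log header mismatch; expected: ",
         paste(SAMPLE_LOG_COLUMNS, collapse = ","), call. = FALSE)
  }
  n <- nrow(raw)
  parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  out <- data.frame(time_min = parse_num(raw$time_min),
                    site = trimws(raw$site), stringsAsFactors = FALSE)
  for (cn in setdiff(SAMPLE_LOG_COLUMNS, c("time_min", "site"))) {
    out[[cn]] <- parse_num(raw[[cn]])
  }
  bad_site <- !out$site %in% c("arterial", "venous")
  bad_req <- !is.finite(out$time_min) | !is.finite(out$po2_mmhg) |
    !is.finite(out$so2) | !is.finite(out$hb_g_dl)
  bad <- bad_site | bad_req
  if (any(bad)) {
    for (i in which(bad)) {
      warning(sprintf("skipping malformed sample-log row at line %d", i + 1L),
              call. = FALSE)
    }
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Ingest all rows of a sample log into a session
#'
#' Rows are processed in time order. Rows carrying pump settings
#' (`cbf_ml_min`/`map_mmhg`/`temp_c`) update the settings history before the
#' sample is ingested. Duplicate samples are skipped with a warning; every
#' successful pairing yields a snapshot and an updated recommendation (see
#' [ingest_sample()]).
#'
#' @param session A [perfusion_session()].
#' @param log A sample-log data frame (from [read_sample_log()] or
#'   [simulate_run()]) or a path to one.
#' @param unit_hints Passed to [ingest_sample()].
#' @return The updated session.
#' @export
add_samples_from_log <- function(session, log, unit_hints = list()) {
  stopifnot(inherits(session, "perfusion_session"))
  if (is.character(log)) log <- read_sample_log(log)
  ord <- order(log$time_min, log$site)
  log <- log[ord, , drop = FALSE]
  for (i in seq_len(nrow(log))) {
    row <- log[i, ]
    if (is.finite(row$cbf_ml_min) || is.finite(row$map_mmhg) ||
        is.finite(row$temp_c)) {
      session <- set_settings(session, row$time_min,
                              cbf_ml_min = row$cbf_ml_min,
                              map_mmhg = row$map_mmhg, temp_c = row$temp_c)
    }
    raw <- list(time = row$time_min, site = row$site, po2 = row$po2_mmhg,
                so2 = row$so2, hb = row$hb_g_dl, lactate = row$lactate_mmol_l,
                ph = row$ph, hco3 = row$hco3_mmol_l,
                ionized_ca = row$ica_mmol_l, k = row$k_mmol_l)
    session <- tryCatch(ingest_sample(session, raw, unit_hints),
                        eshp_duplicate_error = function(e) {
                          warning(conditionMessage(e), call. = FALSE)
                          session
                        })
  }
  session
}

# JSON (de)serialization of the session. A session file is self-contained:
# it echoes the full configuration so a report is reproducible from the file
# alone.
session_to_list <- function(session) {
  list(format = "eshpflow-session", version = 1L,
       donor = list(sex = session$donor$sex,
                    body_weight = session$donor$body_weight,
                    measured_heart_weight = session$donor$measured_heart_weight),
       config = list(params = unclass(session$config$params),
                     constants = unclass(session$config$constants),
                     thresholds = unclass(session$config$thresholds),
                     pairing_tolerance = session$config$pairing_tolerance,
                     hb_gdl_per_mmoll = session$config$hb_gdl_per_mmoll,
                     settings = unclass(session$config$settings),
                     gas_flow = session$config$gas_flow,
                     gas_o2_fraction = session$config$gas_o2_fraction,
                     gas_co2_fraction = session$config$gas_co2_fraction),
       settings_history = session$settings_history,
       samples = session$samples,
       snapshots = session$snapshots,
       recommendations = session$recommendations)
}

#' Write a session to a JSON file
#'
#' @param session A [perfusion_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "perfusion_session"))
  json <- jsonlite::toJSON(session_to_list(session), dataframe = "columns",
                           digits = NA, na = "null", null = "null",
                           auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

restore_df <- function(cols, schema) {
  if (is.null(cols) || !length(cols)) return(schema)
  n <- max(vapply(cols, length, integer(1)), 0L)
  if (n == 0L) return(schema)
  # columns of all-nulls come back as lists; map null -> NA before coercion
  devec <- function(v) {
    if (is.null(v)) return(rep(NA, n))
    if (is.list(v)) {
      v <- unlist(lapply(v, function(e) if (is.null(e) || !length(e)) NA else e))
    }
    v
  }
  vals <- lapply(names(schema), function(cn) {
    v <- devec(cols[[cn]])
    if (is.logical(schema[[cn]])) as.logical(v)
    else if (is.character(schema[[cn]])) as.character(v)
    else if (is.integer(schema[[cn]])) as.integer(v)
    else as.numeric(v)
  })
  names(vals) <- names(schema)
  out <- as.data.frame(vals, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a session from a JSON file
#'
#' @param path Path written by [write_session()].
#' @return A [perfusion_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "eshpflow-session")) {
    stop("not an eshpflow session file: ", path, call. = FALSE)
  }
  donor <- donor_profile(x$donor$sex, x$donor$body_weight,
                         measured_heart_weight = x$donor$measured_heart_weight)
  cfg <- x$config
  config <- tool_config(
    params = do.call(oxygen_parameters, as.list(cfg$params)),
    constants = do.call(normalization_constants, as.list(cfg$constants)),
    thresholds = do.call(advisory_thresholds, as.list(cfg$thresholds)),
    pairing_tolerance = cfg$pairing_tolerance,
    hb_gdl_per_mmoll = cfg$hb_gdl_per_mmoll,
    settings = do.call(perfusion_settings, as.list(cfg$settings)),
    gas_flow = cfg$gas_flow, gas_o2_fraction = cfg$gas_o2_fraction,
    gas_co2_fraction = cfg$gas_co2_fraction)
  session <- perfusion_session(donor, config)
  session$settings_history <- restore_df(x$settings_history, .settings_schema())
  session$samples <- restore_df(x$samples, .sample_schema())
  session$snapshots <- restore_df(x$snapshots, .snapshot_schema())
  session$recommendations <- restore_df(x$recommendations,
                                        .recommendation_schema())
  session
}

#' Write a per-snapshot report CSV
#'
#' Serializes [session_report()] with full numeric precision; re-running on
#' an unchanged session yields a byte-identical file.
#'
#' @param session A [perfusion_session()].
#' @param path Output CSV path.
#' @param trend_window See [session_report()].
#' @return `path`, invisibly.
#' @export
write_report <- function(session, path, trend_window = 5) {
  rep <- session_report(session, trend_window = trend_window)
  num <- vapply(rep, is.numeric, logical(1))
  for (cn in names(rep)[num]) {
    v <- rep[[cn]]
    rep[[cn]] <- ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  }
  utils::write.csv(rep, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
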