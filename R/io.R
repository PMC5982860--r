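#' Read one recording from CSV
#'
#' Two schemas are accepted: `t_ms,ax,ay,az` (three-axis) or `t_ms,a`
#' (magnitude only). Values are in multiples of g unless `units = "m_s2"`,
#' in which case they are divided by 9.8. Parse problems are reported with
#' the offending line number.
#'
#' @param path CSV file path.
#' @param units `"g"` (default) or `"m_s2"`.
#' @param sampling_hz optional nominal rate; inferred from the timestamps
#'   when missing.
#' @param participant_id,label,recording_id optional metadata (usually taken
#'   from the manifest).
#' @return an [accel_ts]. Three-axis files get their magnitude channel
#'   populated on read.
#' @export
read_recording <- function(path, units = c("g", "m_s2"), sampling_hz = NULL,
                           participant_id = NA_character_,
                           label = NA_character_,
                           recording_id = basename(path)) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  three <- c("t_ms", "ax", "ay", "az"); mag <- c("t_ms", "a")
  schema <- if (all(three %in% names(df))) "axes"
            else if (all(mag %in% names(df))) "mag"
            else stop(sprintf(
              "%s: header must contain columns %s or %s (found: %s)", path,
              paste(three, collapse = ","), paste(mag, collapse = ","),
              paste(names(df), collapse = ",")))
  num_cols <- if (schema == "axes") three else mag
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("%s: non-numeric or missing value in column '%s' at line %d",
                   path, col, bad[1L] + 1L))
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) > 1L && any(diff(df$t_ms) <= 0)) {
    bad <- which(diff(df$t_ms) <= 0)[1L] + 1L
    stop(sprintf("%s: timestamps not strictly increasing at line %d",
                 path, bad + 1L))
  }
  conv <- if (units == "m_s2") 9.8 else 1
  ts <- if (schema == "axes")
    accel_ts(t = df$t_ms, ax = df$ax / conv, ay = df$ay / conv,
             az = df$az / conv, sampling_hz = sampling_hz,
             participant_id = participant_id, label = label,
             recording_id = recording_id)
  else
    accel_ts(t = df$t_ms, a = df$a / conv, sampling_hz = sampling_hz,
             participant_id = participant_id, label = label,
             recording_id = recording_id)
  if (is.null(ts$a)) ts <- to_magnitude(ts)
  ts
}

#' Write one recording to CSV
#'
#' Writes the three-axis schema when axis channels are present, otherwise
#' the magnitude schema. Always in multiples of g.
#'
#' @param ts an [accel_ts].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(ts, path) {
  stopifnot(inherits(ts, "accel_ts"))
  df <- if (!is.null(ts$ax))
    data.frame(t_ms = ts$t, ax = ts$ax, ay = ts$ay, az = ts$az)
  else data.frame(t_ms = ts$t, a = ts$a)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest maps recording files to participants and labels:
#' columns `file`, `participant_id`, `label` (`FALL` / `NOT_FALL`) and
#' `sampling_hz`.
#'
#' @param path manifest CSV path.
#' @return data.frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "participant_id", "label", "sampling_hz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("manifest %s lacks columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  bad <- which(!df$label %in% c("FALL", "NOT_FALL"))
  if (length(bad))
    stop(sprintf("manifest %s: invalid label '%s' at line %d",
                 path, df$label[bad[1L]], bad[1L] + 1L))
  df
}

#' @rdname read_manifest
#' @param manifest data.frame of manifest rows.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load every recording listed in a manifest
#'
#' @param path manifest CSV path; recording files are resolved relative to
#'   the manifest's directory unless absolute.
#' @param units passed to [read_recording()].
#' @return named list of [accel_ts].
#' @export
load_cohort <- function(path, units = c("g", "m_s2")) {
  units <- match.arg(units)
  man <- read_manifest(path)
  dir <- dirname(path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(dir, f)
    read_recording(f, units = units, sampling_hz = man$sampling_hz[i],
                   participant_id = man$participant_id[i],
                   label = man$label[i], recording_id = man$file[i])
  })
  names(out) <- man$file
  out
}

feature_file_columns <- function() {
  c(feature_names(), "pt", "is", "ie", "ps", "pe",
    "ie_defaulted", "is_defaulted", "ffi_defaulted", "aamv_degenerate",
    "label", "participant_id", "recording_id", "synthetic")
}

#' Write / read an event-feature dataset
#'
#' Lossless CSV round-trip of feature rows including anchors, fallback flags,
#' provenance and the `synthetic` marker added by [smote_balance()].
#'
#' @param features data.frame of feature rows.
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   data.frame.
#' @export
write_features <- function(features, path) {
  if (!("synthetic" %in% names(features)))
    features$synthetic <- rep(FALSE, nrow(features))
  cols <- intersect(feature_file_columns(), names(features))
  missing_cols <- setdiff(c(feature_names(), "label"), names(features))
  if (length(missing_cols))
    stop(sprintf("feature table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  utils::write.csv(features[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(feature_names(), "label"), names(df))
  if (length(missing_cols))
    stop(sprintf("feature file %s lacks columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (col in intersect(c("ie_defaulted", "is_defaulted", "ffi_defaulted",
                          "aamv_degenerate", "synthetic"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c("participant_id", "recording_id", "label"), names(df)))
    df[[col]] <- as.character(df[[col]])
  df
}

#' Default run configuration
#'
#' One nested list holding every tunable of the pipeline at its published
#' default: detection threshold and quiet period, the feature thresholds,
#' SMOTE balancing target, optimiser setting, cross-validation scheme and
#' classifier grids. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    peak = unclass(peak_config()),
    features = unclass(feature_thresholds()),
    balancing = list(target = 0.40, k = 5, seed = 1L),
    optimizer = c(unclass(opt_config()), list(runs = 10, algorithm = "SA")),
    cv = list(scheme = "five_two", holdout_frac = 0.15, k = 10),
    grids = list(
      NN = list(size = c(7, 20), decay = c(1e-6, 1e-4, 1e-3)),
      SVM = list(sigma = 0.2, C = c(0.7, 1.0, 4.5)),
      TREE = list(trials = c(1, 5, 10), cp = 0.01),
      RULES = list(trials = c(1, 5, 10), cp = 0.01)),
    seed = 1L), class = "run_config")
}

#' @rdname default_run_config
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  structure(yaml::read_yaml(path), class = "run_config")
}
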