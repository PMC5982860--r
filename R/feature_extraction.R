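#' Feature-extraction thresholds and window lengths
#'
#' All constants used to anchor a detected peak and compute the eight
#' fall-dynamics features. Magnitude thresholds are in multiples of g,
#' durations in ms. The defaults are the published wrist/waist values:
#' `th2` = 1.5 g ends the impact, `th3` = 0.8 g marks the free-fall dip,
#' `thPDI` = 1.8 g brackets the peak, the activity ratio counts samples
#' outside \[`thARI_low`, `thARI_high`\] = \[0.85, 1.3\] g, and `thFFI` =
#' 0.8 g locates the free-fall interval. `thSCI` and `sci_min_sep_ms`
#' parameterise the step counter (a local-maximum definition; see Details).
#'
#' @details The step-count index needs a definition of a "step peak": here a
#' local maximum of the magnitude strictly above `thSCI` (default 1.5 g, the
#' impact-end threshold), with counted maxima at least `sci_min_sep_ms`
#' (default 250 ms, i.e. a 4 Hz cadence ceiling) apart, counted greedily in
#' time order.
#'
#' @param th2 impact-end threshold (g).
#' @param th3 impact-start (free-fall) threshold (g).
#' @param thPDI peak-bound threshold (g).
#' @param thARI_low,thARI_high activity-ratio rest band (g); low < high.
#' @param thFFI free-fall threshold (g).
#' @param thSCI step-peak threshold (g).
#' @param ie_search_ms horizon after the peak searched for the impact end.
#' @param is_search_ms window before the impact end searched for the start.
#' @param mvi_lead_ms lead before the impact start for the valley search.
#' @param ari_window_ms width of the activity-ratio window.
#' @param ffi_lead_ms maximum lead before the peak for the free-fall search.
#' @param sci_window_ms width of the step-count window before the peak.
#' @param sci_min_sep_ms minimum separation between counted step peaks.
#' @return an object of class `feature_thresholds`.
#' @export
feature_thresholds <- function(th2 = 1.5, th3 = 0.8, thPDI = 1.8,
                               thARI_low = 0.85, thARI_high = 1.3,
                               thFFI = 0.8, thSCI = 1.5,
                               ie_search_ms = 1000, is_search_ms = 1200,
                               mvi_lead_ms = 500, ari_window_ms = 700,
                               ffi_lead_ms = 200, sci_window_ms = 2200,
                               sci_min_sep_ms = 250) {
  vals <- c(th2 = th2, th3 = th3, thPDI = thPDI, thARI_low = thARI_low,
            thARI_high = thARI_high, thFFI = thFFI, thSCI = thSCI,
            ie_search_ms = ie_search_ms, is_search_ms = is_search_ms,
            mvi_lead_ms = mvi_lead_ms, ari_window_ms = ari_window_ms,
            ffi_lead_ms = ffi_lead_ms, sci_window_ms = sci_window_ms,
            sci_min_sep_ms = sci_min_sep_ms)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds and durations must be positive and finite")
  if (thARI_low >= thARI_high) stop("thARI_low must be below thARI_high")
  structure(as.list(vals), class = "feature_thresholds")
}

#' Locate the impact end
#'
#' The impact end `ie` is the last time within `(pt, pt + ie_search_ms]` at
#' which the magnitude exceeds `th2`. When no sample in that horizon exceeds
#' `th2`, `ie` falls back to `pt + 1000` ms and the `ie_defaulted` flag is set.
#'
#' @param ts an [accel_ts] with magnitude present.
#' @param pt a detected peak time (ms) inside the recording.
#' @param thr a [feature_thresholds].
#' @return list with `ie` (ms) and logical `defaulted`.
#' @export
find_impact_end <- function(ts, pt, thr = feature_thresholds()) {
  stopifnot(inherits(ts, "accel_ts"))
  if (pt < ts$t[1L] || pt > ts$t[length(ts$t)])
    stop("pt lies outside the recording")
  idx <- which(ts$t > pt & ts$t <= pt + thr$ie_search_ms & ts$a > thr$th2)
  if (length(idx) == 0L)
    list(ie = pt + 1000, defaulted = TRUE)
  else
    list(ie = ts$t[idx[length(idx)]], defaulted = FALSE)
}

#' Locate the impact start
#'
#' Scanning forward from `max(ie - is_search_ms, start)` to `pt`, the impact
#' start `is` is the time of the first sample with magnitude at or below
#' `th3` (the free-fall dip) that is followed, no later than `ie`, by a
#' sample at or above `th2` (the impact). When no such pattern exists, `is`
#' falls back to `pt` and the `is_defaulted` flag is set.
#'
#' @param ts an [accel_ts] with magnitude present.
#' @param pt a detected peak time (ms).
#' @param ie the impact end (ms), from [find_impact_end()].
#' @param thr a [feature_thresholds].
#' @return list with `is` (ms) and logical `defaulted`.
#' @export
find_impact_start <- function(ts, pt, ie, thr = feature_thresholds()) {
  stopifnot(inherits(ts, "accel_ts"))
  lo <- max(ie - thr$is_search_ms, ts$t[1L])
  dip <- which(ts$t >= lo & ts$t <= pt & ts$a <= thr$th3)
  if (length(dip) > 0L) {
    high <- which(ts$t <= ie & ts$a >= thr$th2)
    t_last_high <- if (length(high)) ts$t[high[length(high)]] else -Inf
    ok <- dip[ts$t[dip] < t_last_high]
    if (length(ok) > 0L) return(list(is = ts$t[ok[1L]], defaulted = FALSE))
  }
  list(is = pt, defaulted = TRUE)
}

#' Bracket the peak with the peak-duration threshold
#'
#' `ps` is the time of the last sample before `pt` with magnitude below
#' `thPDI`; `pe` the time of the first such sample after `pt`. The recording
#' start/end are used when no such sample exists on that side.
#'
#' @inheritParams find_impact_end
#' @return list with `ps` and `pe` (ms).
#' @export
find_peak_bounds <- function(ts, pt, thr = feature_thresholds()) {
  stopifnot(inherits(ts, "accel_ts"))
  before <- which(ts$t < pt & ts$a < thr$thPDI)
  after  <- which(ts$t > pt & ts$a < thr$thPDI)
  list(ps = if (length(before)) ts$t[before[length(before)]] else ts$t[1L],
       pe = if (length(after)) ts$t[after[1L]] else ts$t[length(ts$t)])
}

# step-peak counter: local maxima above thSCI, >= min_sep apart (greedy)
count_step_peaks <- function(t, a, thSCI, min_sep) {
  n <- length(a)
  if (n == 0L) return(0L)
  left  <- c(TRUE, a[-1L] >= a[-n])
  right <- c(a[-n] >= a[-1L], TRUE)
  cand <- which(a > thSCI & left & right)
  if (length(cand) == 0L) return(0L)
  count <- 0L
  last_t <- -Inf
  for (i in cand) {
    if (t[i] - last_t >= min_sep) {
      count <- count + 1L
      last_t <- t[i]
    }
  }
  count
}

#' Compute the eight fall-dynamics features for one peak
#'
#' Anchors the event (`is`, `ie`, `ps`, `pe`) around the peak time `pt` and
#' computes, on the magnitude channel:
#' \describe{
#'   \item{AAMV}{mean absolute consecutive-sample magnitude change over
#'     \[is, ie\] (g per sample step); 0 with a flag when the window holds
#'     fewer than two samples.}
#'   \item{IDI}{impact duration `ie - is` (ms).}
#'   \item{MPI}{maximum magnitude over \[is, ie\] (g).}
#'   \item{MVI}{minimum magnitude over \[is - mvi_lead_ms, ie\] (g).}
#'   \item{PDI}{peak duration `pe - ps` (ms).}
#'   \item{ARI}{fraction of samples outside the rest band in the
#'     `ari_window_ms` window centred on `(is + ie) / 2`.}
#'   \item{FFI}{mean magnitude over \[tFFI, pt\], with `tFFI` the latest
#'     sample below `thFFI` in \[pt - ffi_lead_ms, pt) — the first one met
#'     scanning backward from the peak — falling back to `pt - ffi_lead_ms`
#'     (flagged) when none exists.}
#'   \item{SCI}{number of step peaks in \[pt - sci_window_ms, pt\].}
#' }
#' All windows are closed time intervals on timestamps and are clipped at the
#' recording boundaries.
#'
#' @param ts an [accel_ts] with magnitude present.
#' @param pt a detected peak time (ms).
#' @param thr a [feature_thresholds].
#' @return one-row data.frame with columns `AAMV`, `IDI`, `MPI`, `MVI`,
#'   `PDI`, `ARI`, `FFI`, `SCI`, the anchor times `pt`, `is`, `ie`, `ps`,
#'   `pe`, and logical flags `ie_defaulted`, `is_defaulted`, `ffi_defaulted`,
#'   `aamv_degenerate`.
#' @export
compute_features <- function(ts, pt, thr = feature_thresholds()) {
  stopifnot(inherits(ts, "accel_ts"))
  if (is.null(ts$a)) stop("magnitude channel missing")
  e <- find_impact_end(ts, pt, thr)
  s <- find_impact_start(ts, pt, e$ie, thr)
  b <- find_peak_bounds(ts, pt, thr)
  win <- function(lo, hi) which(ts$t >= lo & ts$t <= hi)

  imp <- win(s$is, e$ie)
  aamv_degenerate <- length(imp) < 2L
  AAMV <- if (aamv_degenerate) 0 else
    sum(abs(diff(ts$a[imp]))) / (length(imp) - 1L)
  IDI <- e$ie - s$is
  MPI <- max(ts$a[imp])
  MVI <- min(ts$a[win(s$is - thr$mvi_lead_ms, e$ie)])
  PDI <- b$pe - b$ps
  ctr <- (s$is + e$ie) / 2
  ari_idx <- win(ctr - thr$ari_window_ms / 2, ctr + thr$ari_window_ms / 2)
  ARI <- if (length(ari_idx) == 0L) 0 else
    mean(ts$a[ari_idx] < thr$thARI_low | ts$a[ari_idx] > thr$thARI_high)
  ffi_cand <- which(ts$t >= pt - thr$ffi_lead_ms & ts$t < pt & ts$a < thr$thFFI)
  ffi_defaulted <- length(ffi_cand) == 0L
  tFFI <- if (ffi_defaulted) pt - thr$ffi_lead_ms else ts$t[ffi_cand[length(ffi_cand)]]
  FFI <- mean(ts$a[win(tFFI, pt)])
  sci_idx <- win(pt - thr$sci_window_ms, pt)
  SCI <- count_step_peaks(ts$t[sci_idx], ts$a[sci_idx],
                          thr$thSCI, thr$sci_min_sep_ms)

  data.frame(AAMV = AAMV, IDI = IDI, MPI = MPI, MVI = MVI, PDI = PDI,
             ARI = ARI, FFI = FFI, SCI = as.numeric(SCI),
             pt = pt, is = s$is, ie = e$ie, ps = b$ps, pe = b$pe,
             ie_defaulted = e$defaulted, is_defaulted = s$defaulted,
             ffi_defaulted = ffi_defaulted, aamv_degenerate = aamv_degenerate)
}

#' Names of the eight event features
#' @return character vector of the feature column names.
#' @export
feature_names <- function() c("AAMV", "IDI", "MPI", "MVI", "PDI", "ARI", "FFI", "SCI")

#' Detect peaks and extract features for a whole recording
#'
#' Runs [detect_peaks()] and [compute_features()] for every peak, labelling
#' each feature row with the recording's label and provenance. Recordings
#' without any detected peak yield zero rows.
#'
#' @param ts an [accel_ts] with magnitude present.
#' @param config a [peak_config].
#' @param thr a [feature_thresholds].
#' @return data.frame with one row per detected peak: the eight features,
#'   anchors, flags, and `label`, `participant_id`, `recording_id`.
#' @export
extract_features <- function(ts, config = peak_config(),
                             thr = feature_thresholds()) {
  pts <- detect_peaks(ts, config)
  if (length(pts) == 0L) {
    out <- compute_features_empty()
  } else {
    out <- do.call(rbind, lapply(pts, function(p) compute_features(ts, p, thr)))
  }
  if (nrow(out)) {
    out$label <- ts$label
    out$participant_id <- ts$participant_id
    out$recording_id <- ts$recording_id
  }
  out
}

compute_features_empty <- function() {
  df <- data.frame(AAMV = numeric(0), IDI = numeric(0), MPI = numeric(0),
                   MVI = numeric(0), PDI = numeric(0), ARI = numeric(0),
                   FFI = numeric(0), SCI = numeric(0), pt = numeric(0),
                   is = numeric(0), ie = numeric(0), ps = numeric(0),
                   pe = numeric(0), ie_defaulted = logical(0),
                   is_defaulted = logical(0), ffi_defaulted = logical(0),
                   aamv_degenerate = logical(0))
  df$label <- character(0)
  df$participant_id <- character(0)
  df$recording_id <- character(0)
  df
}

#' Extract the labelled event dataset from a cohort of recordings
#'
#' Convenience wrapper applying [extract_features()] over a list of
#' recordings and binding the rows. Every extracted peak inherits its
#' recording's FALL / NOT_FALL label — including vigorous daily-living
#' peaks inside NOT_FALL recordings, which is what makes the downstream
#' classification problem non-trivial.
#'
#' @param recordings list of [accel_ts].
#' @param config a [peak_config].
#' @param thr a [feature_thresholds].
#' @return data.frame of feature rows (possibly zero rows).
#' @export
extract_cohort_features <- function(recordings, config = peak_config(),
                                    thr = feature_thresholds()) {
  rows <- lapply(recordings, extract_features, config = config, thr = thr)
  out <- do.call(rbind, c(rows, list(compute_features_empty())))
  rownames(out) <- NULL
  out
}
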