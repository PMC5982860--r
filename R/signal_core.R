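#' Accelerometer time series
#'
#' Container for one labelled recording from a triaxial accelerometer.
#' Timestamps are in milliseconds and must be strictly increasing;
#' acceleration is expressed in multiples of g (9.8 m/s^2). Either the three
#' axis channels, the magnitude channel, or both may be present.
#'
#' @param t numeric vector of timestamps in ms, strictly increasing.
#' @param a optional magnitude channel (g), non-negative.
#' @param ax,ay,az optional axis channels (g).
#' @param sampling_hz nominal sampling rate in Hz. Inferred from the median
#'   timestamp spacing when missing.
#' @param participant_id opaque participant identifier.
#' @param label `"FALL"` or `"NOT_FALL"` (or `NA` when unknown).
#' @param recording_id opaque recording identifier.
#' @return An object of class `accel_ts`: a list with fields `t`, `a`
#'   (possibly `NULL`), `ax`/`ay`/`az` (possibly `NULL`), `sampling_hz`,
#'   `participant_id`, `label`, `recording_id`.
#' @export
accel_ts <- function(t, a = NULL, ax = NULL, ay = NULL, az = NULL,
                     sampling_hz = NULL, participant_id = NA_character_,
                     label = NA_character_, recording_id = NA_character_) {
  t <- as.numeric(t)
  if (length(t) < 1L) stop("a recording needs at least one sample")
  if (anyNA(t) || any(!is.finite(t))) stop("non-finite timestamps")
  if (length(t) > 1L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stop(sprintf("timestamps must be strictly increasing (sample %d)", bad))
  }
  has_axes <- !is.null(ax) || !is.null(ay) || !is.null(az)
  if (has_axes && (is.null(ax) || is.null(ay) || is.null(az)))
    stop("all three axis channels (ax, ay, az) are required together")
  chk_chan <- function(x, name, nonneg = FALSE) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != length(t))
      stop(sprintf("channel '%s' length (%d) differs from timestamps (%d)",
                   name, length(x), length(t)))
    if (anyNA(x) || any(!is.finite(x)))
      stop(sprintf("non-finite samples in channel '%s'", name))
    if (nonneg && any(x < 0))
      stop("magnitude channel must be non-negative")
    x
  }
  a <- chk_chan(a, "a", nonneg = TRUE)
  ax <- chk_chan(ax, "ax"); ay <- chk_chan(ay, "ay"); az <- chk_chan(az, "az")
  if (is.null(a) && !has_axes) stop("provide either a magnitude or axis channels")
  if (!is.na(label) && !label %in% c("FALL", "NOT_FALL"))
    stop("label must be 'FALL' or 'NOT_FALL'")
  if (is.null(sampling_hz)) {
    sampling_hz <- if (length(t) > 1L) 1000 / stats::median(diff(t)) else NA_real_
  }
  if (!is.na(sampling_hz) && sampling_hz <= 0) stop("sampling_hz must be positive")
  structure(list(t = t, a = a, ax = ax, ay = ay, az = az,
                 sampling_hz = sampling_hz,
                 participant_id = as.character(participant_id),
                 label = as.character(label),
                 recording_id = as.character(recording_id)),
            class = "accel_ts")
}

#' @export
print.accel_ts <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<accel_ts> %d samples, %.6g-%.6g ms, %.4g Hz\n",
              n, x$t[1L], x$t[n], x$sampling_hz))
  cat(sprintf("  participant: %s  label: %s  recording: %s\n",
              x$participant_id, x$label, x$recording_id))
  cat(sprintf("  channels: %s\n",
              paste(c("a", "ax", "ay", "az")[!vapply(x[c("a","ax","ay","az")],
                                                     is.null, logical(1))],
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.accel_ts <- function(x) length(x$t)

#' Acceleration magnitude
#'
#' Euclidean norm of the three axis readings, `sqrt(ax^2 + ay^2 + az^2)`.
#' Vectorised over samples. A subject at rest reads approximately 1 g.
#'
#' @param ax,ay,az axis accelerations in multiples of g.
#' @return magnitude in multiples of g, same length as the inputs.
#' @examples
#' magnitude(0, 0, 1)     # 1: gravity along one axis
#' magnitude(0.6, 0.8, 0) # 1
#' @export
magnitude <- function(ax, ay, az) {
  if (anyNA(ax) || anyNA(ay) || anyNA(az) ||
      any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az)))
    stop("invalid sample: non-finite axis value")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Populate the magnitude channel of a recording
#'
#' Applies [magnitude()] per sample; timestamps and metadata are untouched.
#'
#' @param ts an [accel_ts] with the three axis channels present.
#' @return the same recording with the `a` channel filled in.
#' @export
to_magnitude <- function(ts) {
  stopifnot(inherits(ts, "accel_ts"))
  if (is.null(ts$ax)) stop("recording has no axis channels to take the magnitude of")
  ts$a <- magnitude(ts$ax, ts$ay, ts$az)
  ts
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation of every present channel onto a uniform grid at
#' `target_hz` spanning the original time range. The first timestamp is always
#' on the grid; the final original timestamp is appended when the span is not
#' an integer number of target periods, so both endpoints are preserved.
#'
#' @param ts an [accel_ts] with at least two samples.
#' @param target_hz target sampling rate in Hz, positive.
#' @return a resampled [accel_ts] with `sampling_hz = target_hz`.
#' @export
resample_ts <- function(ts, target_hz) {
  stopifnot(inherits(ts, "accel_ts"))
  if (length(ts$t) < 2L) stop("resampling needs at least two samples")
  if (!is.numeric(target_hz) || length(target_hz) != 1L || target_hz <= 0)
    stop("target_hz must be a positive number")
  step <- 1000 / target_hz
  grid <- seq(ts$t[1L], ts$t[length(ts$t)], by = step)
  last <- ts$t[length(ts$t)]
  if (max(grid) < last - 1e-9) grid <- c(grid, last)
  interp <- function(x) {
    if (is.null(x)) return(NULL)
    stats::approx(ts$t, x, xout = grid, method = "linear", rule = 2)$y
  }
  out <- ts
  out$t <- grid
  out$a <- interp(ts$a)
  if (!is.null(out$a)) out$a <- pmax(out$a, 0)
  out$ax <- interp(ts$ax); out$ay <- interp(ts$ay); out$az <- interp(ts$az)
  out$sampling_hz <- target_hz
  out
}

#' Slice a closed time window out of a recording
#'
#' Keeps the samples with `t_start <= t <= t_end`; both endpoints are included
#' when a sample lands exactly on them. The result may have zero samples,
#' which is not an error.
#'
#' @param ts an [accel_ts].
#' @param t_start,t_end window bounds in ms, `t_start <= t_end`.
#' @return an [accel_ts] restricted to the window (possibly with zero
#'   samples; such degenerate slices are legal only as slice results).
#' @export
slice_window <- function(ts, t_start, t_end) {
  stopifnot(inherits(ts, "accel_ts"))
  if (t_start > t_end) stop("t_start must not exceed t_end")
  keep <- ts$t >= t_start & ts$t <= t_end
  out <- ts
  out$t <- ts$t[keep]
  for (ch in c("a", "ax", "ay", "az"))
    if (!is.null(ts[[ch]])) out[[ch]] <- ts[[ch]][keep]
  out
}

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
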