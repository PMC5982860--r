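#' Template for a synthetic fall recording
#'
#' Encodes the canonical magnitude trajectory of a fall as seen by a worn
#' accelerometer: a baseline around 1 g, a sub-gravity free-fall dip, a sharp
#' impact peak, and an exponential settling back to baseline. All magnitudes
#' in multiples of g, durations in ms.
#'
#' @param baseline resting magnitude, default 1 g.
#' @param dip_level free-fall dip level, default 0.5 g (below the 0.8 g
#'   free-fall threshold so the impact start is locatable).
#' @param dip_ms dip duration, default 300 ms.
#' @param impact_peak impact apex magnitude, default 3.5 g (above the 3 g
#'   peak threshold so noise-free falls are always detected).
#' @param impact_ms rise time from dip to apex, default 80 ms.
#' @param settle_start magnitude right after the apex, default 2.5 g; must
#'   stay below the peak threshold so the apex is the last exceedance.
#' @param settle_ms settling duration, default 800 ms.
#' @param settle_tau exponential settling time constant, default 150 ms.
#' @param pre_ms pre-fall activity duration, default 3000 ms (long enough to
#'   fill the step-count window).
#' @param post_ms post-settle baseline tail, default 1500 ms.
#' @param pre_activity `"STILL"` or `"WALKING"` before the fall.
#' @param noise_sigma i.i.d. Gaussian magnitude noise (g), default 0.05.
#' @param sampling_hz sampling rate, default 100 Hz.
#' @return an object of class `fall_template`.
#' @export
fall_template <- function(baseline = 1.0, dip_level = 0.5, dip_ms = 300,
                          impact_peak = 3.5, impact_ms = 80,
                          settle_start = 2.5, settle_ms = 800,
                          settle_tau = 150, pre_ms = 3000, post_ms = 1500,
                          pre_activity = c("STILL", "WALKING"),
                          noise_sigma = 0.05, sampling_hz = 100) {
  pre_activity <- match.arg(pre_activity)
  if (!(dip_level < baseline && baseline < impact_peak))
    stop("need dip_level < baseline < impact_peak")
  if (settle_start >= impact_peak) stop("settle_start must be below impact_peak")
  durs <- c(dip_ms, impact_ms, settle_ms, pre_ms, post_ms, settle_tau)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (sampling_hz <= 0) stop("sampling_hz must be positive")
  structure(list(baseline = baseline, dip_level = dip_level, dip_ms = dip_ms,
                 impact_peak = impact_peak, impact_ms = impact_ms,
                 settle_start = settle_start, settle_ms = settle_ms,
                 settle_tau = settle_tau, pre_ms = pre_ms, post_ms = post_ms,
                 pre_activity = pre_activity, noise_sigma = noise_sigma,
                 sampling_hz = sampling_hz),
            class = "fall_template")
}

#' Template for a synthetic activity-of-daily-living recording
#'
#' Five activity kinds spanning the negative class: `SITTING` (baseline plus
#' noise), `WALKING` (sinusoid at step frequency), `RUNNING` and `JUMPING`
#' (periodic impact bursts — jumping defaults to 3.6 g peaks, above the
#' detection threshold, to generate false-alarm candidates), and `SEIZURE`
#' (sustained high-frequency shaking mimicking partial tonic-clonic
#' seizures).
#'
#' @param kind activity kind.
#' @param duration_ms recording length, default 8000 ms.
#' @param walk_freq_hz step frequency for WALKING, default 2 Hz.
#' @param walk_amp walking sinusoid amplitude, default 0.3 g (at most 0.4 g).
#' @param burst_peak burst apex for RUNNING/JUMPING; defaults 2.0 g and
#'   3.6 g respectively, capped at 4 g.
#' @param burst_freq_hz burst rate; defaults 2.5 Hz (RUNNING) and 1 Hz
#'   (JUMPING).
#' @param burst_width_ms width of each burst, default 120 ms.
#' @param seizure_freq_hz shaking frequency, default 6 Hz.
#' @param seizure_amp shaking amplitude, default 0.5 g.
#' @param noise_sigma Gaussian magnitude noise (g), default 0.05.
#' @param sampling_hz sampling rate, default 100 Hz.
#' @return an object of class `adl_template`.
#' @export
adl_template <- function(kind = c("SITTING", "WALKING", "RUNNING", "JUMPING",
                                  "SEIZURE"),
                         duration_ms = 8000, walk_freq_hz = 2, walk_amp = 0.3,
                         burst_peak = NULL, burst_freq_hz = NULL,
                         burst_width_ms = 120, seizure_freq_hz = 6,
                         seizure_amp = 0.5, noise_sigma = 0.05,
                         sampling_hz = 100) {
  kind <- match.arg(kind)
  burst_peak <- burst_peak %||% switch(kind, RUNNING = 2.0, JUMPING = 3.6, 1.0)
  burst_freq_hz <- burst_freq_hz %||% switch(kind, RUNNING = 2.5, JUMPING = 1.0, 1.0)
  if (burst_peak > 4) stop("burst_peak is capped at 4 g")
  if (walk_amp > 0.4) stop("walk_amp is capped at 0.4 g")
  if (duration_ms <= 0 || sampling_hz <= 0 || noise_sigma < 0)
    stop("invalid duration, rate or noise level")
  structure(list(kind = kind, duration_ms = duration_ms,
                 walk_freq_hz = walk_freq_hz, walk_amp = walk_amp,
                 burst_peak = burst_peak, burst_freq_hz = burst_freq_hz,
                 burst_width_ms = burst_width_ms,
                 seizure_freq_hz = seizure_freq_hz, seizure_amp = seizure_amp,
                 noise_sigma = noise_sigma, sampling_hz = sampling_hz),
            class = "adl_template")
}

add_noise <- function(a, sigma) {
  if (sigma > 0) a <- a + stats::rnorm(length(a), 0, sigma)
  pmax(a, 0)
}

# optional random-orientation 3-axis decomposition of a magnitude trace
decompose_axes <- function(a) {
  u <- stats::rnorm(3L)
  u <- u / sqrt(sum(u^2))
  list(ax = a * u[1L], ay = a * u[2L], az = a * u[3L])
}

#' Generate one synthetic fall recording
#'
#' Builds the magnitude trace segment by segment on the sampling grid:
#' pre-fall activity, dip, linear rise to the impact apex, exponential
#' settling starting below the peak-detection threshold (so with zero noise
#' the apex is the unique detected peak), then a baseline tail. Gaussian
#' noise is added and the trace clipped at 0.
#'
#' @param tmpl a [fall_template].
#' @param seed integer seed.
#' @param participant_id,recording_id provenance strings.
#' @param axes if `TRUE`, also synthesise a random fixed-orientation 3-axis
#'   decomposition of the magnitude.
#' @return list with `series` (an [accel_ts] labelled FALL) and `truth`
#'   (list: `t_impact` apex time, `dip_start`, `dip_end`, all ms).
#' @export
generate_fall <- function(tmpl = fall_template(), seed = 1L,
                          participant_id = "P1", recording_id = "R1",
                          axes = FALSE) {
  stopifnot(inherits(tmpl, "fall_template"))
  dt <- 1000 / tmpl$sampling_hz
  n_of <- function(ms) max(1L, round(ms / dt))
  n_pre <- n_of(tmpl$pre_ms); n_dip <- n_of(tmpl$dip_ms)
  n_rise <- n_of(tmpl$impact_ms); n_settle <- n_of(tmpl$settle_ms)
  n_post <- n_of(tmpl$post_ms)

  pre_t <- (seq_len(n_pre) - 1L) * dt
  pre <- if (tmpl$pre_activity == "WALKING")
    tmpl$baseline + 0.3 * sin(2 * pi * 2 * pre_t / 1000)
  else rep(tmpl$baseline, n_pre)
  dip <- rep(tmpl$dip_level, n_dip)
  rise <- tmpl$dip_level +
    (tmpl$impact_peak - tmpl$dip_level) * seq_len(n_rise) / n_rise
  settle <- tmpl$baseline + (tmpl$settle_start - tmpl$baseline) *
    exp(-(seq_len(n_settle) * dt) / tmpl$settle_tau)
  post <- rep(tmpl$baseline, n_post)

  a0 <- c(pre, dip, rise, settle, post)
  t <- (seq_along(a0) - 1L) * dt
  apex_idx <- n_pre + n_dip + n_rise
  out <- with_seed(seed, {
    a <- add_noise(a0, tmpl$noise_sigma)
    ax3 <- if (axes) decompose_axes(a) else list(ax = NULL, ay = NULL, az = NULL)
    list(a = a, ax3 = ax3)
  })
  series <- accel_ts(t = t, a = out$a, ax = out$ax3$ax, ay = out$ax3$ay,
                     az = out$ax3$az, sampling_hz = tmpl$sampling_hz,
                     participant_id = participant_id, label = "FALL",
                     recording_id = recording_id)
  list(series = series,
       truth = list(t_impact = t[apex_idx],
                    dip_start = t[n_pre + 1L],
                    dip_end = t[n_pre + n_dip]))
}

#' Generate one synthetic activity-of-daily-living recording
#'
#' @param tmpl an [adl_template].
#' @param seed integer seed.
#' @param participant_id,recording_id provenance strings.
#' @param axes as in [generate_fall()].
#' @return an [accel_ts] labelled NOT_FALL.
#' @export
generate_adl <- function(tmpl = adl_template(), seed = 1L,
                         participant_id = "P1", recording_id = "R1",
                         axes = FALSE) {
  stopifnot(inherits(tmpl, "adl_template"))
  dt <- 1000 / tmpl$sampling_hz
  n <- max(2L, round(tmpl$duration_ms / dt))
  t <- (seq_len(n) - 1L) * dt
  a0 <- switch(tmpl$kind,
    SITTING = rep(1, n),
    WALKING = 1 + tmpl$walk_amp * sin(2 * pi * tmpl$walk_freq_hz * t / 1000),
    RUNNING = ,
    JUMPING = {
      period <- 1000 / tmpl$burst_freq_hz
      phase <- t %% period
      # triangular burst of burst_width_ms at the start of each period
      w <- tmpl$burst_width_ms
      tri <- pmax(0, 1 - abs(phase - w / 2) / (w / 2))
      1 + (tmpl$burst_peak - 1) * tri
    },
    SEIZURE = 1 + tmpl$seizure_amp * sin(2 * pi * tmpl$seizure_freq_hz * t / 1000))
  out <- with_seed(seed, {
    a <- add_noise(a0, tmpl$noise_sigma)
    ax3 <- if (axes) decompose_axes(a) else list(ax = NULL, ay = NULL, az = NULL)
    list(a = a, ax3 = ax3)
  })
  accel_ts(t = t, a = out$a, ax = out$ax3$ax, ay = out$ax3$ay, az = out$ax3$az,
           sampling_hz = tmpl$sampling_hz, participant_id = participant_id,
           label = "NOT_FALL", recording_id = recording_id)
}

#' Generate a labelled multi-participant cohort
#'
#' Emulates the structure of the public fall/ADL corpora: several
#' participants, several recordings each at (possibly mixed) sampling rates,
#' a fixed share of falls per participant and a rotation of daily-living
#' activities for the rest. Each participant receives a multiplicative
#' "style" perturbation (±20% on impact peak and dip depth), emulating
#' between-subject differences such as cautious, slower falls, so
#' participant-wise cross-validation faces genuine subject structure.
#'
#' @param n_participants number of participants (>= 2).
#' @param recordings_per_participant recordings per participant.
#' @param fall_fraction share of each participant's recordings that are
#'   falls; `round(fall_fraction * recordings_per_participant)` per
#'   participant.
#' @param rate_set sampling rates (Hz) cycled over participants.
#' @param seed integer seed; the manifest layout is seed-invariant, the
#'   noise realisations are not.
#' @param fall_tmpl,adl_kinds base fall template and ADL kind rotation.
#' @param noise_sigma noise level applied to every recording.
#' @return list with `recordings` (named list of [accel_ts]), `manifest`
#'   (data.frame: `recording_id`, `participant_id`, `label`, `kind`,
#'   `sampling_hz`, `dataset`) and `truth` (named list of fall ground-truth
#'   annotations).
#' @export
generate_cohort <- function(n_participants = 20, recordings_per_participant = 10,
                            fall_fraction = 0.3, rate_set = c(100, 50, 20),
                            seed = 1L, fall_tmpl = fall_template(),
                            adl_kinds = c("SITTING", "WALKING", "JUMPING",
                                          "SEIZURE", "RUNNING"),
                            noise_sigma = 0.05) {
  if (n_participants < 2L) stop("need at least 2 participants")
  n_fall <- round(fall_fraction * recordings_per_participant)
  recordings <- list(); truth <- list(); rows <- list()
  n_rec <- n_participants * recordings_per_participant
  init <- with_seed(seed, list(
    styles = data.frame(peak = stats::runif(n_participants, 0.8, 1.2),
                        dip = stats::runif(n_participants, 0.8, 1.2)),
    rec_seeds = sample.int(.Machine$integer.max - 1L, n_rec)))
  styles <- init$styles
  k <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    hz <- rate_set[(p - 1L) %% length(rate_set) + 1L]
    for (r in seq_len(recordings_per_participant)) {
      rid <- sprintf("%s_R%02d", pid, r)
      k <- k + 1L
      rec_seed <- init$rec_seeds[k]
      if (r <= n_fall) {
        tf <- fall_tmpl
        tf$impact_peak <- max(tf$baseline + 0.5, tf$impact_peak * styles$peak[p])
        tf$dip_level <- min(0.79, tf$dip_level * styles$dip[p])
        tf$settle_start <- min(tf$settle_start, tf$impact_peak - 0.1)
        tf$noise_sigma <- noise_sigma
        tf$sampling_hz <- hz
        g <- generate_fall(tf, seed = rec_seed, participant_id = pid,
                           recording_id = rid)
        recordings[[rid]] <- g$series
        truth[[rid]] <- g$truth
        kind <- "FALL"
      } else {
        kind <- adl_kinds[(r - n_fall - 1L) %% length(adl_kinds) + 1L]
        ta <- adl_template(kind = kind, noise_sigma = noise_sigma,
                           sampling_hz = hz)
        recordings[[rid]] <- generate_adl(ta, seed = rec_seed,
                                          participant_id = pid,
                                          recording_id = rid)
      }
      rows[[rid]] <- data.frame(recording_id = rid, participant_id = pid,
                                label = if (kind == "FALL") "FALL" else "NOT_FALL",
                                kind = kind, sampling_hz = hz,
                                dataset = "synthetic")
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(recordings = recordings, manifest = manifest, truth = truth)
}
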