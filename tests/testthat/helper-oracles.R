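# Independent reference implementations used to cross-check the package.
# These deliberately take the naive route (explicit scans, materialised
# windows) and share no code with the implementations they verify.

# brute-force peak scan: a sample above th1 is a peak iff no later sample
# within quiet_ms is also above th1
oracle_detect_peaks <- function(t, a, th1 = 3.0, quiet_ms = 2500,
                                burst = "last") {
  out <- numeric(0)
  for (i in seq_along(a)) {
    if (a[i] <= th1) next
    if (burst == "last") {
      later <- which(t > t[i] & t <= t[i] + quiet_ms)
      if (!any(a[later] > th1)) out <- c(out, t[i])
    } else {
      earlier <- which(t >= t[i] - quiet_ms & t < t[i])
      if (!any(a[earlier] > th1)) out <- c(out, t[i])
    }
  }
  out
}

# window-materialising recomputation of the eight features for one peak
oracle_features <- function(ts, pt, thr = wristfall::feature_thresholds()) {
  t <- ts$t; a <- ts$a
  mat <- function(lo, hi) {
    keep <- t >= lo & t <= hi
    list(t = t[keep], a = a[keep])
  }
  # impact end: last sample above th2 in (pt, pt + horizon]
  seg <- mat(pt, pt + thr$ie_search_ms)
  high <- seg$t[seg$t > pt & seg$a > thr$th2]
  ie <- if (length(high)) max(high) else pt + 1000
  # impact start: first dip sample in [ie - window, pt] later followed
  # (not after ie) by a sample at or above th2
  seg <- mat(max(ie - thr$is_search_ms, t[1]), pt)
  is_ <- pt
  for (j in seq_along(seg$t)) {
    if (seg$a[j] > thr$th3) next
    followers <- which(t > seg$t[j] & t <= ie & a >= thr$th2)
    if (length(followers)) { is_ <- seg$t[j]; break }
  }
  # peak bounds around pt at thPDI
  lows_before <- t[t < pt & a < thr$thPDI]
  lows_after <- t[t > pt & a < thr$thPDI]
  ps <- if (length(lows_before)) max(lows_before) else t[1]
  pe <- if (length(lows_after)) min(lows_after) else t[length(t)]

  imp <- mat(is_, ie)
  aamv <- if (length(imp$a) < 2) 0 else {
    s <- 0
    for (j in seq_len(length(imp$a) - 1)) s <- s + abs(imp$a[j + 1] - imp$a[j])
    s / (length(imp$a) - 1)
  }
  mvi_win <- mat(is_ - thr$mvi_lead_ms, ie)
  ctr <- (is_ + ie) / 2
  ari_win <- mat(ctr - thr$ari_window_ms / 2, ctr + thr$ari_window_ms / 2)
  ari <- if (length(ari_win$a) == 0) 0 else {
    outside <- sum(ari_win$a < thr$thARI_low | ari_win$a > thr$thARI_high)
    outside / length(ari_win$a)
  }
  dips <- t[t >= pt - thr$ffi_lead_ms & t < pt & a < thr$thFFI]
  tffi <- if (length(dips)) max(dips) else pt - thr$ffi_lead_ms
  ffi_win <- mat(tffi, pt)
  # step peaks: local maxima above thSCI, kept greedily >= min separation
  sci_win <- mat(pt - thr$sci_window_ms, pt)
  sci <- 0; last_kept <- -Inf
  for (j in seq_along(sci_win$a)) {
    v <- sci_win$a[j]
    if (v <= thr$thSCI) next
    left_ok <- j == 1 || sci_win$a[j - 1] <= v
    right_ok <- j == length(sci_win$a) || sci_win$a[j + 1] <= v
    if (left_ok && right_ok && sci_win$t[j] - last_kept >= thr$sci_min_sep_ms) {
      sci <- sci + 1; last_kept <- sci_win$t[j]
    }
  }
  c(AAMV = aamv, IDI = ie - is_, MPI = max(imp$a), MVI = min(mvi_win$a),
    PDI = pe - ps, ARI = ari, FFI = mean(ffi_win$a), SCI = sci)
}

# random magnitude trace: noisy baseline with sparse super-threshold spikes
random_trace <- function(seed, min_n = 200, max_n = 2000) {
  set.seed(seed)
  n <- sample(min_n:max_n, 1)
  hz <- sample(c(16, 20, 50, 100, 204.8), 1)
  t <- (seq_len(n) - 1) * 1000 / hz
  a <- pmax(0, 1 + stats::rnorm(n, 0, 0.15))
  n_spikes <- sample(0:8, 1)
  if (n_spikes > 0) {
    at <- sample(n, n_spikes)
    a[at] <- a[at] + stats::runif(n_spikes, 1.5, 4)
  }
  wristfall::accel_ts(t = t, a = a, sampling_hz = hz,
                      participant_id = "PX", label = "NOT_FALL",
                      recording_id = sprintf("trace%d", seed))
}

# published end-to-end validation tallies (three thresholds x four models)
# and the statistics they are reported to yield. The RBS/2.5 true-negative
# count is printed as 245 in the source table, which is inconsistent with the
# cohort size every other row implies (309) and with the row's own published
# statistics; the corrected value 255 (stored in the fixture) reproduces all
# six statistics to four decimals.
validation_tables <- function() {
  cm <- utils::read.csv(system.file("extdata",
                                    "validation_confusion_matrices.csv",
                                    package = "wristfall"))
  expected <- utils::read.csv(text = "threshold,model,Acc,Kp,Se,Sp,Pr,G
2.5,NN,0.8414,0.2412,0.8333,0.8418,0.1754,0.8375
2.5,DT,0.9288,0.4454,0.8333,0.9327,0.3333,0.8816
2.5,RBS,0.8576,0.2662,0.8333,0.8586,0.1923,0.8459
2.5,SVM,0.9288,0.3886,0.6667,0.9394,0.3077,0.7914
3.0,NN,0.8317,0.2679,1.0000,0.8249,0.1875,0.9082
3.0,DT,0.9385,0.5096,0.9167,0.9394,0.3793,0.9280
3.0,RBS,0.9029,0.3864,0.9167,0.9024,0.2750,0.9095
3.0,SVM,0.9547,0.5664,0.8333,0.9596,0.4545,0.8942
3.09290,NN,0.8091,0.2386,1.0000,0.8013,0.1690,0.8952
3.09290,DT,0.9126,0.4146,0.9167,0.9125,0.2973,0.9146
3.09290,RBS,0.8867,0.3677,1.0000,0.8822,0.2553,0.9392
3.09290,SVM,0.9515,0.5484,0.8333,0.9562,0.4348,0.8927")
  list(cm = cm, expected = expected)
}

# cohort whose fall impacts all exceed 3.1 g while every other recording
# stays below: detection fitness is exactly 1 on [2, 3.1)
separable_cohort <- function(n_falls = 10, n_adls = 10, seed = 1) {
  falls <- lapply(seq_len(n_falls), function(i)
    wristfall::generate_fall(
      wristfall::fall_template(impact_peak = 3.3, noise_sigma = 0.02,
                               sampling_hz = 50),
      seed = seed + i, participant_id = sprintf("P%02d", i),
      recording_id = sprintf("F%02d", i))$series)
  kinds <- c("SITTING", "WALKING", "SEIZURE")
  adls <- lapply(seq_len(n_adls), function(i)
    wristfall::generate_adl(
      wristfall::adl_template(kinds[(i - 1) %% 3 + 1], noise_sigma = 0.02,
                              sampling_hz = 50, duration_ms = 6000),
      seed = seed + 1000 + i, participant_id = sprintf("P%02d", n_falls + i),
      recording_id = sprintf("A%02d", i)))
  c(falls, adls)
}

# random labelled feature rows for classifier / balancing / comparison tests
random_feature_rows <- function(n, label, seed, shift = 0) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 8, mean = shift), n, 8,
              dimnames = list(NULL, wristfall::feature_names()))
  df <- as.data.frame(x)
  df$label <- label
  df$participant_id <- sprintf("P%02d", sample(8, n, replace = TRUE))
  df$recording_id <- sprintf("R%04d", seq_len(n))
  df
}
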