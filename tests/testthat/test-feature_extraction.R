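# hand-built 100 Hz traces around a peak at a known time
flat_with <- function(mod, n = 600, hz = 100) {
  a <- rep(1, n)
  for (nm in names(mod)) a[as.integer(nm)] <- mod[[nm]]
  accel_ts(t = (seq_len(n) - 1) * 1000 / hz, a = a, sampling_hz = hz,
           label = "FALL")
}

test_that("impact end falls back to pt + 1000 when nothing stays high", {
  ts <- flat_with(list(`101` = 3.5))          # lone spike at t = 1000
  e <- find_impact_end(ts, 1000)
  expect_equal(e$ie, 2000)
  expect_true(e$defaulted)

  # samples at 2 g up to pt + 300 then quiet
  ts <- flat_with(as.list(setNames(rep(2, 30), 102:131)))  # 1010..1300 ms
  ts$a[101] <- 3.5
  e <- find_impact_end(ts, 1000)
  expect_equal(e$ie, 1300)
  expect_false(e$defaulted)

  # high samples beyond the search horizon are ignored
  ts <- flat_with(list(`101` = 3.5, `215` = 2.0))  # 2140 ms > pt + 1000
  expect_true(find_impact_end(ts, 1000)$defaulted)
  expect_error(find_impact_end(ts, 1e9), "outside")
})

test_that("impact start finds the dip-then-impact pattern inside its window", {
  # dip to 0.5 at pt - 350 followed by the impact, with a short 2 g tail
  # after the peak so the impact end (and hence the search window) is tight
  ts <- flat_with(c(list(`66` = 0.5, `101` = 3.5),
                    as.list(setNames(rep(2, 10), 102:111))))
  e <- find_impact_end(ts, 1000)
  expect_equal(e$ie, 1100)
  s <- find_impact_start(ts, 1000, e$ie)
  expect_equal(s$is, 650)
  expect_false(s$defaulted)

  # no sub-threshold sample at all: defaults to pt
  ts <- flat_with(list(`101` = 3.5))
  s <- find_impact_start(ts, 1000, find_impact_end(ts, 1000)$ie)
  expect_equal(s$is, 1000)
  expect_true(s$defaulted)

  # a dip before ie - 1200 is outside the window and must not count
  ts <- flat_with(list(`30` = 0.5, `101` = 3.5))   # dip at 290 ms
  e <- find_impact_end(ts, 1000)                   # ie = 2000 (defaulted)
  expect_gt(e$ie - 1200, 290)
  s <- find_impact_start(ts, 1000, e$ie)
  expect_true(s$defaulted)
})

test_that("peak bounds bracket the super-threshold region", {
  ts <- flat_with(list(`101` = 3.5))
  b <- find_peak_bounds(ts, 1000)
  expect_equal(c(b$ps, b$pe), c(990, 1010))  # one-sample spike: 20 ms apart

  # 2 g plateau for 500 ms around the peak stays above thPDI = 1.8
  ts <- flat_with(c(as.list(setNames(rep(2, 51), 76:126)), list(`101` = 3.5)))
  b <- find_peak_bounds(ts, 1000)
  expect_equal(b$ps, 740)   # last sub-1.8 sample before the plateau
  expect_equal(b$pe, 1260)  # first sub-1.8 sample after it

  # spike on the first sample: recording start is the fallback
  a <- rep(1, 300); a[1] <- 3.5
  ts <- accel_ts(t = (0:299) * 10, a = a, sampling_hz = 100, label = "FALL")
  expect_equal(find_peak_bounds(ts, 0)$ps, 0)
})

test_that("features on constant and degenerate windows take their closed forms", {
  ts <- flat_with(list(`101` = 3.5))
  f <- compute_features(ts, 1000)
  # is defaults to pt, ie to pt + 1000: the impact window is flat at 1 g
  # except the peak sample itself
  expect_equal(f$IDI, 1000)
  expect_equal(f$MPI, 3.5)
  expect_equal(f$MVI, 1)
  expect_true(f$ie_defaulted & f$is_defaulted)

  # fully constant impact window: AAMV 0, ARI 0 (1 g is inside the rest band)
  ts2 <- flat_with(list())
  ts2$a[101] <- 3.5; ts2$a[66] <- 0.5; ts2$a[102:111] <- 2
  f2 <- compute_features(ts2, 1000)
  expect_equal(f2$is, 650)
  win <- ts2$a[ts2$t >= 650 & ts2$t <= f2$ie]
  expect_equal(f2$AAMV, sum(abs(diff(win))) / (length(win) - 1))
  expect_true(f2$ARI >= 0 && f2$ARI <= 1)
  expect_equal(f2$MVI, 0.5)
})

test_that("a walking run-up yields step counts and all features stay finite", {
  hz <- 100
  t <- (0:699) * 10
  a <- 1 + 0.8 * pmax(0, sin(2 * pi * 2 * t / 1000))  # 2 Hz steps to 1.8 g
  a[601] <- 3.5
  ts <- accel_ts(t = t, a = a, sampling_hz = hz, label = "FALL")
  f <- compute_features(ts, 6000)
  expect_gte(f$SCI, 2)
  expect_true(all(is.finite(unlist(f[1, feature_names()]))))
  expect_true(f$ARI >= 0 && f$ARI <= 1)
  expect_lte(f$MVI, f$MPI)
})

test_that("features are invariant under time translation", {
  g <- generate_fall(fall_template(noise_sigma = 0.03), seed = 9)
  ts <- g$series
  shifted <- accel_ts(t = ts$t + 123456, a = ts$a, sampling_hz = ts$sampling_hz,
                      label = ts$label)
  p1 <- detect_peaks(ts); p2 <- detect_peaks(shifted)
  expect_equal(p2, p1 + 123456)
  f1 <- compute_features(ts, p1[1])
  f2 <- compute_features(shifted, p2[1])
  expect_equal(f2[, feature_names()], f1[, feature_names()])
})

test_that("extraction over a cohort labels rows with provenance", {
  coh <- generate_cohort(n_participants = 3, recordings_per_participant = 4,
                         fall_fraction = 0.5, rate_set = 50, seed = 21)
  feats <- extract_cohort_features(coh$recordings)
  expect_true(nrow(feats) >= 6)  # every fall produces at least one event
  expect_true(all(feats$label %in% c("FALL", "NOT_FALL")))
  expect_true(all(feats$participant_id %in% coh$manifest$participant_id))
  expect_true(all(feats$MVI <= feats$MPI))
})
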