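test_that("noise-free falls are detected exactly at the annotated impact", {
  for (hz in c(20, 50, 100, 204.8)) {
    g <- generate_fall(fall_template(noise_sigma = 0, sampling_hz = hz), seed = 1)
    pts <- detect_peaks(g$series, peak_config(th1 = 3.0))
    expect_equal(pts, g$truth$t_impact, info = paste("hz", hz))
    expect_equal(max(g$series$a), fall_template()$impact_peak)
  }
  # sub-threshold impacts mimic the real falls that stay under 3 g
  low <- generate_fall(fall_template(impact_peak = 2.8, noise_sigma = 0), seed = 1)
  expect_length(detect_peaks(low$series, peak_config(th1 = 3.0)), 0L)
})

test_that("noise-free fall features recover the constructed dip and impact", {
  tmpl <- fall_template(noise_sigma = 0)
  g <- generate_fall(tmpl, seed = 2)
  f <- compute_features(g$series, detect_peaks(g$series)[1])
  expect_lte(f$MVI, tmpl$dip_level + 1e-9)
  expect_equal(f$MPI, tmpl$impact_peak)
  expect_equal(f$is, g$truth$dip_start)   # the dip opens the impact window
  expect_false(f$is_defaulted)
  # impact duration within two sample periods of the constructed span
  dt <- 1000 / tmpl$sampling_hz
  constructed <- (g$truth$t_impact - g$truth$dip_start) +
    with(tmpl, settle_tau * log((settle_start - baseline) / 0.5))
  expect_lt(abs(f$IDI - constructed), 2 * dt + 1e-9)
})

test_that("daily-living generators match their intended dynamics", {
  sit <- generate_adl(adl_template("SITTING"), seed = 3)
  expect_length(detect_peaks(sit, peak_config(th1 = 3.0)), 0L)
  expect_equal(sit$label, "NOT_FALL")

  jump <- generate_adl(adl_template("JUMPING"), seed = 4)
  expect_gte(length(detect_peaks(jump, peak_config(th1 = 3.0))), 1L)

  walk <- generate_adl(adl_template("WALKING", walk_amp = 0.4, noise_sigma = 0),
                       seed = 5)
  thr <- feature_thresholds(thSCI = 1.2)
  n <- length(walk$t)
  sci <- wristfall:::count_step_peaks(walk$t, walk$a, 1.2, 250)
  expect_gte(sci, 2)

  run <- generate_adl(adl_template("RUNNING", noise_sigma = 0), seed = 6)
  expect_lt(max(run$a), 2.3)
  seiz <- generate_adl(adl_template("SEIZURE"), seed = 7)
  expect_lt(max(seiz$a), 2.0)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_fall(seed = 10)$series
  b <- generate_fall(seed = 10)$series
  expect_identical(a$a, b$a)
  expect_false(identical(generate_fall(seed = 11)$series$a, a$a))
  expect_identical(generate_adl(seed = 10)$a, generate_adl(seed = 10)$a)
})

test_that("cohorts have the prescribed size, labels and rates", {
  coh <- generate_cohort(n_participants = 20, recordings_per_participant = 10,
                         fall_fraction = 0.3, seed = 1)
  expect_equal(nrow(coh$manifest), 200)
  expect_equal(sum(coh$manifest$label == "FALL"), 60)
  expect_setequal(unique(coh$manifest$sampling_hz), c(100, 50, 20))
  expect_length(coh$truth, 60)
  # identical manifest shape across seeds, different noise realisations
  coh2 <- generate_cohort(n_participants = 20, recordings_per_participant = 10,
                          fall_fraction = 0.3, seed = 2)
  expect_identical(coh$manifest[c("recording_id", "participant_id", "kind")],
                   coh2$manifest[c("recording_id", "participant_id", "kind")])
  r <- coh$manifest$recording_id[1]
  expect_false(identical(coh$recordings[[r]]$a, coh2$recordings[[r]]$a))
})

test_that("time-domain features are near rate-invariant for a fixed template", {
  f <- lapply(c(204.8, 100, 50), function(hz) {
    g <- generate_fall(fall_template(noise_sigma = 0, sampling_hz = hz), seed = 1)
    compute_features(g$series, detect_peaks(g$series)[1])
  })
  for (feat in c("IDI", "MPI", "MVI")) {
    vals <- vapply(f, `[[`, numeric(1), feat)
    spread <- (max(vals) - min(vals)) / max(abs(vals))
    expect_lt(spread, 0.07)
  }
})

test_that("axis decomposition preserves the synthesised magnitude", {
  g <- generate_fall(seed = 3, axes = TRUE)
  ts <- g$series
  expect_equal(magnitude(ts$ax, ts$ay, ts$az), ts$a, tolerance = 1e-12)
})
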