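test_that("magnitude is the Euclidean norm and rejects bad samples", {
  expect_equal(magnitude(0, 0, 1), 1.0)
  expect_equal(magnitude(0.6, 0.8, 0), 1.0)
  expect_equal(magnitude(1, 2, 2), 3.0)
  expect_error(magnitude(NA, 0, 1), "non-finite")
  expect_error(magnitude(Inf, 0, 1), "non-finite")

  # invariance under axis permutation and sign flips, and the norm bound
  set.seed(11)
  for (i in 1:50) {
    v <- rnorm(3)
    m <- magnitude(v[1], v[2], v[3])
    p <- sample(3)
    expect_equal(magnitude(v[p[1]], v[p[2]], v[p[3]]), m)
    s <- sample(c(-1, 1), 3, replace = TRUE)
    expect_equal(magnitude(s[1] * v[1], s[2] * v[2], s[3] * v[3]), m)
    expect_gte(m, max(abs(v)))
  }
})

test_that("to_magnitude fills the magnitude channel elementwise", {
  ts <- accel_ts(t = c(0, 10, 20), ax = c(0, 0, 0), ay = c(0, 0, 0),
                 az = c(1, 1, 1))
  expect_equal(to_magnitude(ts)$a, c(1, 1, 1))
  one <- accel_ts(t = 0, ax = 1, ay = 2, az = 2)
  expect_equal(to_magnitude(one)$a, 3)

  set.seed(7)
  big <- accel_ts(t = seq(0, 990, by = 10), ax = rnorm(100), ay = rnorm(100),
                  az = rnorm(100))
  got <- to_magnitude(big)$a
  expect_equal(got, vapply(1:100, function(i)
    magnitude(big$ax[i], big$ay[i], big$az[i]), numeric(1)))
  expect_error(to_magnitude(accel_ts(t = 0, a = 1)), "no axis channels")
})

test_that("accel_ts validates its invariants", {
  expect_error(accel_ts(t = c(0, 10, 10), a = c(1, 1, 1)), "strictly increasing")
  expect_error(accel_ts(t = c(0, 10), a = c(1, -0.5)), "non-negative")
  expect_error(accel_ts(t = c(0, 10), a = c(1, NA)), "non-finite")
  expect_error(accel_ts(t = c(0, 10), ax = c(1, 1), ay = c(0, 0)), "together")
  expect_error(accel_ts(t = c(0, 10), a = c(1, 1), label = "MAYBE"), "label")
  # sampling rate inferred from spacing when not declared
  expect_equal(accel_ts(t = seq(0, 90, 10), a = rep(1, 10))$sampling_hz, 100)
})

test_that("resampling interpolates linearly and preserves endpoints", {
  const <- accel_ts(t = seq(0, 950, by = 50), a = rep(1, 20), sampling_hz = 20)
  up <- resample_ts(const, 100)
  expect_equal(up$a, rep(1, length(up$t)))
  expect_equal(up$t[1], 0)
  expect_equal(up$t[length(up$t)], 950)

  ramp <- accel_ts(t = seq(0, 1000, by = 100), a = seq(0, 1, by = 0.1),
                   sampling_hz = 10)
  up <- resample_ts(ramp, 100)
  expect_equal(up$a[up$t == 500], 0.5)
  expect_equal(up$a, up$t / 1000)

  hz <- 204.8
  t <- seq(0, 2000, by = 1000 / hz)
  sine <- accel_ts(t = t, a = 1 + 0.5 * sin(2 * pi * t / 1000), sampling_hz = hz)
  down <- resample_ts(sine, 50)
  expect_lt(max(abs(down$a - (1 + 0.5 * sin(2 * pi * down$t / 1000)))), 1e-3)

  # idempotence on a native uniform grid
  same <- resample_ts(const, 20)
  expect_equal(same$t, const$t)
  expect_equal(same$a, const$a)
  expect_error(resample_ts(const, -5), "positive")
})

test_that("window slicing is a closed-interval filter that partitions", {
  ts <- accel_ts(t = seq(0, 990, by = 10), a = rep(1, 100), sampling_hz = 100)
  whole <- slice_window(ts, 0, 990)
  expect_equal(whole$t, ts$t)
  expect_equal(length(slice_window(ts, -500, -10)$t), 0L)
  expect_equal(length(slice_window(ts, 500, 700)$t), 21L)
  expect_error(slice_window(ts, 700, 500), "t_start")

  # complementary closed/open windows reconstruct the sample set
  left <- slice_window(ts, 0, 495)
  right <- slice_window(ts, 495 + 1e-9, 990)
  expect_equal(sort(c(left$t, right$t)), ts$t)
})
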