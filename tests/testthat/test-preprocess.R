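test_that("frame_stack enforces its invariants", {
  arr <- array(1, c(4, 4, 2))
  fs <- frame_stack(arr, "US", "linear_envelope", 20, c(0.1, 0.1))
  expect_s3_class(fs, "FrameStack")
  expect_equal(n_frames(fs), 2L)

  bad <- arr; bad[1, 1, 2] <- NaN
  expect_error(frame_stack(bad, "US", "linear_envelope"), "frame")
  expect_error(frame_stack(arr - 2, "US", "linear_envelope"), "non-negative")
  # negative values fine on the log scale
  expect_silent(frame_stack(arr - 2, "US", "log_dB"))
  expect_error(frame_stack(arr, "US", "linear_envelope",
                           frame_rate_hz = 0), "frame_rate")
})

test_that("envelope_detect recovers amplitude of axial tones", {
  n <- 128
  # zero input -> zero envelope
  z <- envelope_detect(array(0, c(n, 2, 1)))
  expect_true(all(fs_data(z) == 0))
  expect_identical(z$scale, "linear_envelope")

  # constant-amplitude axial sinusoid -> envelope ~ A away from edges
  A <- 3.7
  tone <- A * sin(2 * pi * 0.25 * (0:(n - 1)))
  rf <- array(tone, c(n, 3, 2))
  env <- fs_data(envelope_detect(rf))
  interior <- 17:(n - 16)
  expect_lt(max(abs(env[interior, 1, 1] - A)) / A, 0.02)

  # non-finite input names the offending frame
  rf[5, 1, 2] <- Inf
  expect_error(envelope_detect(rf), "frame\\(s\\): 2")
})

test_that("envelope of a Gaussian tone burst matches the window and an independent oracle", {
  n <- 64
  t <- 0:(n - 1)
  win <- exp(-0.5 * ((t - 32) / 7)^2)
  burst <- win * cos(2 * pi * 0.25 * t)
  env <- fs_data(envelope_detect(array(burst, c(n, 1, 1))))[, 1, 1]

  interior <- which(win > 0.05)
  expect_lt(max(abs(env[interior] - win[interior]) / win[interior]), 0.01)

  # explicit-DFT Hilbert oracle, elementwise
  expect_equal(env, oracle_envelope(burst), tolerance = 1e-10)
})

test_that("envelope_detect is amplitude-homogeneous", {
  set.seed(42)
  rf <- array(rnorm(32 * 4 * 3), c(32, 4, 3))
  e1 <- fs_data(envelope_detect(rf))
  e2 <- fs_data(envelope_detect(2.5 * rf))
  expect_equal(e2, 2.5 * e1, tolerance = 1e-12)
})

test_that("log_compress normalizes to 0 dB and clips at the floor", {
  set.seed(1)
  arr <- array(runif(5 * 4 * 3) + 0.01, c(5, 4, 3))
  arr[1, 1, 1] <- 2          # known maximum
  arr[2, 1, 1] <- 0.2        # one decade below
  stk <- frame_stack(arr, "US", "linear_envelope")
  db <- fs_data(log_compress(stk, floor_db = -60))
  expect_equal(max(db), 0)
  expect_equal(db[1, 1, 1], 0)
  expect_equal(db[2, 1, 1], -20, tolerance = 1e-12)

  # element-wise oracle with clipping
  oracle <- pmax(20 * log10(arr / max(arr)), -60)
  expect_equal(db, oracle, tolerance = 1e-12)

  # scale invariance via normalization
  db2 <- fs_data(log_compress(frame_stack(7 * arr, "US", "linear_envelope")))
  expect_equal(db2, db, tolerance = 1e-12)

  expect_error(log_compress(frame_stack(array(0, c(2, 2, 2)), "US",
                                        "linear_envelope")), "all-zero")
  expect_error(log_compress(stk, floor_db = 10), "negative")
})

test_that("average_frames reduces groups to their means", {
  arr <- array(0, c(3, 3, 4))
  arr[, , 1] <- 1; arr[, , 2] <- 3; arr[, , 3] <- 1; arr[, , 4] <- 3
  stk <- frame_stack(arr, "PA", "linear_envelope")

  expect_identical(fs_data(average_frames(stk, 1)), arr)

  out <- average_frames(stk, 2)
  expect_equal(n_frames(out), 2L)
  expect_true(all(fs_data(out) == 2))

  # global mean conserved when group_size divides n_frames
  set.seed(3)
  stk2 <- random_stack(c(6, 5, 12), seed = 3)
  expect_equal(mean(fs_data(average_frames(stk2, 3))), mean(fs_data(stk2)),
               tolerance = 1e-12)

  expect_warning(average_frames(stk, 3), "trailing")
  expect_error(average_frames(stk, 5), "exceeds")
})

test_that("contrast_stretch maps the chosen percentiles to [0, 1]", {
  ramp <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  expect_equal(contrast_stretch(ramp, 0, 100), ramp, tolerance = 1e-12)

  set.seed(9)
  img <- matrix(runif(400), 20)
  out <- contrast_stretch(img, 1, 99)
  q <- quantile(img, c(0.01, 0.99), names = FALSE)
  oracle <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(range(out), c(0, 1))

  expect_error(contrast_stretch(matrix(5, 3, 3), 1, 99), "degenerate")
  expect_error(contrast_stretch(img, 80, 20), "lo_pct")
})
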