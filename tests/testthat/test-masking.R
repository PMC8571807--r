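test_that("temporal_std follows the population convention", {
  # temporally constant stack -> zero image
  stk <- frame_stack(array(3, c(4, 4, 5)), "US", "log_dB")
  expect_true(all(temporal_std(stk) == 0))

  # pixel alternating 0, 2, 0, 2 -> std 1
  arr <- array(0, c(2, 2, 4)); arr[, , c(2, 4)] <- 2
  expect_true(all(temporal_std(frame_stack(arr, "US", "log_dB")) == 1))

  # random stack vs two-pass oracle
  stk2 <- random_stack(c(7, 6, 11), seed = 8)
  x <- fs_data(stk2)
  oracle <- apply(x, c(1, 2), function(ts) {
    m <- sum(ts) / length(ts)
    sqrt(sum((ts - m)^2) / length(ts))
  })
  expect_equal(temporal_std(stk2), oracle, tolerance = 1e-10)

  expect_error(temporal_std(frame_stack(array(1, c(2, 2, 1)), "US",
                                        "log_dB")), "2 frames")
})

test_that("make_perfusion_mask handles degenerate and simple scenes", {
  # all-zero flow component -> empty mask with warning
  z <- frame_stack(array(0, c(20, 20, 6)), "US", "log_dB")
  expect_warning(m <- make_perfusion_mask(z), "constant|empty")
  expect_false(any(m))

  # one circular decorrelating region on a static background
  set.seed(12)
  n <- 64; nf <- 40
  disc <- (row(matrix(0, n, n)) - 32)^2 + (col(matrix(0, n, n)) - 32)^2 <= 12^2
  arr <- array(rep(matrix(rnorm(n * n, sd = 0.05), n), nf), c(n, n, nf))
  for (t in seq_len(nf)) {
    fr <- arr[, , t]
    fr[disc] <- rnorm(sum(disc), sd = 3)
    arr[, , t] <- fr
  }
  m2 <- make_perfusion_mask(frame_stack(arr, "US", "log_dB"),
                            filter_config())
  expect_gte(sum(m2 & disc) / sum(disc), 0.8)     # covers the disc
  expect_lte(sum(m2 & !disc) / sum(!disc), 0.05)  # little background
  expect_gte(dice_coef(m2, disc), 0.8)
})

test_that("combine_and_grow removes exactly the overlapping PA components", {
  # disjoint blob: fully retained
  perf <- matrix(FALSE, 10, 10); perf[1:3, 1:3] <- TRUE
  pa <- matrix(0, 10, 10); pa[7:9, 7:9] <- 5
  g <- combine_and_grow(perf, pa, 1)
  expect_true(all(g$final_mask == 1))
  expect_identical(g$pa_masked, pa)
  expect_equal(g$iterations, 0L)

  # blob entirely inside the perfusion region: fully removed
  perf2 <- matrix(FALSE, 10, 10); perf2[3:8, 3:8] <- TRUE
  pa2 <- matrix(0, 10, 10); pa2[4:6, 4:6] <- 5
  g2 <- combine_and_grow(perf2, pa2, 1)
  expect_true(all(g2$pa_masked == 0))
  expect_true(all(g2$final_mask[4:6, 4:6] == 0))

  expect_error(combine_and_grow(matrix(0.5, 10, 10), pa, 1), "binary")
})

test_that("the 1x7 strip converges in 4 iterations as hand-worked", {
  perf <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 1)
  pa <- matrix(c(0, 0, 9, 9, 9, 9, 9), 1)
  g <- combine_and_grow(perf, pa, 5)
  expect_equal(as.vector(g$combined), c(1, 1, 3, 3, 3, 3, 3))
  expect_equal(g$iterations, 4L)
  expect_equal(as.vector(g$final_mask), c(1, 1, 0, 0, 0, 0, 0))
})

test_that("growth equals component-wise removal on random scenes", {
  set.seed(55)
  for (i in 1:10) {
    perf <- gaussian_blur(matrix(rnorm(30 * 30), 30), 2) > 0.25
    pa <- gaussian_blur(matrix(rnorm(30 * 30), 30), 1.5)
    thr <- quantile(pa, 0.85)
    g <- combine_and_grow(perf, pa, thr)
    removed_oracle <- oracle_grow_removed(perf, pa >= thr)
    expect_identical(g$final_mask == 0, removed_oracle)
  }
})

test_that("detect_stationary_pa masks flow PA and is idempotent", {
  sim <- simulate_phantom(small_phantom(seed = 4))
  cfg <- filter_config()
  comp <- blockwise_filter(sim$us, cfg)
  det <- detect_stationary_pa(comp, sim$pa, cfg)
  expect_true(all(dim(det$pa_masked) == fs_dim(sim$pa)[1:2]))

  # masking idempotence with a fixed absolute threshold
  cfg2 <- filter_config(pa_threshold = det$pa_threshold)
  masked_stack <- frame_stack(
    array(det$pa_masked, c(dim(det$pa_masked), 2)), "PA", "log_dB")
  g2 <- combine_and_grow(det$perfusion_mask, det$pa_masked,
                         det$pa_threshold)
  expect_equal(g2$pa_masked, det$pa_masked, tolerance = 1e-12)

  # shape mismatch errors
  bad_pa <- frame_stack(array(0, c(10, 10, 4)), "PA", "log_dB")
  expect_error(detect_stationary_pa(comp, bad_pa, cfg), "grids differ")
})

test_that("an empty perfusion mask leaves thresholded PA untouched", {
  pa <- matrix(0, 8, 8); pa[2:3, 2:3] <- 4
  g <- combine_and_grow(matrix(FALSE, 8, 8), pa, 1)
  expect_identical(g$pa_masked, pa)
})
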