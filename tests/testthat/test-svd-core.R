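test_that("block_grid tiles the image exactly", {
  g <- block_grid(c(128, 126), 64, 40)
  expect_equal(g$grid_dim, c(2L, 4L))
  # every pixel in exactly one block
  cover <- matrix(0L, 128, 126)
  for (b in seq_len(nrow(g$blocks))) {
    blk <- g$blocks[b, ]
    cover[(blk$row_start + 1):blk$row_end,
          (blk$col_start + 1):blk$col_end] <-
      cover[(blk$row_start + 1):blk$row_end,
            (blk$col_start + 1):blk$col_end] + 1L
  }
  expect_true(all(cover == 1L))
  # edge blocks shrink
  expect_equal(max(g$blocks$col_end), 126L)

  # 0 means full extent
  g1 <- block_grid(c(50, 60), 0, 0)
  expect_equal(nrow(g1$blocks), 1L)
})

test_that("build_casorati lays out pixels row-major and round-trips", {
  arr <- array(seq_len(2 * 3 * 3), c(2, 3, 3))
  stk <- frame_stack(arr, "US", "log_dB")
  blk <- list(row_start = 0L, row_end = 2L, col_start = 0L, col_end = 2L)
  cas <- build_casorati(stk, blk)
  expect_equal(dim(cas), c(4L, 3L))
  # row-major block order: (r1,c1), (r1,c2), (r2,c1), (r2,c2)
  expect_equal(cas[, 1], c(arr[1, 1, 1], arr[1, 2, 1], arr[2, 1, 1],
                           arr[2, 2, 1]))
  expect_equal(cas[2, ], arr[1, 2, ])

  # scatter-back reproduces the block exactly
  tgt <- array(0, dim(arr))
  tgt <- scatter_block(tgt, blk, cas)
  expect_equal(tgt[1:2, 1:2, ], arr[1:2, 1:2, ] + 0)

  # constant-in-time block -> identical columns
  arr2 <- array(rep(rnorm(6), 3), c(2, 3, 3))
  cas2 <- build_casorati(frame_stack(arr2, "US", "log_dB"), blk)
  expect_true(all(cas2[, 1] == cas2[, 2]) && all(cas2[, 2] == cas2[, 3]))

  expect_error(build_casorati(stk, list(row_start = 0L, row_end = 0L,
                                        col_start = 0L, col_end = 2L)),
               "empty")
})

test_that("compute_spectrum matches known and oracle spectra", {
  # rank-1: first value 0 dB, remainder at numerical floor
  u <- matrix(rnorm(12), 12) ; v <- matrix(rnorm(5), 5)
  sp <- compute_spectrum(u %*% t(v))
  expect_equal(sp$db[1], 0)
  expect_true(all(sp$db[-1] < -100))

  # diagonal(4,2,1): 0, -6.02, -12.04 dB
  sp2 <- compute_spectrum(diag(c(4, 2, 1)))
  expect_equal(sp2$db, 20 * log10(c(1, 0.5, 0.25)), tolerance = 1e-10)

  # random matrix vs sqrt of Gram-matrix eigenvalues
  set.seed(11)
  m <- matrix(rnorm(30 * 12), 30)
  sp3 <- compute_spectrum(m)
  ev <- sqrt(pmax(eigen(crossprod(m), symmetric = TRUE,
                        only.values = TRUE)$values, 0))
  expect_lt(max(abs(sp3$sv$d - ev) / ev[1]), 1e-8)

  expect_error(compute_spectrum(matrix(0, 3, 3)), "zero")
})

test_that("smooth_spectra averages curves over the block grid", {
  # 1x1 grid: identity (with a warning when a real window was requested)
  c1 <- array(rnorm(10), c(10, 1, 1))
  expect_warning(out1 <- smooth_spectra(c1), "single-block")
  expect_identical(out1, c1)
  expect_identical(smooth_spectra(c1, c(1L, 1L)), c1)

  # identical curves: identity
  base <- sort(rnorm(8), decreasing = TRUE)
  c2 <- array(rep(base, 6), c(8, 2, 3))
  expect_equal(smooth_spectra(c2), c2, tolerance = 1e-12)

  # 3x1 grid with c, c+delta, c-delta and 3x3 window: center becomes c
  delta <- runif(8)
  c3 <- array(0, c(8, 3, 1))
  c3[, 1, 1] <- base + delta
  c3[, 2, 1] <- base
  c3[, 3, 1] <- base - delta
  out <- smooth_spectra(c3, c(3L, 3L))
  expect_equal(out[, 2, 1], base, tolerance = 1e-12)
})

test_that("reconstruct_components splits and conserves exactly", {
  # rank-1 temporally constant block, t_low = 1: all stationary
  u <- rnorm(10); v <- rep(1, 6)
  m <- outer(u, v)
  sp <- compute_spectrum(m)
  comp <- reconstruct_components(sp$sv, 1, 2)
  expect_equal(comp$stationary, m, tolerance = 1e-10)
  expect_lt(max(abs(comp$flow)), 1e-10)
  expect_lt(max(abs(comp$noise)), 1e-10)

  # three orthogonal rank-1 terms, sigma = 100, 10, 1, thresholds (1, 2)
  q <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:3]
  p <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  terms <- lapply(1:3, function(k) c(100, 10, 1)[k] * outer(q[, k], p[, k]))
  m2 <- terms[[1]] + terms[[2]] + terms[[3]]
  comp2 <- reconstruct_components(compute_spectrum(m2)$sv, 1, 2)
  expect_equal(comp2$stationary, terms[[1]], tolerance = 1e-8)
  expect_equal(comp2$flow, terms[[2]], tolerance = 1e-8)
  expect_equal(comp2$noise, terms[[3]], tolerance = 1e-8)

  # conservation for arbitrary matrices and thresholds
  set.seed(21)
  for (i in 1:5) {
    m3 <- matrix(rnorm(40 * 9), 40)
    sp3 <- compute_spectrum(m3)
    tl <- sample(1:7, 1); th <- sample((tl + 1):9, 1)
    c3 <- reconstruct_components(sp3$sv, tl, th)
    expect_lt(rel_frob(c3$stationary + c3$flow + c3$noise, m3), 1e-6)
    if (th == 9) expect_true(all(c3$noise == 0))
  }

  expect_error(reconstruct_components(sp$sv, 3, 2), "invalid threshold")
})

test_that("blockwise_filter conserves input and orders energy", {
  stk <- random_stack(c(20, 18, 9), seed = 5)
  cfg <- filter_config(block_rows_px = 10L, block_cols_px = 9L)
  comp <- blockwise_filter(stk, cfg)
  expect_s3_class(comp, "ComponentSet")
  expect_lt(rel_frob(component_sum(comp), fs_data(stk)), 1e-6)

  th <- comp$provenance$thresholds
  expect_true(all(th$t_low < th$t_high))

  # monotone ordering: energy of orders 1..t_low >= any equal-count set of
  # higher orders (singular values are sorted)
  blk <- full_block(stk)
  sp <- compute_spectrum(build_casorati(stk, blk))
  tl <- 3
  e_low <- sum(sp$sv$d[1:tl]^2)
  for (s in list(4:6, 5:7, 7:9)) {
    expect_gte(e_low, sum(sp$sv$d[s]^2))
  }
})

test_that("pure-noise stacks send most energy to the noise component", {
  stk <- random_stack(c(24, 24, 16), seed = 99)
  comp <- suppressWarnings(blockwise_filter(stk, filter_config()))
  e <- vapply(comp[c("stationary", "flow", "noise")],
              function(f) sum(fs_data(f)^2), numeric(1))
  # i.i.d. noise has no coherent low-order structure: the retained
  # stationary subspace is a small fraction of total energy
  expect_lt(e[["stationary"]], 0.35 * sum(e))
  expect_lt(rel_frob(component_sum(comp), fs_data(stk)), 1e-6)
})
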