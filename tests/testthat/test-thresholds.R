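test_that("low_order_threshold finds the first flattening ratio", {
  # hand-computed ratios: 1.100, 1.091, 1.0185... -> first < 1.05 at i = 3
  curve <- c(66, 60, 55, 54, 53.5)
  expect_identical(low_order_threshold(curve, 1.05, "raw"), 3L)

  # two-point curve already below the preset -> t_low = 1
  expect_identical(low_order_threshold(c(10, 9.9), 1.05, "raw"), 1L)

  # shifted domain matches the loop oracle on random decreasing curves
  set.seed(31)
  for (i in 1:20) {
    curve <- sort(rnorm(40, sd = 10), decreasing = TRUE)
    got <- tryCatch(low_order_threshold(curve, 1.2),
                    pasvd_no_boundary = function(e) NA_integer_)
    expect_identical(got, oracle_low_threshold(curve, 1.2))
  }

  expect_error(low_order_threshold(c(10, 9), 0.9), "preset")
})

test_that("no tissue/flow boundary raises a typed error carrying the ratios", {
  curve <- c(100, 50, 25, 12.5)     # shifted: large ratios throughout
  err <- tryCatch(low_order_threshold(curve, 1.01),
                  pasvd_no_boundary = function(e) e)
  expect_s3_class(err, "pasvd_no_boundary")
  expect_length(err$ratios, 3L)
  expect_true(all(err$ratios >= 1.01))
})

test_that("high_order_threshold locates a constructed knee", {
  # gentle slope, steep knee at order 40 of 60, gentle tail
  curve <- c(seq(0, -8, length.out = 39),
             seq(-8, -30, length.out = 5),
             seq(-30, -33, length.out = 16))
  got <- high_order_threshold(curve, 0.30)
  expect_identical(got, oracle_high_threshold(curve, 0.30))
  w <- round(0.3 * 60)
  expect_lt(abs(got - 40), w / 2 + 3)

  # strictly linear curve: constant differences; tie broken to the first
  # searched index (left half-window complete)
  lin <- seq(0, -59)
  expect_identical(high_order_threshold(lin, 0.30),
                   oracle_high_threshold(lin, 0.30))

  expect_error(high_order_threshold(1:5, 0.3), "at least 10")
  expect_error(high_order_threshold(lin, 1.5), "diff_ma_frac")
})

test_that("threshold rules reproduce the explicit-loop oracle on varied curves", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(20:300, 1)
    knee <- sample(seq(ceiling(0.5 * n), floor(0.95 * n)), 1)
    drop <- runif(1, 5, 40)
    curve <- c(seq(0, runif(1, -20, -5), length.out = 3),
               seq(runif(1, -20, -5), -drop, length.out = knee - 3),
               seq(-drop, -drop - runif(1, 10, 30),
                   length.out = n - knee)) + rnorm(n, sd = 0.05)
    curve <- cummin(curve)          # enforce non-increasing
    frac <- runif(1, 0.25, 0.35)
    expect_identical(high_order_threshold(curve, frac),
                     oracle_high_threshold(curve, frac))
    got <- tryCatch(low_order_threshold(curve, 1.05),
                    pasvd_no_boundary = function(e) NA_integer_)
    expect_identical(got, oracle_low_threshold(curve, 1.05))
  }
})

test_that("median_filter_thresholds removes outliers and keeps edges", {
  # uniform field: identity
  u <- matrix(5L, 4, 4)
  out <- median_filter_thresholds(u, u + 10L, c(3L, 3L))
  expect_equal(out$t_low, u)
  expect_equal(out$t_high, u + 10L)

  # center outlier in a 3x3 field is replaced by the neighborhood median
  f <- matrix(3L, 3, 3); f[2, 2] <- 40L
  out2 <- median_filter_thresholds(f, f + 100L, c(3L, 3L))
  expect_equal(out2$t_low[2, 2], 3)

  # checkerboard vs exhaustive sorting oracle, cell by cell
  cb <- matrix(ifelse((row(matrix(0, 5, 6)) + col(matrix(0, 5, 6))) %% 2 == 0,
                      3L, 5L), 5, 6)
  got <- median_filter_thresholds(cb, cb, c(3L, 3L))$t_low
  for (i in 1:5) {
    for (j in 1:6) {
      ri <- max(1, i - 1):min(5, i + 1)
      ci <- max(1, j - 1):min(6, j + 1)
      expect_equal(got[i, j], round(median(sort(as.vector(cb[ri, ci])))))
    }
  }

  expect_error(median_filter_thresholds(u, u, c(2L, 3L)), "odd")
})
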