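# shared fixtures and oracles, built in code at test time

rel_frob <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small random FrameStack on the log_dB-like scale
random_stack <- function(dims = c(16, 14, 8), seed = 1, modality = "US") {
  set.seed(seed)
  frame_stack(array(rnorm(prod(dims)), dims), modality = modality,
              scale = "log_dB", frame_rate_hz = 20,
              pixel_pitch_mm = c(0.1, 0.1))
}

full_block <- function(stack) {
  d <- fs_dim(stack)
  list(row_start = 0L, row_end = d[1L], col_start = 0L, col_end = d[2L])
}

# independent O(n^2) discrete Hilbert envelope: explicit DFT loops, no fft()
oracle_envelope <- function(x) {
  n <- length(x)
  X <- complex(n)
  for (k in 0:(n - 1)) {
    X[k + 1] <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  z <- complex(n)
  for (m in 0:(n - 1)) {
    z[m + 1] <- sum(X * h * exp(2i * pi * (0:(n - 1)) * m / n)) / n
  }
  Mod(z)
}

# explicit-loop re-implementation of the two threshold rules (the oracle
# for criterion 4); shares only the documented conventions, not the code
oracle_low_threshold <- function(curve, preset, shifted = TRUE) {
  v <- if (shifted) curve - min(curve) + 1 else curve
  for (i in seq_len(length(v) - 1)) {
    if (v[i] / v[i + 1] < preset) return(i)
  }
  NA_integer_
}

oracle_moving_average <- function(x, w) {
  n <- length(x)
  hl <- (w - 1) %/% 2
  hr <- w %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hl); hi <- min(n, i + hr)
    out[i] <- mean(x[lo:hi])
  }
  out
}

oracle_high_threshold <- function(curve, frac = 0.30) {
  n <- length(curve)
  sm <- oracle_moving_average(curve, 5)
  d1 <- numeric(n - 1)
  for (i in seq_len(n - 1)) d1[i] <- sm[i + 1] - sm[i]
  w <- max(1, round(frac * n))
  d2 <- oracle_moving_average(d1, w)
  start <- min((w - 1) %/% 2 + 1, length(d2))
  best <- start
  for (i in start:length(d2)) {
    if (d2[i] < d2[best]) best <- i
  }
  as.integer(best)
}

# component-wise removal oracle for mask growth: a thresholded-PA connected
# component is removed iff it intersects the perfusion region
oracle_grow_removed <- function(perfusion, pa_mask) {
  labs <- label_components(pa_mask, connectivity = 8L)
  removed <- matrix(FALSE, nrow(pa_mask), ncol(pa_mask))
  if (max(labs) > 0) {
    for (l in seq_len(max(labs))) {
      comp <- labs == l
      if (any(comp & perfusion)) removed <- removed | comp
    }
  }
  removed
}

# plain-loop histogram overlap oracle
oracle_overlap <- function(a, b, n_bins) {
  lo <- min(c(a, b)); hi <- max(c(a, b))
  edges <- seq(lo, hi, length.out = n_bins + 1)
  count_in <- function(x) {
    h <- numeric(n_bins)
    for (v in x) {
      k <- n_bins
      for (j in seq_len(n_bins - 1)) {
        if (v < edges[j + 1]) { k <- j; break }
      }
      h[k] <- h[k] + 1
    }
    h / length(x)
  }
  ha <- count_in(a); hb <- count_in(b)
  s <- 0
  for (k in seq_len(n_bins)) s <- s + min(ha[k], hb[k])
  s
}

# small phantom for fast end-to-end smoke tests (9.6 mm FOV still holds the
# 8 mm phantom)
small_phantom <- function(seed = 1, n_frames = 80L) {
  phantom_config(image_dim = c(96L, 96L), n_frames = n_frames, seed = seed)
}
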