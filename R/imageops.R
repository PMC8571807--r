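# Small self-contained 2-D image operations on plain matrices.
# Images here are at most a few hundred pixels on a side, so vectorized
# base-R (shift-and-combine) implementations are fast enough; no external
# imaging dependency is required.

#' Centered moving average with edge shrinking
#'
#' @param x Numeric vector.
#' @param w Window length (>= 1); the window is centered and shrinks to the
#'   valid range near the edges, so no padding values are invented.
#' @return Numeric vector of the same length.
#' @keywords internal
#' @export
moving_average <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w <= 1L || n == 0L) return(x)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - hl, 1L)
  hi <- pmin(i + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Shift a matrix by (dr, dc) with edge replication (clamped indices).
shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Shift a logical matrix with constant `fill` outside the domain.
shift_fill <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

# Offsets of a disc structuring element of radius r (pixels).
disc_offsets <- function(r) {
  r <- max(0L, as.integer(round(r)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

eight_neighbors <- expand.grid(dr = -1:1, dc = -1:1)
eight_neighbors <- eight_neighbors[!(eight_neighbors$dr == 0 &
                                       eight_neighbors$dc == 0), ]
four_neighbors <- data.frame(dr = c(-1L, 1L, 0L, 0L),
                             dc = c(0L, 0L, -1L, 1L))

#' Binary morphology with a disc structuring element
#'
#' `binary_dilate()` / `binary_erode()` use a disc of the given pixel radius;
#' `binary_close()` is dilation followed by erosion and is used to bridge
#' small gaps in edge maps.
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels.
#' @return Logical matrix of the same shape.
#' @keywords internal
#' @export
binary_dilate <- function(mask, radius = 1) {
  offs <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_fill(mask, offs$dr[k], offs$dc[k], FALSE)
  }
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius = 1) {
  offs <- disc_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_fill(mask, offs$dr[k], offs$dc[k], TRUE)
  }
  out
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius = 1) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# One step of 8-connected (or 4-connected) dilation of a logical matrix.
dilate_neighbors <- function(mask, connectivity = 8L) {
  nb <- if (connectivity == 8L) eight_neighbors else four_neighbors
  out <- mask
  for (k in seq_len(nrow(nb))) {
    out <- out | shift_fill(mask, nb$dr[k], nb$dc[k], FALSE)
  }
  out
}

#' Gaussian blur of a 2-D image
#'
#' Separable Gaussian smoothing with kernel radius `ceiling(3 * sigma)`.
#' Near the borders the kernel is renormalized over its valid support, so a
#' constant image stays exactly constant.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the input.
#' @return Numeric matrix of the same shape.
#' @keywords internal
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Kr <- gauss_band(nrow(img), sigma)
  Kc <- gauss_band(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

# Row-normalized banded Gaussian smoothing matrix of size n x n.
gauss_band <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1L & idx <= n
    K[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

#' Sobel gradient magnitude
#'
#' @param img Numeric matrix.
#' @return Matrix of gradient magnitudes (edge-replicated borders).
#' @keywords internal
#' @export
sobel_magnitude <- function(img) {
  sx <- function(dr, dc) shift_clamp(img, dr, dc)
  gx <- (sx(-1, -1) + 2 * sx(0, -1) + sx(1, -1) -
           sx(-1, 1) - 2 * sx(0, 1) - sx(1, 1)) / 8
  gy <- (sx(-1, -1) + 2 * sx(-1, 0) + sx(-1, 1) -
           sx(1, -1) - 2 * sx(1, 0) - sx(1, 1)) / 8
  sqrt(gx^2 + gy^2)
}

#' Hysteresis thresholding of a gradient-magnitude map
#'
#' Pixels above `hi` seed the edge set, which grows (8-connected) into
#' pixels above `lo` until a fixed point is reached.
#'
#' @param mag Numeric matrix of gradient magnitudes.
#' @param lo,hi Thresholds with `lo <= hi`.
#' @return Logical edge mask.
#' @keywords internal
#' @export
hysteresis_threshold <- function(mag, lo, hi) {
  strong <- mag >= hi
  weak <- mag >= lo
  repeat {
    grown <- dilate_neighbors(strong) & weak
    nxt <- strong | grown
    if (identical(nxt, strong)) break
    strong <- nxt
  }
  strong
}

#' Fill interior holes of a binary mask
#'
#' A hole is any off-pixel region not 4-connected to the image border.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @keywords internal
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  outside <- matrix(FALSE, nrow(mask), ncol(mask))
  outside[1L, ] <- bg[1L, ]
  outside[nrow(mask), ] <- bg[nrow(mask), ]
  outside[, 1L] <- outside[, 1L] | bg[, 1L]
  outside[, ncol(mask)] <- outside[, ncol(mask)] | bg[, ncol(mask)]
  repeat {
    nxt <- dilate_neighbors(outside, connectivity = 4L) & bg
    nxt <- nxt | outside
    if (identical(nxt, outside)) break
    outside <- nxt
  }
  !outside
}

#' Connected-component labelling of a binary image
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels (0 = background, components numbered
#'   from 1 in scan order).
#' @keywords internal
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  lab <- 0L
  while (any(remaining)) {
    lab <- lab + 1L
    seed <- which(remaining)[1L]
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[seed] <- TRUE
    repeat {
      nxt <- (dilate_neighbors(comp, connectivity) & mask) | comp
      if (identical(nxt, comp)) break
      comp <- nxt
    }
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  labels
}

# Mean filter over a small 2-D grid with edge shrinking (used for smoothing
# per-order singular values across the block grid).
grid_mean_filter <- function(mat, window) {
  grid_apply_filter(mat, window, mean)
}

# Median filter over a small 2-D grid with edge shrinking.
grid_median_filter <- function(mat, window) {
  grid_apply_filter(mat, window, stats::median)
}

grid_apply_filter <- function(mat, window, fun) {
  wr <- as.integer(window[1L]); wc <- as.integer(window[2L])
  if (wr %% 2L == 0L || wc %% 2L == 0L) {
    stop("grid filter window dimensions must be odd", call. = FALSE)
  }
  nr <- nrow(mat); nc <- ncol(mat)
  hr <- wr %/% 2L; hc <- wc %/% 2L
  out <- mat
  for (i in seq_len(nr)) {
    ri <- max(1L, i - hr):min(nr, i + hr)
    for (j in seq_len(nc)) {
      ci <- max(1L, j - hc):min(nc, j + hc)
      out[i, j] <- fun(mat[ri, ci])
    }
  }
  out
}
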