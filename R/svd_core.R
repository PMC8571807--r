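#' Singular spectrum of a Casorati matrix
#'
#' Computes the (economy-size) singular value decomposition of a block's
#' Casorati matrix and expresses the singular values in decibels relative to
#' the largest one: `20 * log10(sigma / sigma_max)`, a non-increasing curve
#' starting at 0 dB. The factors are retained for partial reconstruction.
#'
#' @param casorati Numeric `pixels x frames` matrix (finite, not all zero).
#' @return A list with `db` (singular values in dB, descending), `sv` (the
#'   `svd()` factor list) and `n_orders` (`min(pixels, frames)`).
#' @export
compute_spectrum <- function(casorati) {
  if (!all(is.finite(casorati))) {
    stop("non-finite values in Casorati matrix", call. = FALSE)
  }
  if (all(casorati == 0)) {
    stop("zero Casorati matrix has no singular spectrum", call. = FALSE)
  }
  sv <- svd(casorati)
  db <- 20 * log10(pmax(sv$d / sv$d[1L], .Machine$double.xmin))
  list(db = db, sv = sv, n_orders = length(sv$d))
}

#' Smooth singular-value curves across the block grid
#'
#' For each singular order, the value is replaced by the mean over a
#' neighborhood of blocks (a 2-D moving average over the grid), shrinking
#' the window at grid edges. Curves of unequal length (edge blocks) must be
#' truncated to a common length by the caller beforehand.
#'
#' @param curves Numeric array `n_orders x grid_rows x grid_cols` of
#'   singular-value curves (dB or linear, per `domain`).
#' @param grid_window Odd integer pair, window in blocks (default `c(3, 3)`).
#' @param domain `"db"` (average the dB values, canonical) or `"linear"`
#'   (average the linear magnitudes, then return to dB).
#' @return Array of the same shape with smoothed curves.
#' @export
smooth_spectra <- function(curves, grid_window = c(3L, 3L),
                           domain = c("db", "linear")) {
  domain <- match.arg(domain)
  stopifnot(is.array(curves), length(dim(curves)) == 3L)
  d <- dim(curves)
  if (d[2L] == 1L && d[3L] == 1L) {
    if (all(grid_window > 1L)) {
      warning("single-block grid: spectrum smoothing is the identity",
              call. = FALSE)
    }
    return(curves)
  }
  out <- curves
  for (o in seq_len(d[1L])) {
    plane <- matrix(curves[o, , ], d[2L], d[3L])
    if (domain == "linear") {
      plane <- 20 * log10(grid_mean_filter(10^(plane / 20), grid_window))
    } else {
      plane <- grid_mean_filter(plane, grid_window)
    }
    out[o, , ] <- plane
  }
  out
}

#' Low-order singular-value threshold (tissue/flow boundary)
#'
#' Finds the first singular order `i` at which the ratio of consecutive
#' curve values `S(i) / S(i+1)` drops below a preset, i.e. where the steep
#' initial (tissue-dominated) part of the curve flattens out. Orders
#' `1..t_low` are classified as stationary tissue.
#'
#' @param curve_db Numeric vector, singular values in dB (non-increasing).
#' @param preset Ratio threshold, `> 1`. Strongly dependent on image
#'   quality; default 1.05.
#' @param ratio_domain `"shifted"` (default): the curve is offset so its
#'   minimum is +1 dB before ratios are formed, which keeps the ratio
#'   well-defined for curves that cross 0 dB. `"raw"`: ratios on the values
#'   as given (requires a strictly positive curve).
#' @return 1-based integer order `t_low`.
#' @section Errors: if no order satisfies the condition, an error of class
#'   `"pasvd_no_boundary"` is raised carrying the ratio trace in its
#'   `ratios` field; callers may catch it and fall back to `t_low = 1`.
#' @export
low_order_threshold <- function(curve_db, preset = 1.05,
                                ratio_domain = c("shifted", "raw")) {
  ratio_domain <- match.arg(ratio_domain)
  if (preset <= 1) stop("`preset` must exceed 1", call. = FALSE)
  n <- length(curve_db)
  if (n < 2L) stop("curve too short for a ratio", call. = FALSE)
  v <- if (ratio_domain == "shifted") curve_db - min(curve_db) + 1 else curve_db
  if (any(v <= 0)) {
    stop("curve values must be positive in the chosen ratio domain",
         call. = FALSE)
  }
  ratios <- v[-n] / v[-1L]
  hit <- which(ratios < preset)
  if (!length(hit)) {
    cond <- structure(
      class = c("pasvd_no_boundary", "error", "condition"),
      list(message = "no tissue/flow boundary found: no consecutive singular-value ratio drops below the preset",
           call = sys.call(-1L), ratios = ratios, preset = preset))
    stop(cond)
  }
  hit[1L]
}

#' High-order singular-value threshold (flow/noise boundary)
#'
#' Locates the knee where the singular-value curve falls onto the noise
#' plateau: the curve is smoothed with a length-5 moving average,
#' first-order finite differences are taken, the differences are smoothed
#' again with a moving average whose length is a fraction of the curve
#' length, and the global minimum of the result marks the threshold. The
#' difference at position `i` is assigned to order `i` (left-edge
#' alignment), so the argmin maps directly to a singular order; ties break
#' to the smallest index (conservative: more orders kept as flow).
#'
#' The smoothing windows are centered and shrink at the curve ends. The
#' global-minimum search skips positions whose left half-window is
#' incomplete: there the shrunken average over-weights the steep low-order
#' (tissue) segment, which the low-order threshold already claims.
#' Right-shrunken positions stay in the search because the flow/noise knee
#' typically sits near the end of the curve.
#'
#' @param curve_db Numeric vector of at least 10 singular values in dB.
#' @param diff_ma_frac Fraction of the curve length used as the second
#'   moving-average window; recommended range 0.25--0.35, default 0.30.
#' @return 1-based integer order `t_high`.
#' @export
high_order_threshold <- function(curve_db, diff_ma_frac = 0.30) {
  n <- length(curve_db)
  if (n < 10L) stop("curve must have at least 10 orders", call. = FALSE)
  if (diff_ma_frac <= 0 || diff_ma_frac >= 1) {
    stop("`diff_ma_frac` must lie in (0, 1)", call. = FALSE)
  }
  sm <- moving_average(curve_db, 5L)
  d1 <- diff(sm)                      # d1[i] belongs to order i
  w <- max(1L, as.integer(round(diff_ma_frac * n)))
  d2 <- moving_average(d1, w)
  start <- min((w - 1L) %/% 2L + 1L, length(d2))
  start - 1L + which.min(d2[start:length(d2)])  # first minimum on ties
}

#' Median-filter threshold fields over the block grid
#'
#' Removes outlier thresholds produced by per-block curve analysis while
#' preserving edges from genuine tissue boundaries: a 2-D median over the
#' block grid, applied independently to the low-order and high-order
#' threshold fields, with windows shrinking at grid edges. Outputs are
#' rounded to the nearest integer order.
#'
#' @param t_low,t_high Integer matrices (grid_rows x grid_cols).
#' @param window Odd integer pair; conventionally equal to the grid window
#'   used when smoothing the singular-value curves.
#' @return List with median-filtered `t_low` and `t_high` matrices.
#' @export
median_filter_thresholds <- function(t_low, t_high, window = c(3L, 3L)) {
  stopifnot(is.matrix(t_low), is.matrix(t_high),
            all(dim(t_low) == dim(t_high)))
  list(
    t_low = round(grid_median_filter(t_low, window)),
    t_high = round(grid_median_filter(t_high, window))
  )
}

#' Partial reconstructions from retained singular orders
#'
#' Splits a block into three additive parts using the factor list from
#' [compute_spectrum()]: stationary = orders `1..t_low`, flow = orders
#' `t_low+1..t_high`, noise = orders `t_high+1..end`. The three matrices sum
#' to the input block exactly (up to SVD round-off).
#'
#' @param sv Factor list (`u`, `d`, `v`) from `svd()`.
#' @param t_low,t_high Threshold orders, `1 <= t_low < t_high <= length(d)`.
#' @return List of matrices `stationary`, `flow`, `noise`.
#' @export
reconstruct_components <- function(sv, t_low, t_high) {
  L <- length(sv$d)
  t_low <- as.integer(t_low); t_high <- as.integer(t_high)
  if (t_low < 1L || t_high <= t_low || t_high > L) {
    stop(sprintf("invalid threshold pair (t_low=%d, t_high=%d, orders=%d)",
                 t_low, t_high, L), call. = FALSE)
  }
  part <- function(orders) {
    if (!length(orders)) {
      return(matrix(0, nrow(sv$u), nrow(sv$v)))
    }
    sv$u[, orders, drop = FALSE] %*%
      (sv$d[orders] * t(sv$v[, orders, drop = FALSE]))
  }
  list(
    stationary = part(seq_len(t_low)),
    flow = part(seq.int(t_low + 1L, t_high)),
    noise = part(if (t_high < L) seq.int(t_high + 1L, L) else integer(0))
  )
}
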