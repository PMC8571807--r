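#' Per-pixel temporal standard deviation
#'
#' Standard deviation of each pixel over frames, population convention
#' (divisor `n`). Decorrelating flow pixels show a high temporal standard
#' deviation; static tissue shows a low one.
#'
#' @param stack A `FrameStack` with at least 2 frames.
#' @return Numeric matrix (depth x lateral).
#' @export
temporal_std <- function(stack) {
  x <- fs_data(stack)
  nf <- dim(x)[3L]
  if (nf < 2L) stop("temporal_std needs at least 2 frames", call. = FALSE)
  mu <- rowMeans(x, dims = 2L)
  mu2 <- rowMeans(x^2, dims = 2L)
  sqrt(pmax(mu2 - mu^2, 0))
}

#' Build the binary perfusion mask from the US flow component
#'
#' Pipeline: per-frame Gaussian blur of the flow component, temporal
#' standard deviation, dynamic-range compression (`log1p` followed by
#' min--max rescaling to `[0, 1]`), gradient-magnitude edge detection with
#' hysteresis, morphological closing (removing small edges), and filling of
#' the enclosed interior. The result marks regions of moving blood.
#'
#' @param flow_stack The `flow` component of a [blockwise_filter()] result.
#' @param config A [filter_config()] list (uses `blur_sigma_px`,
#'   `close_radius_px`, `edge_hi_quantile`, `edge_lo_frac`).
#' @return Logical matrix, `TRUE` inside perfusion regions. If nothing is
#'   detected an all-`FALSE` mask is returned with a warning (a valid
#'   outcome when no flow is present).
#' @export
make_perfusion_mask <- function(flow_stack, config = filter_config()) {
  stopifnot(inherits(flow_stack, "FrameStack"))
  x <- fs_data(flow_stack)
  d <- dim(x)
  if (d[3L] < 2L) stop("flow stack needs at least 2 frames", call. = FALSE)
  blurred <- x
  if (config$blur_sigma_px > 0) {
    Kr <- gauss_band(d[1L], config$blur_sigma_px)
    Kc <- t(gauss_band(d[2L], config$blur_sigma_px))
    for (t in seq_len(d[3L])) {
      blurred[, , t] <- Kr %*% x[, , t] %*% Kc
    }
  }
  s <- temporal_std(fs_replace(flow_stack, blurred))
  if (max(s) <= 0) {
    warning("flow component is temporally constant; empty perfusion mask",
            call. = FALSE)
    return(matrix(FALSE, d[1L], d[2L]))
  }
  comp <- log1p(s)
  comp <- (comp - min(comp)) / (max(comp) - min(comp))
  mag <- sobel_magnitude(comp)
  hi <- stats::quantile(mag, config$edge_hi_quantile, names = FALSE)
  if (hi <= 0) {
    warning("no gradient structure in flow component; empty perfusion mask",
            call. = FALSE)
    return(matrix(FALSE, d[1L], d[2L]))
  }
  edges <- hysteresis_threshold(mag, config$edge_lo_frac * hi, hi)
  closed <- binary_close(edges, config$close_radius_px)
  mask <- fill_holes(closed)
  if (config$open_radius_px > 0) {
    # trim the detector-width halo and cut single-pixel necks between
    # adjacent regions left by touching edge rings
    mask <- binary_dilate(binary_erode(mask, config$open_radius_px),
                          config$open_radius_px)
  }
  if (!any(mask)) {
    warning("no perfusion region detected", call. = FALSE)
  }
  mask
}

#' Combine perfusion and PA masks and grow the overlap
#'
#' Implements the overlap-growing scheme that decides which thresholded PA
#' signal is flow-associated. The thresholded PA mask (value 2) is added to
#' the perfusion mask (value 1), so overlapping pixels take value 3. The
#' overlap is then grown iteratively: every pixel of value 2 with an
#' 8-connected neighbor of value 3 becomes 3, until a fixed point. The
#' final binary mask is 0 where the combined value reached 3 (PA signal
#' connected to perfusion) and 1 elsewhere; multiplying the PA image by it
#' removes flow-associated PA signal. Under 8-connectivity this is exactly
#' component-wise removal: a PA connected component is removed if and only
#' if it intersects the perfusion region.
#'
#' @param perfusion Logical (or strictly 0/1) perfusion mask.
#' @param pa_image Numeric matrix of the same shape.
#' @param pa_threshold Threshold in the units of `pa_image`; pixels with
#'   `pa_image >= pa_threshold` form the PA mask.
#' @return List with `final_mask` (0/1 matrix), `combined` (the grown
#'   0/1/2/3 image), `iterations` (number of growth sweeps that changed the
#'   image), and `pa_masked` (`pa_image * final_mask`).
#' @export
combine_and_grow <- function(perfusion, pa_image, pa_threshold) {
  if (is.logical(perfusion)) {
    perf <- perfusion
  } else {
    if (!all(perfusion %in% c(0, 1))) {
      stop("perfusion mask must be binary", call. = FALSE)
    }
    perf <- perfusion == 1
  }
  if (!all(dim(perf) == dim(pa_image))) {
    stop("perfusion mask and PA image must share shape", call. = FALSE)
  }
  pa_mask <- pa_image >= pa_threshold
  combined <- perf * 1L + pa_mask * 2L
  iterations <- 0L
  repeat {
    three <- combined == 3L
    candidates <- (combined == 2L) & dilate_neighbors(three, 8L)
    if (!any(candidates)) break
    combined[candidates] <- 3L
    iterations <- iterations + 1L
  }
  final_mask <- matrix(as.numeric(combined < 3L), nrow(pa_image))
  list(final_mask = final_mask, combined = combined,
       iterations = iterations, pa_masked = pa_image * final_mask)
}

#' Detect stationary photoacoustic sources
#'
#' End stage of the dual-modality pipeline: SVD-noise-filters the PA stack
#' (stationary + flow reconstruction), averages the filtered frames into a
#' single PA image, builds the perfusion mask from the US flow component,
#' and removes flow-associated PA signal with [combine_and_grow()]. What
#' remains are PA sources that do not move with the blood --- e.g.
#' intraplaque hemorrhage.
#'
#' @param components_us A `ComponentSet` from [blockwise_filter()] on the US
#'   stack.
#' @param pa_stack The co-registered PA `FrameStack` (same pixel grid).
#' @param config A [filter_config()] list. `pa_threshold_quantile` sets the
#'   PA threshold as a quantile of the averaged PA image; alternatively an
#'   absolute threshold can be supplied via the `pa_threshold` entry.
#' @return List with `pa_masked` (the stationary-PA image), `pa_image` (the
#'   averaged noise-filtered PA image before masking), `final_mask`,
#'   `perfusion_mask`, `combined`, `pa_threshold`, and `us_background` (the
#'   temporal mean of the US stationary component, for overlay rendering).
#' @export
detect_stationary_pa <- function(components_us, pa_stack,
                                 config = filter_config()) {
  stopifnot(inherits(components_us, "ComponentSet"),
            inherits(pa_stack, "FrameStack"))
  d_us <- fs_dim(components_us$flow)
  d_pa <- fs_dim(pa_stack)
  if (!all(d_us[1:2] == d_pa[1:2])) {
    stop(sprintf("US (%d x %d) and PA (%d x %d) grids differ",
                 d_us[1L], d_us[2L], d_pa[1L], d_pa[2L]), call. = FALSE)
  }
  components_pa <- blockwise_filter(pa_stack, config)
  pa_filtered <- fs_data(components_pa$stationary) +
    fs_data(components_pa$flow)
  pa_image <- rowMeans(pa_filtered, dims = 2L)
  perfusion <- make_perfusion_mask(components_us$flow, config)
  thr <- config[["pa_threshold"]]
  if (is.null(thr)) {
    thr <- stats::quantile(pa_image, config$pa_threshold_quantile,
                           names = FALSE)
  }
  grown <- combine_and_grow(perfusion, pa_image, thr)
  c(grown,
    list(pa_image = pa_image, perfusion_mask = perfusion,
         pa_threshold = thr,
         us_background = rowMeans(fs_data(components_us$stationary),
                                  dims = 2L)))
}
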