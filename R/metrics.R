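#' Region-of-interest pair for contrast evaluation
#'
#' Defines a signal region and a background region on an image, either as
#' 0-based half-open rectangles `c(r0, r1, c0, c1)` or as logical masks.
#' Regions must be non-empty and disjoint.
#'
#' @param signal,background Rectangle (length-4 integer vector) or logical
#'   matrix.
#' @return Object of class `"RoiPair"`.
#' @export
roi_pair <- function(signal, background) {
  structure(list(signal = signal, background = background),
            class = "RoiPair")
}

roi_pixels <- function(image, roi) {
  if (is.logical(roi)) {
    if (!all(dim(roi) == dim(image))) {
      stop("ROI mask shape differs from image", call. = FALSE)
    }
    return(image[roi])
  }
  roi <- as.integer(roi)
  if (length(roi) != 4L) {
    stop("rectangular ROI must be c(r0, r1, c0, c1), 0-based half-open",
         call. = FALSE)
  }
  if (roi[1L] < 0L || roi[3L] < 0L || roi[2L] > nrow(image) ||
      roi[4L] > ncol(image) || roi[2L] <= roi[1L] || roi[4L] <= roi[3L]) {
    stop("ROI outside image bounds or empty", call. = FALSE)
  }
  image[(roi[1L] + 1L):roi[2L], (roi[3L] + 1L):roi[4L]]
}

roi_index_set <- function(image, roi) {
  idx <- matrix(FALSE, nrow(image), ncol(image))
  if (is.logical(roi)) return(roi)
  roi <- as.integer(roi)
  idx[(roi[1L] + 1L):roi[2L], (roi[3L] + 1L):roi[4L]] <- TRUE
  idx
}

#' Fractional histogram overlap between two sample sets
#'
#' Computes `eta = sum_k min(h_signal(x_k), h_background(x_k))` over a
#' shared set of equal-width bins spanning the pooled sample range, with
#' each histogram normalized to unit mass. `eta` is the fraction of
#' probability mass the two distributions share: 1 for identical sample
#' sets, 0 for disjoint supports.
#'
#' @param signal_samples,background_samples Non-empty numeric vectors.
#' @param n_bins Number of shared bins (>= 2, default 256).
#' @return `eta` in `[0, 1]`. If all pooled samples are equal the overlap is
#'   1 by convention (identical point masses).
#' @export
histogram_overlap <- function(signal_samples, background_samples,
                              n_bins = 256L) {
  if (!length(signal_samples) || !length(background_samples)) {
    stop("both sample sets must be non-empty", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  pooled <- range(c(signal_samples, background_samples))
  if (pooled[1L] == pooled[2L]) return(1)
  edges <- seq(pooled[1L], pooled[2L], length.out = n_bins + 1L)
  bin_of <- function(x) {
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  }
  h_sig <- tabulate(bin_of(signal_samples), n_bins) / length(signal_samples)
  h_bg <- tabulate(bin_of(background_samples), n_bins) /
    length(background_samples)
  sum(pmin(h_sig, h_bg))
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - eta`, with `eta` the fractional histogram overlap between the
#' pixel values of the signal and background ROIs. The gCNR lies in
#' `[0, 1]` and measures the fraction of pixels an ideal observer can
#' classify correctly; unlike CNR/SNR it is invariant under any strictly
#' increasing remapping of the gray scale (when bin edges are recomputed
#' from the pooled range), which makes it suitable for evaluating nonlinear
#' filters.
#'
#' @param image Numeric matrix.
#' @param rois A [roi_pair()].
#' @param n_bins Number of shared histogram bins (default 256).
#' @return gCNR value in `[0, 1]`.
#' @export
gcnr <- function(image, rois, n_bins = 256L) {
  stopifnot(inherits(rois, "RoiPair"))
  sig_idx <- roi_index_set(image, rois$signal)
  bg_idx <- roi_index_set(image, rois$background)
  if (any(sig_idx & bg_idx)) {
    stop("signal and background ROIs overlap", call. = FALSE)
  }
  1 - histogram_overlap(image[sig_idx], image[bg_idx], n_bins)
}

#' Relative gCNR change between two images
#'
#' @param before,after Numeric matrices evaluated with the same ROIs.
#' @param rois A [roi_pair()].
#' @param n_bins Number of shared histogram bins.
#' @return Percent change `100 * (gcnr(after) - gcnr(before)) / gcnr(before)`.
#' @export
gcnr_improvement <- function(before, after, rois, n_bins = 256L) {
  g0 <- gcnr(before, rois, n_bins)
  g1 <- gcnr(after, rois, n_bins)
  if (g0 == 0) {
    stop("gCNR of the reference image is 0: relative change undefined",
         call. = FALSE)
  }
  100 * (g1 - g0) / g0
}
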