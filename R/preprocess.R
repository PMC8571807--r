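#' Envelope detection of beamformed RF frames
#'
#' Computes the per-frame analytic-signal magnitude along the axial axis
#' (array dimension 1), i.e. the standard B-mode envelope of each A-line via
#' the discrete Hilbert transform.
#'
#' @param rf_frames Real 3-D array of beamformed RF data, axial axis first
#'   (`depth x lateral x frame`). A matrix is treated as a single frame.
#' @param modality,frame_rate_hz,pixel_pitch_mm Metadata for the resulting
#'   [frame_stack()].
#'
#' @return A `FrameStack` on the `linear_envelope` scale, same shape as the
#'   input; non-negative everywhere.
#'
#' @details The analytic signal of each A-line is formed in the frequency
#'   domain (zero negative frequencies, double positive ones; DC and, for
#'   even lengths, Nyquist kept unscaled) and its modulus taken. The
#'   operation is amplitude-homogeneous: `envelope(c * x) = c * envelope(x)`
#'   for `c > 0`.
#' @export
envelope_detect <- function(rf_frames, modality = "US", frame_rate_hz = 20,
                            pixel_pitch_mm = c(0.1, 0.1)) {
  if (is.matrix(rf_frames)) rf_frames <- array(rf_frames, c(dim(rf_frames), 1L))
  if (!is.array(rf_frames) || length(dim(rf_frames)) != 3L) {
    stop("`rf_frames` must be a 3-D array with the axial dimension first",
         call. = FALSE)
  }
  if (!all(is.finite(rf_frames))) {
    bad <- which(apply(rf_frames, 3L, function(f) any(!is.finite(f))))
    stop(sprintf("non-finite RF values in frame(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- dim(rf_frames)
  n <- d[1L]
  # frequency-domain multiplier for the analytic signal of a length-n A-line
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  env <- array(0, d)
  for (t in seq_len(d[3L])) {
    fr <- matrix(rf_frames[, , t], nrow = n)
    sp <- stats::mvfft(fr)
    env[, , t] <- Mod(stats::mvfft(sp * h, inverse = TRUE)) / n
  }
  frame_stack(env, modality = modality, scale = "linear_envelope",
              frame_rate_hz = frame_rate_hz, pixel_pitch_mm = pixel_pitch_mm,
              provenance = list(preprocess = "envelope_detect"))
}

#' Log compression of an envelope stack
#'
#' Maps a non-negative envelope stack to decibels relative to its global
#' maximum: `20 * log10(value / max)`, clipped below at `floor_db`. The
#' output maximum is exactly 0 dB, so the result is invariant under
#' multiplication of the input by a positive constant.
#'
#' @param stack A `FrameStack` on the `linear_envelope` scale.
#' @param floor_db Negative clipping floor in dB (default -60).
#' @return A `FrameStack` on the `log_dB` scale.
#' @export
log_compress <- function(stack, floor_db = -60) {
  stopifnot(inherits(stack, "FrameStack"))
  if (stack$scale != "linear_envelope") {
    stop("log_compress expects a linear_envelope stack", call. = FALSE)
  }
  if (!is.numeric(floor_db) || length(floor_db) != 1L || floor_db >= 0) {
    stop("`floor_db` must be a single negative number", call. = FALSE)
  }
  x <- fs_data(stack)
  m <- max(x)
  if (m <= 0) stop("all-zero stack: no reference maximum", call. = FALSE)
  db <- 20 * log10(pmax(x / m, 10^(floor_db / 20)))
  prov <- stack$provenance
  prov$log_compress <- list(floor_db = floor_db, reference_max = m)
  fs_replace(stack, db, scale = "log_dB", provenance = prov)
}

#' Average consecutive frame groups
#'
#' Reduces a stack by replacing each group of `group_size` consecutive
#' frames with their arithmetic mean, e.g. to average paired
#' single-wavelength photoacoustic acquisitions.
#'
#' @param stack A `FrameStack`.
#' @param group_size Positive integer; must not exceed `n_frames`. A trailing
#'   remainder of frames that does not fill a group is dropped with a warning.
#' @return A `FrameStack` with `floor(n_frames / group_size)` frames.
#' @export
average_frames <- function(stack, group_size) {
  stopifnot(inherits(stack, "FrameStack"))
  group_size <- as.integer(group_size)
  nf <- n_frames(stack)
  if (group_size < 1L) stop("`group_size` must be >= 1", call. = FALSE)
  if (group_size > nf) {
    stop(sprintf("group_size (%d) exceeds n_frames (%d)", group_size, nf),
         call. = FALSE)
  }
  n_groups <- nf %/% group_size
  if (n_groups * group_size < nf) {
    warning(sprintf("dropping %d trailing frame(s) not filling a group",
                    nf - n_groups * group_size), call. = FALSE)
  }
  if (group_size == 1L) return(stack)
  x <- fs_data(stack)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L], n_groups))
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * group_size + 1L):(g * group_size)
    out[, , g] <- rowMeans(x[, , idx, drop = FALSE], dims = 2L)
  }
  fs_replace(stack, out)
}

#' Percentile-based contrast stretch
#'
#' Linearly rescales a 2-D image so that the `lo_pct` percentile maps to 0
#' and the `hi_pct` percentile to 1, clipping outside `[0, 1]`. Used for
#' display normalization (e.g. a 1--99 percentile dynamic range).
#'
#' @param image Numeric matrix.
#' @param lo_pct,hi_pct Percentiles in `[0, 100]` with `lo_pct < hi_pct`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
contrast_stretch <- function(image, lo_pct = 1, hi_pct = 99) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    stop("need 0 <= lo_pct < hi_pct <= 100", call. = FALSE)
  }
  q <- stats::quantile(image, probs = c(lo_pct, hi_pct) / 100, names = FALSE,
                       type = 7)
  if (q[2L] <= q[1L]) {
    stop("degenerate percentile range (constant image?)", call. = FALSE)
  }
  pmin(pmax((image - q[1L]) / (q[2L] - q[1L]), 0), 1)
}
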