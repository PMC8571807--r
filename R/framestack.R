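#' Multiframe image stack with acquisition metadata
#'
#' A `FrameStack` is the basic container of the package: a real-valued 3-D
#' array of beamformed image frames (depth x lateral x frame) together with
#' the metadata needed to interpret it downstream. The axial (depth) axis is
#' array dimension 1 with depth increasing downward, matching B-mode display.
#'
#' @param data Numeric 3-D array, `depth_px x lateral_px x n_frames`. A 2-D
#'   matrix is promoted to a single-frame stack.
#' @param modality Either `"US"` (ultrasound) or `"PA"` (photoacoustic).
#' @param scale Either `"linear_envelope"` (non-negative envelope amplitudes)
#'   or `"log_dB"` (log-compressed; values may be negative).
#' @param frame_rate_hz Positive frame rate in Hz.
#' @param pixel_pitch_mm Length-2 positive numeric, `(axial, lateral)` pixel
#'   pitch in millimetres.
#' @param provenance Optional named list recording how the stack was produced
#'   (filter configuration, seeds, processing path). Carried along verbatim.
#'
#' @return An object of class `"FrameStack"`.
#'
#' @details Invariants enforced at construction: all values finite;
#'   `n_frames >= 1`; `linear_envelope` data non-negative. Use
#'   [fs_data()] and [n_frames()] for access.
#'
#' @examples
#' fs <- frame_stack(array(abs(rnorm(4 * 4 * 3)), c(4, 4, 3)), "US",
#'                   "linear_envelope", 20, c(0.1, 0.1))
#' n_frames(fs)
#' @export
frame_stack <- function(data, modality = c("US", "PA"),
                        scale = c("linear_envelope", "log_dB"),
                        frame_rate_hz = 20,
                        pixel_pitch_mm = c(0.1, 0.1),
                        provenance = list()) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  if (is.matrix(data)) {
    data <- array(data, c(dim(data), 1L))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (depth x lateral x frame)", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    bad <- which(apply(data, 3L, function(f) any(!is.finite(f))))
    stop(sprintf("non-finite values in frame(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (dim(data)[3L] < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (scale == "linear_envelope" && any(data < 0)) {
    stop("linear_envelope data must be non-negative", call. = FALSE)
  }
  frame_rate_hz <- as.numeric(frame_rate_hz)
  if (length(frame_rate_hz) != 1L || !is.finite(frame_rate_hz) ||
      frame_rate_hz <= 0) {
    stop("`frame_rate_hz` must be a positive number", call. = FALSE)
  }
  pixel_pitch_mm <- as.numeric(pixel_pitch_mm)
  if (length(pixel_pitch_mm) != 2L || any(!is.finite(pixel_pitch_mm)) ||
      any(pixel_pitch_mm <= 0)) {
    stop("`pixel_pitch_mm` must be two positive numbers (axial, lateral)",
         call. = FALSE)
  }
  structure(
    list(data = data, modality = modality, scale = scale,
         frame_rate_hz = frame_rate_hz, pixel_pitch_mm = pixel_pitch_mm,
         provenance = provenance),
    class = "FrameStack"
  )
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FrameStack [%s, %s]: %d x %d px, %d frame(s) @ %.3g Hz\n",
              x$modality, x$scale, d[1L], d[2L], d[3L], x$frame_rate_hz))
  cat(sprintf("  pixel pitch (axial, lateral): %.3g x %.3g mm\n",
              x$pixel_pitch_mm[1L], x$pixel_pitch_mm[2L]))
  if (length(x$provenance)) {
    cat(sprintf("  provenance: %s\n",
                paste(names(x$provenance), collapse = ", ")))
  }
  invisible(x)
}

#' Accessors for FrameStack objects
#'
#' @param x A `FrameStack`.
#' @return `fs_data()` returns the underlying 3-D array; `n_frames()` the
#'   number of frames; `fs_dim()` the full `c(depth, lateral, frames)` shape.
#' @export
fs_data <- function(x) {
  stopifnot(inherits(x, "FrameStack"))
  x$data
}

#' @rdname fs_data
#' @export
n_frames <- function(x) dim(fs_data(x))[3L]

#' @rdname fs_data
#' @export
fs_dim <- function(x) dim(fs_data(x))

#' Replace the data array of a stack, keeping metadata
#'
#' Internal helper used by filters that transform the pixel data but leave
#' the acquisition metadata intact.
#' @noRd
fs_replace <- function(x, data, scale = x$scale, provenance = x$provenance) {
  frame_stack(data, modality = x$modality, scale = scale,
              frame_rate_hz = x$frame_rate_hz,
              pixel_pitch_mm = x$pixel_pitch_mm,
              provenance = provenance)
}
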