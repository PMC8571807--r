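#' Partition an image plane into rectangular blocks
#'
#' Blocks tile the image without overlap in row-major order from the top
#' left; edge blocks shrink to the remaining pixels. Coordinates are
#' 0-based, half-open (`row_start <= r < row_end`).
#'
#' @param image_dim Integer pair `(depth_px, lateral_px)`.
#' @param block_rows_px,block_cols_px Nominal block size in pixels. A value
#'   of `0` (or anything >= the image extent) means a single block spanning
#'   that dimension.
#' @return An object of class `"BlockGrid"`: a list with `blocks` (a
#'   data.frame with columns `row_start`, `row_end`, `col_start`, `col_end`,
#'   `grid_row`, `grid_col`), `grid_dim` (blocks per dimension), `image_dim`
#'   and `block_dim`.
#' @examples
#' g <- block_grid(c(128, 126), 64, 40)
#' g$grid_dim
#' @export
block_grid <- function(image_dim, block_rows_px, block_cols_px) {
  image_dim <- as.integer(image_dim)
  stopifnot(length(image_dim) == 2L, all(image_dim >= 1L))
  block_rows_px <- as.integer(block_rows_px)
  block_cols_px <- as.integer(block_cols_px)
  if (block_rows_px <= 0L || block_rows_px > image_dim[1L]) {
    block_rows_px <- image_dim[1L]
  }
  if (block_cols_px <= 0L || block_cols_px > image_dim[2L]) {
    block_cols_px <- image_dim[2L]
  }
  row_starts <- seq.int(0L, image_dim[1L] - 1L, by = block_rows_px)
  col_starts <- seq.int(0L, image_dim[2L] - 1L, by = block_cols_px)
  blocks <- expand.grid(grid_col = seq_along(col_starts),
                        grid_row = seq_along(row_starts))
  blocks <- blocks[order(blocks$grid_row, blocks$grid_col), , drop = FALSE]
  blocks$row_start <- row_starts[blocks$grid_row]
  blocks$row_end <- pmin(blocks$row_start + block_rows_px, image_dim[1L])
  blocks$col_start <- col_starts[blocks$grid_col]
  blocks$col_end <- pmin(blocks$col_start + block_cols_px, image_dim[2L])
  rownames(blocks) <- NULL
  structure(
    list(blocks = blocks[, c("row_start", "row_end", "col_start", "col_end",
                             "grid_row", "grid_col")],
         grid_dim = c(length(row_starts), length(col_starts)),
         image_dim = image_dim,
         block_dim = c(block_rows_px, block_cols_px)),
    class = "BlockGrid"
  )
}

#' @export
print.BlockGrid <- function(x, ...) {
  cat(sprintf("BlockGrid: %d x %d px image, nominal blocks %d x %d px, grid %d x %d (%d blocks)\n",
              x$image_dim[1L], x$image_dim[2L], x$block_dim[1L],
              x$block_dim[2L], x$grid_dim[1L], x$grid_dim[2L],
              nrow(x$blocks)))
  invisible(x)
}

#' Build the Casorati matrix of one block
#'
#' Reshapes the spatiotemporal data of a rectangular block into a
#' `pixels x frames` matrix: row `k` is the time series of the `k`-th pixel
#' of the block in row-major order. This is the spatiotemporal matrix whose
#' singular-value structure the filter thresholds.
#'
#' @param stack A `FrameStack` with at least 2 frames.
#' @param block A one-row slice of `BlockGrid$blocks` (or any list with
#'   `row_start`, `row_end`, `col_start`, `col_end`, 0-based half-open).
#' @return Numeric matrix of size `(block pixels) x n_frames`.
#' @seealso [scatter_block()] for the inverse placement.
#' @export
build_casorati <- function(stack, block) {
  x <- fs_data(stack)
  if (dim(x)[3L] < 2L) stop("need at least 2 frames", call. = FALSE)
  rs <- (block$row_start + 1L):block$row_end
  cs <- (block$col_start + 1L):block$col_end
  if (block$row_end <= block$row_start || block$col_end <= block$col_start) {
    stop("empty block", call. = FALSE)
  }
  if (block$row_start < 0L || block$col_start < 0L ||
      block$row_end > dim(x)[1L] || block$col_end > dim(x)[2L]) {
    stop("block exceeds image bounds", call. = FALSE)
  }
  sub <- x[rs, cs, , drop = FALSE]
  br <- length(rs); bc <- length(cs); nf <- dim(x)[3L]
  # row-major pixel order: transpose the spatial dims before flattening
  m <- aperm(sub, c(2L, 1L, 3L))
  dim(m) <- c(br * bc, nf)
  m
}

#' Scatter a Casorati-shaped block matrix back into a 3-D stack
#'
#' Inverse of [build_casorati()]: writes the `pixels x frames` matrix into
#' the block's position of a target array (in place semantics via return).
#'
#' @param target Numeric 3-D array to write into.
#' @param block Block coordinates as for [build_casorati()].
#' @param casorati Matrix as produced by [build_casorati()].
#' @return The updated array.
#' @export
scatter_block <- function(target, block, casorati) {
  rs <- (block$row_start + 1L):block$row_end
  cs <- (block$col_start + 1L):block$col_end
  br <- length(rs); bc <- length(cs)
  nf <- ncol(casorati)
  stopifnot(nrow(casorati) == br * bc)
  sub <- casorati
  dim(sub) <- c(bc, br, nf)
  target[rs, cs, ] <- aperm(sub, c(2L, 1L, 3L))
  target
}
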