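# Hierarchical array container: a directory per container, a subdirectory
# per group, each holding meta.json (jsonlite) and data.bin (little-endian
# float64, column-major). Chosen over TIFF/HDF5 because no R binding for
# either is guaranteed in the runtime environment; the layout is
# self-describing and lossless.

required_stack_attrs <- c("modality", "scale", "frame_rate_hz",
                          "pixel_pitch_mm", "dim")

container_group_dir <- function(path, group) {
  file.path(path, gsub("^/+", "", group))
}

#' Write an array group into a container
#'
#' Low-level writer used by [write_stack()]: stores `arr` as little-endian
#' float64 with a JSON metadata sidecar.
#'
#' @param path Container directory (created if missing).
#' @param group Group name, e.g. `"us"` or `"components/flow"`.
#' @param arr Numeric array or matrix.
#' @param meta Named list of attributes stored alongside the dimensions.
#' @return The group directory, invisibly.
#' @export
container_write_array <- function(path, group, arr, meta = list()) {
  gd <- container_group_dir(path, group)
  dir.create(gd, recursive = TRUE, showWarnings = FALSE)
  meta$dim <- if (is.null(dim(arr))) length(arr) else dim(arr)
  jsonlite::write_json(meta, file.path(gd, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(gd, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  invisible(gd)
}

#' Read an array group from a container
#'
#' @param path Container directory.
#' @param group Group name.
#' @return List with `data` (array with restored dimensions) and `meta`.
#' @export
container_read_array <- function(path, group) {
  gd <- container_group_dir(path, group)
  mf <- file.path(gd, "meta.json")
  bf <- file.path(gd, "data.bin")
  if (!file.exists(mf) || !file.exists(bf)) {
    stop(sprintf("group '%s' not found in container '%s'", group, path),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$dim)) stop("container metadata lacks 'dim'", call. = FALSE)
  n <- prod(meta$dim)
  con <- file(bf, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) {
    stop(sprintf("group '%s': expected %d values, found %d", group, n,
                 length(x)), call. = FALSE)
  }
  dim(x) <- meta$dim
  list(data = x, meta = meta)
}

#' Write a FrameStack into a container group
#'
#' @param stack A `FrameStack`.
#' @param path Container directory.
#' @param group Group name (default the lower-cased modality).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, group = tolower(stack$modality)) {
  stopifnot(inherits(stack, "FrameStack"))
  meta <- list(modality = stack$modality, scale = stack$scale,
               frame_rate_hz = stack$frame_rate_hz,
               pixel_pitch_mm = stack$pixel_pitch_mm)
  if (length(stack$provenance)) meta$provenance <- stack$provenance
  container_write_array(path, group, fs_data(stack), meta)
  invisible(path)
}

#' Read a FrameStack from a container group
#'
#' Validates the declared layout: all required attributes must be present
#' (a missing one is named in the error), the array must be 3-D with axis
#' order depth x lateral x frame, and values must be finite (NaNs are
#' reported with their count and first location).
#'
#' @param path Container directory.
#' @param group Group name (default `"us"`).
#' @return A `FrameStack`.
#' @export
read_stack <- function(path, group = "us") {
  got <- container_read_array(path, group)
  missing_attrs <- setdiff(required_stack_attrs, names(got$meta))
  if (length(missing_attrs)) {
    stop(sprintf("container group '%s' is missing attribute(s): %s",
                 group, paste(missing_attrs, collapse = ", ")),
         call. = FALSE)
  }
  x <- got$data
  if (length(dim(x)) != 3L) {
    stop(sprintf("group '%s': expected 3-D (depth x lateral x frame) data, got %d dims",
                 group, length(dim(x))), call. = FALSE)
  }
  bad <- !is.finite(x)
  if (any(bad)) {
    first <- arrayInd(which(bad)[1L], dim(x))
    stop(sprintf("group '%s': %d non-finite value(s); first at (row %d, col %d, frame %d)",
                 group, sum(bad), first[1L], first[2L], first[3L]),
         call. = FALSE)
  }
  prov <- got$meta$provenance
  frame_stack(x, modality = got$meta$modality, scale = got$meta$scale,
              frame_rate_hz = got$meta$frame_rate_hz,
              pixel_pitch_mm = unlist(got$meta$pixel_pitch_mm),
              provenance = if (is.null(prov)) list() else prov)
}

#' Load a filter configuration from a flat YAML file
#'
#' Keys are validated against [filter_config()]; unknown keys are an
#' error so that typos never silently fall back to defaults. The returned
#' list always contains every parameter, so the provenance of a run records
#' defaulted values explicitly.
#'
#' @param file Path to a flat key--value YAML file (may be absent fields).
#' @return A complete [filter_config()] list.
#' @export
load_filter_config <- function(file) {
  vals <- yaml::read_yaml(file)
  if (is.null(vals)) vals <- list()
  do.call(filter_config, vals)
}

#' Load a phantom configuration from a flat YAML file
#'
#' @param file Path to a flat key--value YAML file.
#' @return A [phantom_config()].
#' @export
load_phantom_config <- function(file) {
  vals <- yaml::read_yaml(file)
  if (is.null(vals)) vals <- list()
  do.call(phantom_config, vals)
}

#' Write run provenance into a container
#'
#' @param path Container directory.
#' @param provenance Named list (configuration snapshot, thresholds, seeds,
#'   timestamps).
#' @return The file path, invisibly.
#' @export
write_provenance <- function(path, provenance) {
  dir.create(file.path(path, "provenance"), recursive = TRUE,
             showWarnings = FALSE)
  f <- file.path(path, "provenance", "provenance.json")
  provenance$software <- list(
    package = "pasvd",
    version = as.character(utils::packageVersion("pasvd")))
  provenance$written_at <- format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ")
  jsonlite::write_json(provenance, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(f)
}
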