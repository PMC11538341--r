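#' File interfaces
#'
#' Bead stacks and frame series travel as multi-page 16-bit TIFF with a
#' JSON sidecar holding the physical metadata; segmentation masks as
#' integer-label TIFF.  All helpers preserve integer gray levels exactly
#' up to 65535.
#'
#' @name io
NULL

#' Write / read a bead z-stack as multi-page TIFF + JSON sidecar
#'
#' @param stack a [bead_stack()]
#' @param path TIFF path; `<path>.json` holds dx, dy, dz, z0_index and the
#'   intensity scale
#' @return `path` (write) / a [bead_stack()] (read)
#' @export
write_bead_stack <- function(stack, path) {
  v <- stack$voxels
  scale <- max(v)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(dx = stack$dx, dy = stack$dy, dz = stack$dz,
                            z0_index = stack$z0_index, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bead_stack
#' @export
read_bead_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]] * meta$scale
  bead_stack(v, meta$dx, meta$dy, meta$dz, meta$z0_index)
}

#' Write / read an integer label mask as TIFF
#'
#' @param masks a [cell_mask_set()]
#' @param path TIFF path; pixel size goes in the JSON sidecar
#' @return `path` (write) / a [cell_mask_set()] (read)
#' @export
write_mask_tiff <- function(masks, path) {
  tiff::writeTIFF(masks$labels / 65535, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size = masks$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- tiff::readTIFF(path, as.is = TRUE)
  cell_mask_set(matrix(as.integer(lab), nrow(lab)), meta$pixel_size)
}

#' Write / read a gray-level frame series as multi-page TIFF
#'
#' @param frames list of integer-valued matrices (gray levels)
#' @param path TIFF path
#' @param bit_depth sensor maximum (values are stored as 16-bit)
#' @return `path` (write) / list of matrices (read)
#' @export
write_frames <- function(frames, path, bit_depth = 4095) {
  if (is.matrix(frames)) frames <- list(frames)
  tiff::writeTIFF(lapply(frames, function(f) f / 65535), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(pages, function(p) matrix(as.numeric(p), nrow(p)))
}
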