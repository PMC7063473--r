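#' Volume and fluence file I/O
#'
#' Labeled volumes are stored as raw unsigned 8-bit label binaries
#' (`<prefix>_labels.bin`, x fastest, then y, then z) with a JSON sidecar
#' (`<prefix>_labels.json`) carrying `nx, ny, nz, dx, dy, dz`, the label
#' map, and the frame convention. Fluence fields are stored likewise as
#' 32-bit little-endian float binaries (`<prefix>_fluence.bin`) with a
#' sidecar echoing the grid, normalization, seed and configuration. Readers
#' verify that the binary payload length matches the sidecar dimensions.
#'
#' @param volume a `labeled_volume`.
#' @param prefix file path prefix (directory must exist).
#' @return the prefix, invisibly; readers return the reconstructed object.
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume <- function(volume, prefix) {
  s <- volume$spec
  if (max(volume$labels) > 255L) stop("labels above 255 cannot be stored as uint8")
  bin <- paste0(prefix, "_labels.bin")
  writeBin(as.raw(as.integer(volume$labels)), bin)
  jsonlite::write_json(
    list(nx = s$nx, ny = s$ny, nz = s$nz, dx = s$dx, dy = s$dy, dz = s$dz,
         label_map = volume$label_map,
         frame = "x mediolateral, y dorsoventral (0 = dorsal face), z rostrocaudal",
         order = "x fastest, then y, then z", dtype = "uint8"),
    paste0(prefix, "_labels.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(prefix)
}

#' @rdname volume_io
#' @export
read_volume <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, "_labels.json"),
                              simplifyVector = FALSE)
  n <- side$nx * side$ny * side$nz
  bin <- paste0(prefix, "_labels.bin")
  if (file.info(bin)$size != n)
    stop(sprintf("sidecar says %d voxels but '%s' holds %d bytes", n, bin,
                 file.info(bin)$size))
  labels <- as.integer(readBin(bin, "raw", n = n))
  spec <- voxel_spec(side$nx, side$ny, side$nz, side$dx, side$dy, side$dz)
  .new_volume(spec, array(labels, c(side$nx, side$ny, side$nz)),
              side$label_map)
}

#' @rdname volume_io
#' @param result a `fluence_result`.
#' @export
write_fluence <- function(result, prefix) {
  s <- result$spec
  writeBin(as.numeric(result$fluence), paste0(prefix, "_fluence.bin"),
           size = 4, endian = "little")
  jsonlite::write_json(
    list(nx = s$nx, ny = s$ny, nz = s$nz, dx = s$dx, dy = s$dy, dz = s$dz,
         normalization = "fluence per delivered watt (mm^-2 W^-1)",
         dtype = "float32_le", order = "x fastest, then y, then z",
         n_photons = result$n_photons, seed = result$seed,
         wavelength_nm = result$wavelength,
         combination_mode = result$combination_mode,
         escaped_fraction = result$escaped_fraction,
         lost_fraction = result$lost_fraction),
    paste0(prefix, "_fluence.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(prefix)
}

#' @rdname volume_io
#' @export
read_fluence <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, "_fluence.json"),
                              simplifyVector = FALSE)
  n <- side$nx * side$ny * side$nz
  bin <- paste0(prefix, "_fluence.bin")
  if (file.info(bin)$size != 4 * n)
    stop(sprintf("sidecar says %d voxels but '%s' holds %d bytes", n, bin,
                 file.info(bin)$size))
  f <- readBin(bin, "numeric", n = n, size = 4, endian = "little")
  list(fluence = array(f, c(side$nx, side$ny, side$nz)), sidecar = side)
}
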