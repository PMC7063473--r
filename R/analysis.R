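#' Intensity map at a delivered power
#'
#' Scales the per-watt fluence field to an intensity map in mW/mm^2 for a
#' given delivered power: fluence (mm^-2 per delivered W) times power (mW)
#' gives mW/mm^2 element-wise; the map is linear in power.
#'
#' @param result a `fluence_result` from [run_mc()].
#' @param power delivered power (mW); defaults to the source power.
#' @return 3-D array of intensity (mW/mm^2).
#' @export
intensity_map <- function(result, power = result$source$power) {
  if (power < 0) stop("power must be >= 0")
  result$fluence * power
}

#' Channelrhodopsin activation mask
#'
#' Voxels whose intensity reaches the opsin activation threshold and that
#' contain tissue (label > 0). The conventional threshold for
#' channelrhodopsin is 1 mW/mm^2.
#'
#' @param intensity 3-D intensity array (mW/mm^2), from [intensity_map()].
#' @param volume the `labeled_volume` the field was computed on.
#' @param threshold activation threshold (mW/mm^2), > 0.
#' @return logical 3-D array.
#' @export
activation_mask <- function(intensity, volume, threshold = 1) {
  if (threshold <= 0) stop("threshold must be positive")
  intensity >= threshold & volume$labels > 0L
}

#' Dorsoventral activation depth
#'
#' Maximal depth of activation below the dorsal tissue surface: for every
#' activated voxel, the distance from its center down to the surface of the
#' first tissue voxel in its own (x, z) column (see [dorsal_surface()]);
#' the maximum over the mask is returned. Returns 0 for an empty mask.
#'
#' @param mask logical 3-D activation mask.
#' @param volume the `labeled_volume`.
#' @return depth (mm).
#' @export
activation_depth_dv <- function(mask, volume) {
  if (!any(mask)) return(0)
  s <- volume$spec
  surf <- dorsal_surface(volume)  # nx x nz, top face of first tissue voxel
  idx <- which(mask, arr.ind = TRUE)
  yc <- (idx[, 2] - 0.5) * s$dy
  max(yc - surf[cbind(idx[, 1], idx[, 3])], na.rm = TRUE)
}

#' Longitudinal activation extent
#'
#' Maximal distance of any activated voxel from the fiber tip's midline
#' along the cord axis z. With a symmetric phantom and source the extent is
#' the same in both directions to within one voxel.
#'
#' @param mask logical 3-D activation mask.
#' @param volume the `labeled_volume`.
#' @param source the [source_spec()] (its tip z is the midline).
#' @return extent (mm); 0 for an empty mask.
#' @export
activation_extent_long <- function(mask, volume, source) {
  if (!any(mask)) return(0)
  s <- volume$spec
  iz <- which(mask, arr.ind = TRUE)[, 3]
  zc <- (iz - 0.5) * s$dz
  max(abs(zc - source$tip_position[3]))
}

#' Along-fiber vs across-fiber extent ratio of the activation contour
#'
#' For a beam entering the tissue perpendicular to the fiber tracts (beam
#' along y, fibers along z), the ratio of the threshold iso-contour's
#' maximal extent along z to its maximal extent along x, both measured from
#' the beam axis at voxel-center resolution. A ratio above 1 means the
#' light distribution is elongated along the fiber tracts.
#'
#' @param intensity 3-D intensity array (mW/mm^2).
#' @param volume the `labeled_volume`.
#' @param source the [source_spec()]; its beam axis must be perpendicular
#'   to z.
#' @param threshold iso-level (mW/mm^2).
#' @return list with `ratio`, `extent_z`, `extent_x` (mm).
#' @export
extent_ratio <- function(intensity, volume, source, threshold = 1) {
  if (abs(source$beam_axis[3]) > 1e-9)
    stop("extent_ratio requires a beam perpendicular to the fiber (z) axis")
  mask <- activation_mask(intensity, volume, threshold)
  if (!any(mask)) stop("threshold iso-surface is empty")
  s <- volume$spec
  idx <- which(mask, arr.ind = TRUE)
  ez <- max(abs((idx[, 3] - 0.5) * s$dz - source$tip_position[3]))
  ex <- max(abs((idx[, 1] - 0.5) * s$dx - source$tip_position[1]))
  list(ratio = ez / ex, extent_z = ez, extent_x = ex)
}

#' Optogenetic activation metrics
#'
#' Summarizes a fluence field into planning metrics at an opsin threshold:
#' activated tissue volume, maximal dorsoventral activation depth from the
#' dorsal surface, maximal longitudinal extent from the fiber midline, and
#' (when the beam is perpendicular to the fiber axis) the along- vs
#' across-fiber extent ratio of the threshold contour.
#'
#' @param result a `fluence_result`.
#' @param volume the `labeled_volume` it was computed on.
#' @param source the [source_spec()].
#' @param power delivered power (mW).
#' @param threshold activation threshold (mW/mm^2).
#' @return object of class `activation_metrics`.
#' @export
activation_metrics <- function(result, volume, source,
                               power = source$power, threshold = 1) {
  inten <- intensity_map(result, power)
  mask <- activation_mask(inten, volume, threshold)
  s <- volume$spec
  ratio <- if (abs(source$beam_axis[3]) < 1e-9 && any(mask))
    extent_ratio(inten, volume, source, threshold)$ratio else NA_real_
  structure(list(threshold = threshold, power = power,
                 activated_volume = sum(mask) * s$dx * s$dy * s$dz,
                 depth_dv = activation_depth_dv(mask, volume),
                 extent_long = activation_extent_long(mask, volume, source),
                 extent_ratio = ratio,
                 n_photons = result$n_photons, seed = result$seed,
                 wavelength = result$wavelength),
            class = "activation_metrics")
}

#' @export
print.activation_metrics <- function(x, ...) {
  cat(sprintf("<activation_metrics> %g mW at threshold %g mW/mm^2\n",
              x$power, x$threshold))
  cat(sprintf("  activated volume   %.4g mm^3\n", x$activated_volume))
  cat(sprintf("  dorsoventral depth %.3g mm\n", x$depth_dv))
  cat(sprintf("  longitudinal extent %.3g mm from the fiber midline\n",
              x$extent_long))
  if (!is.na(x$extent_ratio))
    cat(sprintf("  along/across-fiber extent ratio %.3f (+%.1f%%)\n",
                x$extent_ratio, 100 * (x$extent_ratio - 1)))
  invisible(x)
}

#' Write activation metrics as a JSON report
#'
#' @param metrics an [activation_metrics()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(
    list(threshold_mw_mm2 = metrics$threshold, power_mw = metrics$power,
         activated_volume_mm3 = metrics$activated_volume,
         depth_dv_mm = metrics$depth_dv,
         extent_long_mm = metrics$extent_long,
         extent_ratio = metrics$extent_ratio,
         n_photons = metrics$n_photons, seed = metrics$seed,
         wavelength_nm = metrics$wavelength),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
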