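#' Voxel grid specification
#'
#' Regular 3-D voxel grid. Frame convention: x is mediolateral, y is
#' dorsoventral (y increases ventrally from the dorsal face at y = 0), z is
#' the rostrocaudal cord axis. Voxel (i, j, k) (0-based) covers the
#' half-open box `[i dx, (i+1) dx) x ...`; positions are in mm from the grid
#' corner.
#'
#' @param nx,ny,nz voxel counts (>= 1).
#' @param dx,dy,dz voxel pitch (mm, > 0); `dy`, `dz` default to `dx`.
#' @param cap maximum total voxel count permitted (guards accidental huge
#'   allocations).
#' @return object of class `voxel_spec`.
#' @export
voxel_spec <- function(nx, ny, nz, dx, dy = dx, dz = dx, cap = 2e7) {
  n <- c(nx, ny, nz); d <- c(dx, dy, dz)
  if (any(n < 1) || any(n != as.integer(n))) stop("voxel counts must be positive integers")
  if (any(d <= 0)) stop("voxel pitch must be positive")
  if (prod(n) > cap)
    stop(sprintf("grid of %.3g voxels exceeds the cap of %.3g", prod(n), cap))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), dx = dx, dy = dy, dz = dz),
            class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat(sprintf("<voxel_spec> %d x %d x %d voxels, pitch %g x %g x %g mm (%g x %g x %g mm)\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz,
              x$nx * x$dx, x$ny * x$dy, x$nz * x$dz))
  invisible(x)
}

.new_volume <- function(spec, labels, label_map) {
  storage.mode(labels) <- "integer"
  dim(labels) <- c(spec$nx, spec$ny, spec$nz)
  used <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing <- setdiff(used, as.integer(names(label_map)))
  if (length(missing))
    stop("labels without a label_map entry: ", paste(missing, collapse = ", "))
  structure(list(spec = spec, labels = labels, label_map = label_map),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume>\n  ")
  print(x$spec)
  tab <- table(factor(x$labels, levels = c(0L, as.integer(names(x$label_map)))))
  nm <- c("(background)", unlist(x$label_map, use.names = FALSE))
  for (i in seq_along(tab))
    cat(sprintf("  label %s %-14s %d voxels\n", names(tab)[i], nm[i], tab[i]))
  invisible(x)
}

# voxel-center coordinates along one axis
.centers <- function(n, d) (seq_len(n) - 0.5) * d

#' Homogeneous block phantom
#'
#' All voxels carry one tissue label. Mostly a test fixture, but also the
#' geometry for the homogeneous white-matter elongation experiment.
#'
#' @param spec a [voxel_spec()].
#' @param label tissue label (0 = empty surrounding medium).
#' @param name tissue name recorded in the label map.
#' @return a `labeled_volume`.
#' @export
homogeneous_block <- function(spec, label = 1L, name = "tissue") {
  lm <- if (label > 0) setNames(list(name), label) else list()
  .new_volume(spec, array(as.integer(label), c(spec$nx, spec$ny, spec$nz)),
              lm)
}

#' Layered slab phantom
#'
#' Layers stacked along +y from the dorsal face (y = 0); thicknesses are
#' realized to the nearest voxel plane. Any remaining planes below the stack
#' are background (label 0). Zero-thickness layers are skipped with a
#' warning.
#'
#' @param spec a [voxel_spec()].
#' @param layers list of `c(thickness_mm, label)` pairs (or a 2-column
#'   matrix).
#' @param label_map named list mapping labels to tissue names; defaults to
#'   `"tissue_<label>"`.
#' @return a `labeled_volume`.
#' @export
layered_slab <- function(spec, layers, label_map = NULL) {
  if (is.matrix(layers)) layers <- lapply(seq_len(nrow(layers)),
                                          function(i) layers[i, ])
  th <- vapply(layers, `[`, numeric(1), 1)
  lb <- vapply(layers, `[`, numeric(1), 2)
  if (any(th < 0)) stop("layer thicknesses must be >= 0")
  if (any(th == 0)) {
    warning("skipping zero-thickness layer(s)")
    lb <- lb[th > 0]; th <- th[th > 0]
  }
  if (sum(th) > spec$ny * spec$dy + 1e-9)
    stop("layer stack exceeds the grid extent along y")
  planes <- pmin(round(cumsum(th) / spec$dy), spec$ny)
  labels <- array(0L, c(spec$nx, spec$ny, spec$nz))
  start <- 0L
  for (i in seq_along(th)) {
    if (planes[i] > start)
      labels[, (start + 1L):planes[i], ] <- as.integer(lb[i])
    start <- planes[i]
  }
  if (is.null(label_map)) {
    u <- setdiff(sort(unique(as.integer(lb))), 0L)
    label_map <- setNames(as.list(paste0("tissue_", u)), u)
  }
  .new_volume(spec, labels, label_map)
}

#' Species geometry presets for the cord phantom
#'
#' To-scale approximations of transverse spinal-cord anatomy: an elliptical
#' cord outline (white matter) with a butterfly-shaped gray-matter core
#' built from two mirrored dorsal horns, two ventral horns, and a central
#' commissure band. Dimensions are in mm; the butterfly scales with the cord
#' ellipse. These are documented approximations - transverse cord anatomy
#' varies along the cord and between individuals.
#'
#' @param species `"mouse"`, `"macaque"`, or `"human"`.
#' @return list of class `species_preset` with fields `species`, `cord_a`
#'   and `cord_b` (ellipse semi-axes, mediolateral and dorsoventral),
#'   `wm_dorsal` (dorsal white-matter thickness above the gray matter),
#'   butterfly parameters, and a default voxel `pitch`.
#' @export
species_preset <- function(species = c("mouse", "macaque", "human")) {
  species <- match.arg(species)
  base <- list(
    mouse   = list(cord_a = 1.2, cord_b = 0.9, wm_dorsal = 0.35, pitch = 0.02),
    macaque = list(cord_a = 4.0, cord_b = 3.0, wm_dorsal = 1.20, pitch = 0.05),
    human   = list(cord_a = 6.0, cord_b = 4.25, wm_dorsal = 1.80, pitch = 0.05)
  )[[species]]
  sx <- base$cord_a / 1.2; sy <- base$cord_b / 0.9
  p <- list(species = species, cord_a = base$cord_a, cord_b = base$cord_b,
            wm_dorsal = base$wm_dorsal, pitch = base$pitch,
            # dorsal horns: semi-axes and mediolateral center offset
            dorsal_horn_length = 0.55 * sy, dorsal_horn_width = 0.35 * sx,
            dorsal_horn_offset = 0.38 * sx,
            # ventral horns
            ventral_horn_length = 0.60 * sy, ventral_horn_width = 0.55 * sx,
            ventral_horn_offset = 0.42 * sx, ventral_horn_center = 0.28 * sy,
            # central commissure band
            commissure_thickness = 0.30 * sy, commissure_width = 1.00 * sx)
  # dorsal horn tip must sit wm_dorsal below the dorsal cord surface
  p$dorsal_horn_center <- -(base$cord_b - base$wm_dorsal -
                              p$dorsal_horn_length / 2)
  structure(p, class = "species_preset")
}

# butterfly membership for cross-section coordinates relative to cord center
# (xr = |x - x0| to keep exact bilateral symmetry, yv positive ventral)
.in_butterfly <- function(xr, yv, p) {
  in_ell <- function(cx, cy, ax, by)
    ((xr - cx) / ax)^2 + ((yv - cy) / by)^2 <= 1
  dorsal <- in_ell(p$dorsal_horn_offset, p$dorsal_horn_center,
                   p$dorsal_horn_width / 2, p$dorsal_horn_length / 2)
  ventral <- in_ell(p$ventral_horn_offset, p$ventral_horn_center,
                    p$ventral_horn_width / 2, p$ventral_horn_length / 2)
  commissure <- abs(yv) <= p$commissure_thickness / 2 &
    xr <= p$commissure_width / 2
  dorsal | ventral | commissure
}

#' Procedural spinal-cord phantom
#'
#' Voxelizes the transverse cord cross-section of a [species_preset()] and
#' extrudes it uniformly along z (the fiber tracts run along z). Voxels
#' inside the gray-matter butterfly get label 2, the rest of the cord
#' ellipse label 1 (white matter), and everything outside the cord label 0
#' (surrounding escape medium). The dorsal-most point of the cord touches
#' the y = 0 grid face, where an illumination fiber is typically placed.
#'
#' @param preset a [species_preset()] or a species name.
#' @param spec optional [voxel_spec()]; by default a grid with the preset's
#'   pitch, a small mediolateral margin, and `z_extent_mm` of cord length.
#' @param z_extent_mm grid length along the cord axis when `spec` is NULL.
#' @return a `labeled_volume` with label map `1 = white_matter,
#'   2 = gray_matter`.
#' @export
cord_phantom <- function(preset, spec = NULL, z_extent_mm = 4) {
  if (is.character(preset)) preset <- species_preset(preset)
  if (is.null(spec)) {
    d <- preset$pitch
    nx <- 2L * ceiling((preset$cord_a + 0.1) / d)
    ny <- ceiling((2 * preset$cord_b + 2 * d) / d)
    nz <- ceiling(z_extent_mm / d)
    spec <- voxel_spec(nx, ny, nz, d)
  }
  if (2 * preset$cord_a > spec$nx * spec$dx ||
      2 * preset$cord_b > spec$ny * spec$dy)
    stop("cord ellipse does not fit inside the grid cross-section")
  x0 <- spec$nx * spec$dx / 2
  xr <- abs(.centers(spec$nx, spec$dx) - x0)
  yv <- .centers(spec$ny, spec$dy) - preset$cord_b  # 0 at cord center
  g <- expand.grid(xr = xr, yv = yv)
  in_cord <- (g$xr / preset$cord_a)^2 + (g$yv / preset$cord_b)^2 <= 1
  in_gm <- in_cord & .in_butterfly(g$xr, g$yv, preset)
  cross <- matrix(0L, spec$nx, spec$ny)
  cross[in_cord] <- 1L
  cross[in_gm] <- 2L
  labels <- array(cross, c(spec$nx, spec$ny, spec$nz))
  .new_volume(spec, labels,
              label_map = list(`1` = "white_matter", `2` = "gray_matter"))
}

#' Dorsal tissue surface height per (x, z) column
#'
#' y-coordinate (mm) of the top face of the first tissue voxel in each
#' dorsoventral column, NA where a column holds no tissue. Activation depth
#' is measured from this surface, since the fiber sits against the cord.
#'
#' @param volume a `labeled_volume`.
#' @return `nx` x `nz` matrix of surface heights (mm).
#' @export
dorsal_surface <- function(volume) {
  s <- volume$spec
  first <- apply(volume$labels > 0L, c(1, 3), function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  (first - 1L) * s$dy
}
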