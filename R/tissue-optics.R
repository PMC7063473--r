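#' Wavelength power-law scaling of the reduced scattering coefficient
#'
#' Scales a reduced scattering coefficient measured at a reference wavelength
#' to a simulation wavelength with the generic-tissue power law
#' \eqn{\mu_s'(\lambda) = \mu_s'(\lambda_{ref}) (\lambda/\lambda_{ref})^{-b}}.
#' This is the standard way to carry a single-wavelength measurement (here
#' typically 633 nm, chosen to minimize hemoglobin absorption) to an
#' optogenetic excitation wavelength such as 473 nm.
#'
#' @param mus_prime_ref reduced scattering coefficient at `lambda_ref`
#'   (mm^-1).
#' @param lambda_ref reference wavelength (nm).
#' @param lambda_sim target wavelength (nm).
#' @param b scattering power-law exponent (dimensionless, >= 0). Brain-like
#'   soft tissue is typically near 1.6.
#' @return reduced scattering coefficient at `lambda_sim` (mm^-1).
#' @examples
#' scale_scattering(1.57, 633, 473, b = 1.6)
#' @export
scale_scattering <- function(mus_prime_ref, lambda_ref, lambda_sim, b) {
  if (any(mus_prime_ref < 0)) stop("mus_prime_ref must be >= 0")
  if (any(lambda_ref <= 0) || any(lambda_sim <= 0))
    stop("wavelengths must be positive")
  if (any(b < 0)) stop("b must be >= 0")
  mus_prime_ref * (lambda_sim / lambda_ref)^(-b)
}

#' Whole-blood absorption spectrum
#'
#' Returns the packaged whole-blood absorption table: absorption coefficient
#' of fully oxygenated and fully deoxygenated whole blood (150 g/L
#' hemoglobin) on a 450-700 nm grid. The table is an approximate compilation
#' of the standard literature oxy/deoxy-hemoglobin molar extinction values,
#' converted to whole-blood mu_a; it is packaged data, not a measurement made
#' by this package.
#'
#' @return data.frame with columns `wavelength_nm`, `mua_oxy_mm`,
#'   `mua_deoxy_mm` (mm^-1).
#' @export
hb_extinction <- function() {
  if (is.null(.sl_cache$hb)) {
    path <- system.file("extdata", "hemoglobin_whole_blood.csv",
                        package = "spinelight", mustWork = TRUE)
    .sl_cache$hb <- read.csv(path, comment.char = "#")
  }
  .sl_cache$hb
}

.sl_cache <- new.env(parent = emptyenv())

#' Absorption coefficient of perfused tissue from blood content
#'
#' Adds hemoglobin absorption to a bloodless baseline:
#' \deqn{\mu_a = \mu_{a,base} + B [S \mu_{a,oxy}(\lambda) +
#'   (1-S)\mu_{a,deoxy}(\lambda)]}
#' with `B` the blood volume fraction and `S` the hemoglobin oxygen
#' saturation. Whole-blood spectra are linearly interpolated on the packaged
#' wavelength grid; wavelengths outside the grid are an error (no
#' extrapolation).
#'
#' @param B blood volume fraction in `[0, 1]`.
#' @param S oxygen saturation in `[0, 1]`.
#' @param lambda_nm wavelength (nm), inside the table range.
#' @param mua_baseline bloodless absorption coefficient (mm^-1).
#' @param table extinction table, default the packaged [hb_extinction()].
#' @return absorption coefficient (mm^-1).
#' @export
blood_absorption <- function(B, S, lambda_nm, mua_baseline = 0,
                             table = hb_extinction()) {
  if (any(B < 0 | B > 1)) stop("B must be in [0, 1]")
  if (any(S < 0 | S > 1)) stop("S must be in [0, 1]")
  if (any(mua_baseline < 0)) stop("mua_baseline must be >= 0")
  rng <- range(table$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2]))
    stop(sprintf("wavelength %g nm outside extinction table range [%g, %g]",
                 lambda_nm[1], rng[1], rng[2]))
  oxy <- approx(table$wavelength_nm, table$mua_oxy_mm, xout = lambda_nm)$y
  deoxy <- approx(table$wavelength_nm, table$mua_deoxy_mm, xout = lambda_nm)$y
  mua_baseline + B * (S * oxy + (1 - S) * deoxy)
}

#' Similarity conversion from reduced to full scattering coefficient
#'
#' @param mus_prime reduced scattering coefficient (mm^-1).
#' @param g scattering anisotropy factor, `0 <= g < 1`.
#' @return full scattering coefficient \eqn{\mu_s = \mu_s'/(1-g)} (mm^-1).
#' @export
reduced_to_full <- function(mus_prime, g) {
  if (any(mus_prime < 0)) stop("mus_prime must be >= 0")
  if (any(g < 0 | g >= 1)) stop("g must satisfy 0 <= g < 1")
  mus_prime / (1 - g)
}

#' Tissue class definition
#'
#' A tissue type as used by the generic-tissue model: direction-resolved
#' reduced scattering at a reference wavelength, scattering power-law
#' exponent, anisotropy factor, bloodless absorption, and blood content.
#' `fiber_axis` names the Cartesian axis the organized fibers (and hence the
#' longitudinal mu_s') run along; `"isotropic"` collapses the two measured
#' directions to their mean on all three axes, which is the default reading
#' for gray matter where myelin organization is nearly random.
#'
#' @param name tissue name.
#' @param label small positive integer voxel label.
#' @param mus_prime_long_ref,mus_prime_rad_ref reduced scattering along /
#'   perpendicular to the fiber axis at `lambda_ref` (mm^-1).
#' @param lambda_ref reference wavelength (nm).
#' @param b scattering power-law exponent.
#' @param g anisotropy factor, `0 <= g < 1`.
#' @param mua_baseline bloodless absorption coefficient (mm^-1).
#' @param blood_volume_fraction,oxygen_saturation blood content in `[0, 1]`.
#' @param fiber_axis one of `"x"`, `"y"`, `"z"`, `"isotropic"`.
#' @return object of class `tissue_class`.
#' @export
tissue_class <- function(name, label, mus_prime_long_ref, mus_prime_rad_ref,
                         lambda_ref = 633, b = 1.6, g = 0.9,
                         mua_baseline = 0.05, blood_volume_fraction = 0,
                         oxygen_saturation = 0,
                         fiber_axis = c("z", "x", "y", "isotropic")) {
  fiber_axis <- match.arg(fiber_axis)
  stopifnot(is.character(name), length(name) == 1,
            label == as.integer(label), label >= 1)
  if (mus_prime_long_ref < 0 || mus_prime_rad_ref < 0)
    stop("reduced scattering coefficients must be >= 0")
  if (mua_baseline < 0) stop("mua_baseline must be >= 0")
  if (g < 0 || g >= 1) stop("g must satisfy 0 <= g < 1")
  if (lambda_ref <= 0) stop("lambda_ref must be positive")
  if (blood_volume_fraction < 0 || blood_volume_fraction > 1)
    stop("blood_volume_fraction must be in [0, 1]")
  if (oxygen_saturation < 0 || oxygen_saturation > 1)
    stop("oxygen_saturation must be in [0, 1]")
  structure(list(name = name, label = as.integer(label),
                 mus_prime_long_ref = mus_prime_long_ref,
                 mus_prime_rad_ref = mus_prime_rad_ref,
                 lambda_ref = lambda_ref, b = b, g = g,
                 mua_baseline = mua_baseline,
                 blood_volume_fraction = blood_volume_fraction,
                 oxygen_saturation = oxygen_saturation,
                 fiber_axis = fiber_axis),
            class = "tissue_class")
}

#' @export
print.tissue_class <- function(x, ...) {
  cat(sprintf("<tissue_class> %s (label %d)\n", x$name, x$label))
  cat(sprintf("  mus' long/rad: %.3g / %.3g mm^-1 at %g nm (b = %g)\n",
              x$mus_prime_long_ref, x$mus_prime_rad_ref, x$lambda_ref, x$b))
  cat(sprintf("  g = %g, mua_baseline = %g mm^-1, B = %g, S = %g, fibers: %s\n",
              x$g, x$mua_baseline, x$blood_volume_fraction,
              x$oxygen_saturation, x$fiber_axis))
  invisible(x)
}

#' Per-voxel optical properties
#'
#' The physics parameters the transport engine sees for one tissue label:
#' absorption, one full (unreduced) scattering coefficient per Cartesian
#' axis, and the Henyey-Greenstein anisotropy factor.
#'
#' @param mua absorption coefficient (mm^-1).
#' @param mus_x,mus_y,mus_z full scattering coefficients per axis (mm^-1).
#' @param g anisotropy factor.
#' @return object of class `optical_properties`.
#' @export
optical_properties <- function(mua, mus_x, mus_y, mus_z, g) {
  if (any(c(mua, mus_x, mus_y, mus_z) < 0))
    stop("optical coefficients must be >= 0")
  if (g < 0 || g >= 1) stop("g must satisfy 0 <= g < 1")
  structure(list(mua = mua, mus_x = mus_x, mus_y = mus_y, mus_z = mus_z,
                 g = g), class = "optical_properties")
}

#' Direction-dependent effective scattering coefficient
#'
#' Combines the three axis scattering coefficients of a voxel with the
#' photon's current unit direction of flight. The default `"quadratic"` mode
#' weights by squared direction cosines,
#' \eqn{\mu_{s,eff} = u_x^2\mu_{s,x} + u_y^2\mu_{s,y} + u_z^2\mu_{s,z}};
#' `"abs_normalized"` weights by normalized absolute components. Both modes
#' return exactly the common value when the three axis coefficients are
#' equal, which is the validation property that guarantees the anisotropic
#' engine reduces to a conventional isotropic voxel code.
#'
#' @param props an [optical_properties()] object, or numeric vector
#'   `c(mus_x, mus_y, mus_z)`.
#' @param u unit 3-vector (|u| = 1 within 1e-9).
#' @param mode combination rule.
#' @return effective scattering coefficient (mm^-1).
#' @export
effective_mus <- function(props, u,
                          mode = c("quadratic", "abs_normalized")) {
  mode <- match.arg(mode)
  if (inherits(props, "optical_properties"))
    m <- c(props$mus_x, props$mus_y, props$mus_z)
  else m <- as.numeric(props)
  stopifnot(length(m) == 3, length(u) == 3)
  if (abs(sum(u^2) - 1) > 1e-9) stop("u must be a unit vector")
  # the quadratic form is rearranged so that equal axis coefficients give
  # exactly that coefficient, immune to |u|^2 rounding
  if (mode == "quadratic") m[1] + u[2]^2 * (m[2] - m[1]) + u[3]^2 * (m[3] - m[1])
  else m[1] + (abs(u[2]) * (m[2] - m[1]) + abs(u[3]) * (m[3] - m[1])) /
    sum(abs(u))
}

# Table of reduced scattering measurements at 633 nm used for the presets:
# per species, white matter (longitudinal / radial) and gray matter
# (longitudinal / radial), mm^-1.
.sl_ref_mus <- list(
  human_fresh = list(wm = c(1.56, 3.51), gm = c(2.61, 2.69)),
  human_fixed = list(wm = c(1.59, 3.46), gm = c(2.24, 2.57)),
  macaque_fixed     = list(wm = c(1.58, 3.59), gm = c(2.67, 2.90))
)

#' Packaged tissue-table presets
#'
#' Builds the white/gray-matter tissue pair for one of the packaged
#' 633-nm reduced-scattering measurement sets (`"human_fresh"`,
#' `"human_fixed"`, `"macaque_fixed"`), or their cross-species mean
#' (`"cross_species_mean"`). White matter is label 1 with fibers
#' along z (the rostrocaudal cord axis); gray matter is label 2 and treated
#' as isotropic by default (`gm_directional = TRUE` keeps its two measured
#' directions). Mouse simulations conventionally reuse the macaque
#' coefficients, the mouse cord being too small for direction-resolved
#' measurement.
#'
#' @param name preset name.
#' @param blood_volume_fraction,oxygen_saturation blood content applied to
#'   both tissues; defaults are the perfused-tissue simulation conditions
#'   (2.8% blood, 62% saturation).
#' @param mua_baseline bloodless absorption (mm^-1), default 0.05.
#' @param g,b anisotropy factor and scattering power, applied to both
#'   tissues.
#' @param gm_directional keep gray matter direction-resolved instead of
#'   isotropic-mean.
#' @return list of two [tissue_class()] objects (white matter, gray matter).
#' @export
tissue_preset <- function(name = c("macaque_fixed", "human_fresh",
                                   "human_fixed",
                                   "cross_species_mean"),
                          blood_volume_fraction = 0.028,
                          oxygen_saturation = 0.62,
                          mua_baseline = 0.05, g = 0.9, b = 1.6,
                          gm_directional = FALSE) {
  name <- match.arg(name)
  if (name == "cross_species_mean") {
    wm <- rowMeans(sapply(.sl_ref_mus, function(t) t$wm))
    gm <- rowMeans(sapply(.sl_ref_mus, function(t) t$gm))
  } else {
    wm <- .sl_ref_mus[[name]]$wm
    gm <- .sl_ref_mus[[name]]$gm
  }
  list(
    tissue_class("white_matter", 1L, wm[1], wm[2], lambda_ref = 633, b = b,
                 g = g, mua_baseline = mua_baseline,
                 blood_volume_fraction = blood_volume_fraction,
                 oxygen_saturation = oxygen_saturation, fiber_axis = "z"),
    tissue_class("gray_matter", 2L, gm[1], gm[2], lambda_ref = 633, b = b,
                 g = g, mua_baseline = mua_baseline,
                 blood_volume_fraction = blood_volume_fraction,
                 oxygen_saturation = oxygen_saturation,
                 fiber_axis = if (gm_directional) "z" else "isotropic")
  )
}

#' Build the per-label optical-property table at a simulation wavelength
#'
#' For each tissue: the two direction-resolved reduced scattering
#' coefficients are power-law scaled from the reference to the simulation
#' wavelength, converted to full coefficients via the similarity relation
#' mu_s = mu_s'/(1-g), and mapped onto Cartesian axes through the tissue's
#' `fiber_axis` (fibers along z puts the longitudinal value on z and the
#' radial value on x and y; isotropic tissues get the mean of the two values
#' on all axes). Absorption is baseline plus hemoglobin at the simulation
#' wavelength. Every entry must end up with mu_a > 0, which the fluence
#' estimator requires.
#'
#' @param tissues list of [tissue_class()] objects with distinct labels.
#' @param lambda_nm simulation wavelength (nm), within the extinction-table
#'   range.
#' @param g_override optionally force one g for all tissues.
#' @return data.frame of class `property_table` with columns `label`,
#'   `name`, `mua`, `mus_x`, `mus_y`, `mus_z`, `g`; attribute
#'   `wavelength_nm`.
#' @export
build_property_table <- function(tissues, lambda_nm, g_override = NULL) {
  if (inherits(tissues, "tissue_class")) tissues <- list(tissues)
  labels <- vapply(tissues, function(t) t$label, integer(1))
  if (anyDuplicated(labels)) stop("tissue labels must be distinct")
  rows <- lapply(tissues, function(t) {
    g <- if (is.null(g_override)) t$g else g_override
    long <- scale_scattering(t$mus_prime_long_ref, t$lambda_ref, lambda_nm,
                             t$b)
    rad <- scale_scattering(t$mus_prime_rad_ref, t$lambda_ref, lambda_nm,
                            t$b)
    if (t$fiber_axis == "isotropic") {
      m <- rep(reduced_to_full(mean(c(long, rad)), g), 3)
    } else {
      m <- rep(reduced_to_full(rad, g), 3)
      m[match(t$fiber_axis, c("x", "y", "z"))] <- reduced_to_full(long, g)
    }
    mua <- blood_absorption(t$blood_volume_fraction, t$oxygen_saturation,
                            lambda_nm, t$mua_baseline)
    data.frame(label = t$label, name = t$name, mua = mua, mus_x = m[1],
               mus_y = m[2], mus_z = m[3], g = g,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$mua <= 0))
    stop("every tissue must have mua > 0 (required by the fluence estimator)")
  structure(tab, class = c("property_table", "data.frame"),
            wavelength_nm = lambda_nm)
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> at %g nm\n", attr(x, "wavelength_nm")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# engine-facing matrix: row l = label l, columns mua, mus_x, mus_y, mus_z, g
.props_matrix <- function(tab, volume = NULL) {
  if (!is.null(volume)) {
    used <- setdiff(sort(unique(as.integer(volume$labels))), 0L)
    missing <- setdiff(used, tab$label)
    if (length(missing))
      stop("no optical properties for label(s): ",
           paste(missing, collapse = ", "))
  }
  m <- matrix(0, nrow = max(tab$label), ncol = 5)
  m[tab$label, ] <- as.matrix(tab[, c("mua", "mus_x", "mus_y", "mus_z",
                                      "g")])
  m
}

#' Read / write tissue tables as JSON
#'
#' Tissue definitions round-trip through a flat JSON array with fields
#' `label`, `name`, `mus_prime_long_ref`, `mus_prime_rad_ref`,
#' `lambda_ref_nm`, `b`, `g`, `mua_baseline`, `blood_volume_fraction`,
#' `oxygen_saturation`, `fiber_axis`.
#'
#' @param tissues list of [tissue_class()] objects.
#' @param path file path.
#' @return `read_tissue_table` returns a list of [tissue_class()] objects;
#'   `write_tissue_table` returns `path` invisibly.
#' @export
write_tissue_table <- function(tissues, path) {
  if (inherits(tissues, "tissue_class")) tissues <- list(tissues)
  recs <- lapply(tissues, function(t)
    list(label = t$label, name = t$name,
         mus_prime_long_ref = t$mus_prime_long_ref,
         mus_prime_rad_ref = t$mus_prime_rad_ref,
         lambda_ref_nm = t$lambda_ref, b = t$b, g = t$g,
         mua_baseline = t$mua_baseline,
         blood_volume_fraction = t$blood_volume_fraction,
         oxygen_saturation = t$oxygen_saturation,
         fiber_axis = t$fiber_axis))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tissue_table
#' @export
read_tissue_table <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    tissue_class(r$name, r$label, r$mus_prime_long_ref,
                 r$mus_prime_rad_ref, lambda_ref = r$lambda_ref_nm,
                 b = r$b, g = r$g, mua_baseline = r$mua_baseline,
                 blood_volume_fraction = r$blood_volume_fraction,
                 oxygen_saturation = r$oxygen_saturation,
                 fiber_axis = r$fiber_axis))
}
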