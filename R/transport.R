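#' Fiber-optic source specification
#'
#' Describes the light launch: a flat-disc fiber face of given core diameter
#' emitting into the acceptance cone set by the numerical aperture inside
#' tissue (half-angle `asin(NA / n_tissue)`), with directions drawn
#' uniformly in solid angle within the cone. Two diagnostic profiles are
#' also available: `"collimated"` (disc, all photons along the beam axis)
#' and `"isotropic_point"` (point source radiating uniformly), used for
#' closed-form physics checks.
#'
#' @param tip_position 3-vector, fiber tip center (mm).
#' @param beam_axis unit 3-vector, emission direction.
#' @param core_diameter fiber core diameter (mm), default 0.105.
#' @param numerical_aperture fiber NA, default 0.22; must be below the
#'   tissue refractive index.
#' @param power delivered power (mW), default 10.
#' @param wavelength wavelength (nm), default 473.
#' @param profile `"flat_disc"` (default), `"collimated"`, or
#'   `"isotropic_point"`.
#' @return object of class `source_spec`.
#' @export
source_spec <- function(tip_position, beam_axis = c(0, 1, 0),
                        core_diameter = 0.105, numerical_aperture = 0.22,
                        power = 10, wavelength = 473,
                        profile = c("flat_disc", "collimated",
                                    "isotropic_point")) {
  profile <- match.arg(profile)
  stopifnot(length(tip_position) == 3, length(beam_axis) == 3)
  if (abs(sum(beam_axis^2) - 1) > 1e-9) stop("beam_axis must be a unit vector")
  if (core_diameter <= 0) stop("core_diameter must be positive")
  if (numerical_aperture <= 0) stop("numerical_aperture must be positive")
  if (power <= 0) stop("power must be positive")
  structure(list(tip_position = as.numeric(tip_position),
                 beam_axis = as.numeric(beam_axis),
                 core_diameter = core_diameter,
                 numerical_aperture = numerical_aperture, power = power,
                 wavelength = wavelength, profile = profile),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf("<source_spec> %s fiber, core %g mm, NA %g, %g mW at %g nm\n",
              x$profile, x$core_diameter, x$numerical_aperture, x$power,
              x$wavelength))
  cat(sprintf("  tip (%g, %g, %g) mm, axis (%g, %g, %g)\n",
              x$tip_position[1], x$tip_position[2], x$tip_position[3],
              x$beam_axis[1], x$beam_axis[2], x$beam_axis[3]))
  invisible(x)
}

#' Monte Carlo run configuration
#'
#' @param n_photons number of photon packets.
#' @param seed RNG seed; the same seed, volume, table and source give a
#'   bit-identical [run_mc()] result.
#' @param roulette_threshold weight below which Russian roulette is played
#'   (default 1e-4).
#' @param roulette_survival survival probability (default 0.1); survivors
#'   are rescaled by its inverse, so the game preserves expectation.
#' @param combination_mode direction-combination rule for the axis
#'   scattering coefficients, `"quadratic"` (default) or `"abs_normalized"`.
#' @param max_path_mm per-photon path-length safety cap (mm).
#' @param n_tissue tissue refractive index used for the launch cone only
#'   (boundaries are refractive-index matched).
#' @param detector_na optional acceptance NA for the bottom-face (y+)
#'   detector used by the virtual punch-through experiment; NULL accepts
#'   all exit angles.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_photons, seed = 1L, roulette_threshold = 1e-4,
                       roulette_survival = 0.1,
                       combination_mode = c("quadratic", "abs_normalized"),
                       max_path_mm = 1000, n_tissue = 1.37,
                       detector_na = NULL) {
  combination_mode <- match.arg(combination_mode)
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_survival <= 0 || roulette_survival > 1)
    stop("roulette_survival must be in (0, 1]")
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 combination_mode = combination_mode,
                 max_path_mm = max_path_mm, n_tissue = n_tissue,
                 detector_na = detector_na),
            class = "run_config")
}

#' Sample photon launches from a fiber source
#'
#' R-level reference sampler for the launch geometry (the compiled engine
#' implements the same distributions internally): positions uniform on the
#' fiber face disc, directions uniform in solid angle within the acceptance
#' cone of half-angle `asin(NA / n_tissue)` about the beam axis.
#'
#' @param source a [source_spec()].
#' @param n number of draws.
#' @param n_tissue tissue refractive index.
#' @return list with `positions` and `directions`, both `n` x 3 matrices.
#' @export
launch_photons <- function(source, n, n_tissue = 1.37) {
  if (source$numerical_aperture >= n_tissue)
    stop("numerical aperture must be below the tissue refractive index")
  w <- source$beam_axis
  e1 <- if (abs(w[3]) < 0.9) c(w[2], -w[1], 0) else c(-w[3], 0, w[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  r <- source$core_diameter / 2 * sqrt(runif(n))
  psi <- 2 * pi * runif(n)
  pos <- outer(rep(1, n), source$tip_position) +
    (r * cos(psi)) %o% e1 + (r * sin(psi)) %o% e2
  if (source$profile == "collimated") {
    dir <- outer(rep(1, n), w)
  } else if (source$profile == "isotropic_point") {
    pos <- outer(rep(1, n), source$tip_position)
    cost <- runif(n, -1, 1); phi <- 2 * pi * runif(n)
    sint <- sqrt(1 - cost^2)
    dir <- cbind(sint * cos(phi), sint * sin(phi), cost)
  } else {
    cos_half <- cos(asin(source$numerical_aperture / n_tissue))
    cost <- 1 - runif(n) * (1 - cos_half)
    sint <- sqrt(pmax(0, 1 - cost^2))
    phi <- 2 * pi * runif(n)
    dir <- cost %o% w + (sint * cos(phi)) %o% e1 + (sint * sin(phi)) %o% e2
    dir <- dir / sqrt(rowSums(dir^2))
  }
  list(positions = pos, directions = dir)
}

#' Henyey-Greenstein deflection sampling
#'
#' Draws deflection cosines from the Henyey-Greenstein phase function by
#' inverse-CDF sampling; `hg_quantile()` is the deterministic quantile
#' function used by the sampler. For `g = 0` the cosine is uniform on
#' `[-1, 1]`; the defining property E(cos theta) = g holds for all valid g.
#'
#' @param n number of draws.
#' @param g anisotropy factor, `0 <= g < 1`.
#' @return `hg_deflection`: numeric vector of deflection cosines.
#' @export
hg_deflection <- function(n, g) {
  hg_quantile(runif(n), g)
}

#' @rdname hg_deflection
#' @param p probabilities in `[0, 1)`.
#' @export
hg_quantile <- function(p, g) {
  if (g < 0 || g >= 1) stop("g must satisfy 0 <= g < 1")
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  if (g == 0) return(2 * p - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * p)
  pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
}

.profile_code <- function(profile)
  match(profile, c("flat_disc", "collimated", "isotropic_point")) - 1L

#' Run the anisotropic voxelized Monte Carlo simulation
#'
#' Propagates `n_photons` weighted packets from the source through the
#' labeled volume with hop-drop-spin steps. At each step the local
#' scattering coefficient is rebuilt from the photon's direction of flight
#' and the voxel's three axis coefficients (see [effective_mus()]);
#' dimensionless step bookkeeping is kept across voxel-boundary crossings.
#' Packets deposit `W mua/mut` per step, play Russian roulette below the
#' weight threshold, and terminate by escaping through a grid face or into
#' a label-0 voxel (boundaries are refractive-index matched; no Fresnel
#' reflection).
#'
#' Fluence is reported per delivered watt:
#' `F = deposited / (n_photons * mua * voxel_volume)` (mm^-2 W^-1 by
#' dimensional bookkeeping with unit launched energy).
#'
#' @param volume a `labeled_volume`.
#' @param props a `property_table` covering every tissue label in the
#'   volume, with `mua > 0`.
#' @param source a [source_spec()].
#' @param config a [run_config()].
#' @return object of class `fluence_result`: `fluence` (3-D array, mm^-2
#'   per delivered W), `absorbed` (3-D array, fraction of launched weight),
#'   `escaped_fraction`, `escaped_faces` (named: `x-`, `x+`, `y-`, `y+`,
#'   `z-`, `z+`), `escaped_label0`, `lost_fraction`, `detector_fraction`
#'   (weight out of the y+ face within the detector acceptance cone), plus
#'   the echoed spec, seed and configuration.
#' @export
run_mc <- function(volume, props, source, config) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(props, "property_table"),
            inherits(source, "source_spec"), inherits(config, "run_config"))
  if (source$numerical_aperture >= config$n_tissue &&
      source$profile == "flat_disc")
    stop("numerical aperture must be below the tissue refractive index")
  s <- volume$spec
  tp <- source$tip_position
  if (any(tp < 0) || tp[1] > s$nx * s$dx || tp[2] > s$ny * s$dy ||
      tp[3] > s$nz * s$dz)
    stop("source tip_position lies outside the grid")
  pm <- .props_matrix(props, volume)
  cos_half <- cos(asin(min(source$numerical_aperture / config$n_tissue, 1)))
  det_cos <- if (is.null(config$detector_na)) -1 else
    cos(asin(min(config$detector_na / config$n_tissue, 1)))
  set.seed(config$seed)
  raw <- .mc_engine(as.integer(volume$labels), s$nx, s$ny, s$nz,
                    s$dx, s$dy, s$dz, pm,
                    source$tip_position, source$beam_axis,
                    source$core_diameter / 2, cos_half,
                    .profile_code(source$profile),
                    config$n_photons, config$roulette_threshold,
                    config$roulette_survival,
                    match(config$combination_mode,
                          c("quadratic", "abs_normalized")) - 1L,
                    config$max_path_mm, det_cos)
  n <- config$n_photons
  absorbed <- array(raw$absorbed / n, c(s$nx, s$ny, s$nz))
  mua_vox <- array(0, c(s$nx, s$ny, s$nz))
  tissue <- volume$labels > 0L
  mua_vox[tissue] <- pm[volume$labels[tissue], 1]
  vvox <- s$dx * s$dy * s$dz
  fluence <- array(0, c(s$nx, s$ny, s$nz))
  fluence[tissue] <- absorbed[tissue] / (mua_vox[tissue] * vvox)
  faces <- raw$escaped_faces / n
  names(faces) <- c("x-", "x+", "y-", "y+", "z-", "z+")
  structure(list(fluence = fluence, absorbed = absorbed,
                 escaped_fraction = sum(faces) + raw$escaped_label0 / n,
                 escaped_faces = faces,
                 escaped_label0 = raw$escaped_label0 / n,
                 lost_fraction = raw$lost / n,
                 detector_fraction = raw$detector_weight / n,
                 n_photons = n, seed = config$seed,
                 wavelength = source$wavelength,
                 combination_mode = config$combination_mode,
                 spec = s, source = source, config = config),
            class = "fluence_result")
}

#' @export
print.fluence_result <- function(x, ...) {
  cat(sprintf("<fluence_result> %d photons at %g nm (%s combination, seed %d)\n",
              x$n_photons, x$wavelength, x$combination_mode, x$seed))
  cat(sprintf("  absorbed %.4f | escaped %.4f | lost %.2g\n",
              sum(x$absorbed), x$escaped_fraction, x$lost_fraction))
  cat(sprintf("  peak fluence %.3g mm^-2 W^-1\n", max(x$fluence)))
  invisible(x)
}

#' Reference isotropic Monte Carlo in a homogeneous box
#'
#' Independently coded validation oracle: a single scalar scattering
#' coefficient, free paths sampled analytically against the box walls (no
#' voxel walking), deposition binned to the grid at interaction sites.
#' Used to check that the anisotropic engine reduces to conventional
#' isotropic transport when its three axis coefficients are equal.
#'
#' @param spec a [voxel_spec()] defining the box and the deposition grid.
#' @param mua,mus,g homogeneous optical properties (mus is the full
#'   scattering coefficient).
#' @param source a [source_spec()].
#' @param config a [run_config()] (combination mode is irrelevant here).
#' @return list with `absorbed` (3-D array, fraction of launched weight),
#'   `escaped_fraction`, `n_photons`.
#' @export
run_iso_reference <- function(spec, mua, mus, g, source, config) {
  cos_half <- cos(asin(min(source$numerical_aperture / config$n_tissue, 1)))
  set.seed(config$seed)
  raw <- .mc_iso_oracle(spec$nx, spec$ny, spec$nz, spec$dx, spec$dy,
                        spec$dz, mua, mus, g, source$tip_position,
                        source$beam_axis, source$core_diameter / 2,
                        cos_half, .profile_code(source$profile),
                        config$n_photons, config$roulette_threshold,
                        config$roulette_survival)
  list(absorbed = array(raw$absorbed / config$n_photons,
                        c(spec$nx, spec$ny, spec$nz)),
       escaped_fraction = raw$escaped / config$n_photons,
       n_photons = config$n_photons)
}
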