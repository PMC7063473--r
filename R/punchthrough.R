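#' Depth-resolved optical transmittance profile
#'
#' Transmittance through a tissue thickness z: the ratio of detected
#' intensity to the fiber intensity with no tissue present. Nonpositive
#' transmittance values cannot enter a log fit and are dropped with a
#' warning.
#'
#' @param z tissue thicknesses (mm), strictly increasing.
#' @param transmittance T(z) values in (0, 1] (a small overshoot above 1 is
#'   tolerated for noisy data).
#' @param reference description of the reference intensity I0.
#' @return object of class `transmittance_profile` (a data.frame with
#'   columns `z` and `transmittance`).
#' @export
transmittance_profile <- function(z, transmittance,
                                  reference = "fiber output, no tissue") {
  stopifnot(length(z) == length(transmittance))
  keep <- transmittance > 0
  if (!all(keep)) {
    warning(sum(!keep), " nonpositive transmittance value(s) excluded")
    z <- z[keep]; transmittance <- transmittance[keep]
  }
  if (length(z) && any(diff(z) <= 0)) stop("z must be strictly increasing")
  if (length(transmittance) && min(z) <= 1e-9 &&
      transmittance[1] > 1 + 0.05)
    warning("T(0) exceeds 1 by more than the tolerance")
  structure(data.frame(z = z, transmittance = transmittance),
            class = c("transmittance_profile", "data.frame"),
            reference = reference)
}

#' Compute transmittance from detected intensities
#'
#' T(z) = I(z) / I0, the total detected intensity at each depth over the
#' reference intensity with no tissue present.
#'
#' @param intensity detected intensities (>= 0), one per depth.
#' @param I0 reference intensity (> 0).
#' @param z tissue thicknesses (mm).
#' @return a [transmittance_profile()].
#' @export
compute_transmittance <- function(intensity, I0, z) {
  if (I0 <= 0) stop("I0 must be positive")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  transmittance_profile(z, intensity / I0)
}

#' Fit the effective attenuation coefficient to a transmittance profile
#'
#' Fits the modified Beer-Lambert decay `T(z) = exp(-mueff z)` to a
#' depth-resolved transmittance profile. The default `"log_linear"` method
#' is an ordinary least-squares fit of `log T` against `z` with a free
#' intercept, `mueff` being minus the slope; `"nonlinear"` is a
#' single-parameter Gauss-Newton least-squares fit on T itself with the
#' intercept fixed at 1. Both recover a noiseless exponential exactly. A
#' quadratic lack-of-fit diagnostic flags curvature in `log T`, the
#' signature of a profile that has not reached the diffusive regime (where
#' the fitted constant should be read as a relative decay constant rather
#' than the diffusion-theory mueff).
#'
#' @param profile a [transmittance_profile()] (or data.frame with columns
#'   `z`, `transmittance`).
#' @param window optional `c(zmin, zmax)` fit window (mm); default the full
#'   profile.
#' @param method `"log_linear"` (default) or `"nonlinear"`.
#' @return object of class `mueff_fit` with components `mu_eff` (mm^-1),
#'   `se`, `r_squared` (of the log-linear fit), `intercept`, `window`,
#'   `method`, `n`, `curvature_flag`, and the fitted data.
#' @seealso [diffusion_mueff()] for the diffusion-theory prediction.
#' @export
fit_mueff <- function(profile, window = NULL,
                      method = c("log_linear", "nonlinear")) {
  method <- match.arg(method)
  z <- profile$z; tr <- profile$transmittance
  keep <- tr > 0
  if (!all(keep)) {
    warning(sum(!keep), " nonpositive transmittance value(s) excluded")
    z <- z[keep]; tr <- tr[keep]
  }
  if (is.null(window)) window <- range(z)
  inw <- z >= window[1] & z <= window[2]
  z <- z[inw]; tr <- tr[inw]
  if (length(z) < 3)
    stop("insufficient data: need at least 3 usable points in the window")

  fit_ll <- lm(log(tr) ~ z)
  sm <- suppressWarnings(summary(fit_ll))  # "perfect fit" on noiseless data
  mu_ll <- -unname(coef(fit_ll)[2])
  se_ll <- sm$coefficients[2, 2]
  r2 <- sm$r.squared

  # curvature diagnostic: significant quadratic term in log T
  curv <- FALSE
  if (length(z) >= 4 && length(unique(z)) >= 3) {
    qf <- suppressWarnings(summary(lm(log(tr) ~ z + I(z^2))))
    if (nrow(qf$coefficients) == 3)
      curv <- is.finite(qf$coefficients[3, 4]) &&
        qf$coefficients[3, 4] < 0.01
  }

  if (method == "log_linear") {
    mu <- mu_ll; se <- se_ll; intercept <- exp(unname(coef(fit_ll)[1]))
  } else {
    # Gauss-Newton on T = exp(-mu z), intercept fixed at 1
    mu <- max(mu_ll, 0)
    for (i in 1:200) {
      f <- exp(-mu * z)
      jac <- -z * f
      step <- sum((tr - f) * jac) / sum(jac^2)
      mu <- mu + step
      if (!is.finite(mu)) stop("nonlinear fit diverged")
      if (abs(step) < 1e-14 * max(1, abs(mu))) break
    }
    f <- exp(-mu * z)
    dof <- length(z) - 1
    se <- if (dof > 0) sqrt(sum((tr - f)^2) / dof / sum((z * f)^2)) else NA
    intercept <- 1
  }
  structure(list(mu_eff = mu, se = se, r_squared = r2,
                 intercept = intercept, window = window, method = method,
                 n = length(z), curvature_flag = curv,
                 data = data.frame(z = z, transmittance = tr)),
            class = "mueff_fit")
}

#' @export
print.mueff_fit <- function(x, ...) {
  cat(sprintf("<mueff_fit> mu_eff = %.4g mm^-1 (SE %.2g), %s fit, n = %d\n",
              x$mu_eff, x$se, x$method, x$n))
  invisible(x)
}

#' @export
summary.mueff_fit <- function(object, ...) {
  cat(sprintf("Effective attenuation fit (%s), window [%g, %g] mm, n = %d\n",
              object$method, object$window[1], object$window[2], object$n))
  cat(sprintf("  mu_eff    %.6g mm^-1\n  std.error %.3g\n  intercept %.4g\n",
              object$mu_eff, object$se, object$intercept))
  cat(sprintf("  R^2 (log-linear) %.6f\n", object$r_squared))
  if (object$curvature_flag)
    cat("  NOTE: significant curvature in log T - profile may not be in the\n",
        "  diffusive regime; read mu_eff as a relative decay constant.\n")
  invisible(object)
}

#' @export
coef.mueff_fit <- function(object, ...) c(mu_eff = object$mu_eff)

#' @export
predict.mueff_fit <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$data$z
  else if (is.data.frame(newdata)) newdata$z else newdata
  object$intercept * exp(-object$mu_eff * z)
}

#' @export
residuals.mueff_fit <- function(object, ...) {
  object$data$transmittance - predict(object)
}

#' @export
plot.mueff_fit <- function(x, ...) {
  plot(x$data$z, x$data$transmittance, log = "y", xlab = "thickness z (mm)",
       ylab = "transmittance", ...)
  zz <- seq(min(x$data$z), max(x$data$z), length.out = 100)
  graphics::lines(zz, x$intercept * exp(-x$mu_eff * zz))
  invisible(x)
}

#' Diffusion-theory effective attenuation coefficient
#'
#' The standard diffusive-regime decay constant
#' \eqn{\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}}. Useful as a cross-check
#' for fitted punch-through decay constants when the probed thickness is in
#' the diffusive regime.
#'
#' @param mua absorption coefficient (mm^-1), > 0.
#' @param mus_prime reduced scattering coefficient (mm^-1), >= 0.
#' @return mu_eff (mm^-1).
#' @export
diffusion_mueff <- function(mua, mus_prime) {
  if (any(mua <= 0)) stop("mua must be positive")
  if (any(mus_prime < 0)) stop("mus_prime must be >= 0")
  sqrt(3 * mua * (mua + mus_prime))
}

#' Virtual punch-through experiment
#'
#' Reproduces the punch-through attenuation measurement in silico: the
#' fiber tip is lowered into a slab phantom in steps, the transport engine
#' is run at each depth, and the weight escaping through the bottom (y+)
#' face - optionally restricted to a detection-objective acceptance cone -
#' is recorded. Transmittance is reported against the remaining tissue
#' thickness below the tip and, by default, normalized so that the
#' shallowest remaining thickness has T = 1 (a free-intercept fit makes the
#' normalization immaterial).
#'
#' @param volume a slab `labeled_volume` filling the grid down to y+.
#' @param props a `property_table`.
#' @param source a [source_spec()]; the beam must point along +y. The tip y
#'   is overridden by each depth in the schedule.
#' @param depths fiber-tip insertion depths below y = 0 (mm), within the
#'   slab.
#' @param config a [run_config()]; photon count applies per depth, and
#'   `detector_na` (if set) applies the acceptance-angle cut. Depth runs
#'   use consecutive seeds starting at `config$seed`.
#' @param normalize divide by the transmittance at the largest depth.
#' @return a [transmittance_profile()] (z = remaining thickness, mm) with
#'   attribute `raw` holding the unnormalized bottom-face fractions.
#' @export
simulate_punchthrough <- function(volume, props, source, depths, config,
                                  normalize = TRUE) {
  s <- volume$spec
  L <- s$ny * s$dy
  if (any(depths < 0 | depths >= L))
    stop("depth schedule must lie within the slab thickness")
  if (abs(source$beam_axis[2] - 1) > 1e-9)
    stop("the punch-through beam must point along +y")
  tvals <- vapply(seq_along(depths), function(i) {
    src <- source
    src$tip_position[2] <- depths[i]
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run_mc(volume, props, src, cfg)$detector_fraction
  }, numeric(1))
  remaining <- L - depths
  ord <- order(remaining)
  raw <- tvals[ord]
  tr <- if (normalize) raw / raw[1] else raw
  out <- transmittance_profile(remaining[ord], tr,
                               reference = if (normalize)
                                 "bottom-face escape at the shallowest remaining thickness"
                               else "launched power")
  attr(out, "raw") <- raw
  out
}

#' Read / write transmittance profiles
#'
#' Two-column whitespace- or comma-separated text (`z_mm`, `transmittance`)
#' with `#` comment headers.
#'
#' @param profile a [transmittance_profile()].
#' @param path file path.
#' @param comment header lines to write (without the leading `#`).
#' @return `read_profile` returns a [transmittance_profile()];
#'   `write_profile` returns `path` invisibly.
#' @export
write_profile <- function(profile, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", c(comment, "z_mm transmittance"))), con)
  utils::write.table(profile[, c("z", "transmittance")], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data lines in profile file: ", path)
  fields <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- which(vapply(fields, length, integer(1)) < 2 |
                 vapply(fields, function(f)
                   anyNA(suppressWarnings(as.numeric(f[1:2]))), logical(1)))
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop(sprintf("malformed profile line %d: '%s'", lineno, lines[lineno]))
  }
  m <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
  transmittance_profile(m[, 1], m[, 2])
}
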