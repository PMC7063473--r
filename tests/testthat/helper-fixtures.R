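# Shared fixture builders for the test suite.  All fixtures are generated in
# code; photon counts are kept small except where a check's tolerance
# genuinely needs more.

# single isotropic tissue with fixed optical properties, no blood
iso_tissue <- function(mus_prime, mua, g = 0, label = 1L,
                       name = "tissue") {
  tissue_class(name, label, mus_prime, mus_prime, b = 0, g = g,
               mua_baseline = mua, blood_volume_fraction = 0,
               fiber_axis = "isotropic")
}

iso_props <- function(mus_prime, mua, g = 0, lambda = 633) {
  build_property_table(list(iso_tissue(mus_prime, mua, g)), lambda)
}

# anisotropic white-matter-like tissue, fibers along a chosen axis
wm_tissue <- function(long = 1.57, rad = 3.52, mua = 0.05, g = 0.9,
                      axis = "z", label = 1L) {
  tissue_class("white_matter", label, long, rad, b = 0, g = g,
               mua_baseline = mua, blood_volume_fraction = 0,
               fiber_axis = axis)
}

# fiber on the top (dorsal, y = 0) face at the lateral center of the grid
top_fiber <- function(spec, ...) {
  source_spec(c(spec$nx * spec$dx / 2, 0, spec$nz * spec$dz / 2),
              c(0, 1, 0), ...)
}

# random unit vectors, n x 3
random_units <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
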