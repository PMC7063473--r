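---
title: "Direction-resolved Monte Carlo light transport in organized white matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction-resolved Monte Carlo light transport in organized white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinelight)
```

## The problem

Optogenetic stimulation of the spinal cord differs from the cortical case in
one decisive way: the fiber cannot be implanted. It sits against the dorsal
surface, and light must first cross the dorsal white matter - a densely
packed, highly organized bundle of myelinated axons running along the cord -
before reaching the opsin-expressing gray matter. Organized myelin scatters
light anisotropically: the reduced scattering coefficient measured along the
fiber tracts is roughly half the value measured across them (about
1.57 mm^-1 vs 3.52 mm^-1 at 633 nm in white matter, averaged across
species), while gray matter, whose myelin is disordered, shows no
directional preference. A transport model that uses a single scalar
scattering coefficient per tissue therefore misestimates both how deep the
light reaches and how far it spreads along the cord.

`spinelight` implements a voxelized Monte Carlo photon transport engine in
which every voxel carries one full scattering coefficient per Cartesian
axis, together with the surrounding machinery needed to use it for
planning: a generic-tissue optical-property model, procedural spinal-cord
phantoms, activation-volume metrics at a channelrhodopsin irradiance
threshold, and a punch-through effective-attenuation estimator.

## The transport model

The engine is a weighted photon-packet ("hop-drop-spin") random walk of the
MCML/mcxyz family. Packets launch from a flat fiber face (core diameter
0.105 mm, NA 0.22 by default) with directions uniform in solid angle inside
the acceptance cone of half-angle `asin(NA / n)`, using a tissue refractive
index n = 1.37 for the cone only - boundaries are treated as
refractive-index matched, and photons escape at grid faces and at label-0
voxels without Fresnel reflection.

The single modification to conventional voxelized transport is the
scattering coefficient seen by a packet. Each voxel stores
(mu_s,x, mu_s,y, mu_s,z); at every step, and again at every voxel-boundary
crossing, the effective coefficient is rebuilt from the current direction
of flight u. The default combination is the squared-direction-cosine form

    mu_s,eff = ux^2 mu_s,x + uy^2 mu_s,y + uz^2 mu_s,z ,

with an |u|-weighted normalized mean available as
`combination_mode = "abs_normalized"`. These are the only two linear
readings that satisfy the defining validation property: when the three axis
coefficients are equal, mu_s,eff equals that common value *exactly* for
every direction, so the anisotropic engine reduces to a conventional
isotropic voxel code (an unnormalized combination of |u| components cannot,
since |ux|+|uy|+|uz| ranges over [1, sqrt(3)]). The quadratic form is the
default because it is smooth, exact for equal axes, and reproduces each
axis coefficient for axis-aligned flight. The test suite checks the
reduction property against an independently coded isotropic Monte Carlo
oracle that samples free paths analytically against the box walls and
shares no code with the voxelized engine.

Step bookkeeping follows the dimensionless-step convention: a sampled
optical depth `s = -ln(xi)` is consumed at the local rate
`mu_t = mu_a + mu_s,eff`, with the remainder carried across voxel-boundary
crossings where `mu_t` is re-evaluated. The direction - and therefore
`mu_s,eff` - changes only at scatter events, where the deflection cosine is
drawn from the Henyey-Greenstein phase function by inverse-CDF sampling.
At each step end the packet deposits `W mu_a / mu_t` into the current
voxel; Russian roulette (threshold 1e-4, survival 0.1, survivors rescaled)
terminates light packets while preserving expectation, and the suite
verifies `absorbed + escaped = 1` to 1e-3. Fluence is reported per
delivered watt, `F = deposited / (N mu_a V_voxel)` (mm^-2 W^-1), so an
intensity map at power P mW is simply `F * P` in mW/mm^2.

Two diagnostic source profiles beyond the fiber launch exist because the
closed-form physics limits need them: `"collimated"` (Beer-Lambert
transmission through a pure absorber) and `"isotropic_point"` (far-field
fluence log-slope `-sqrt(3 mu_a (mu_a + mu_s'))` in a homogeneous medium).

Determinism is part of the contract: the engine consumes R's seeded RNG
stream in a fixed single-threaded photon order, so identical seeds give
bit-identical fluence volumes.

## The tissue model and its parameters

Per tissue, the model takes the two direction-resolved reduced scattering
coefficients at a reference wavelength and maps them to the engine's axis
coefficients in three steps:

* **Wavelength scaling.** `mu_s'(lambda) = mu_s'(ref) (lambda/ref)^-b`.
  The scattering power `b` is not part of the packaged measurements; the
  default `b = 1.6` is the generic literature value for brain-like soft
  tissue. Simulating at the reference wavelength sidesteps it entirely.
* **Similarity conversion.** The engine propagates with full coefficients
  `mu_s = mu_s'/(1-g)`. The anisotropy factor `g` is likewise not
  measured here; the default `g = 0.90` is typical for neural tissue. In
  the diffusive regime the fluence depends on the product `mu_s(1-g)`, so
  results are insensitive to how the measured `mu_s'` is split.
* **Axis mapping.** `fiber_axis = "z"` places the longitudinal value on z
  and the radial value on x and y (the cord phantoms extrude their fibers
  along z). Gray matter defaults to `"isotropic"`: its two measured
  directions are averaged, reflecting the near-random myelin organization
  there; an option keeps the two values separate.

Absorption is `mu_a = mu_a,baseline + B [S mu_a,oxy + (1-S) mu_a,deoxy]`.
The packaged defaults emulate perfused tissue at an optogenetic wavelength:
blood volume fraction B = 2.8%, oxygen saturation S = 62%, and a bloodless
baseline of 0.05 mm^-1 (the direction-resolved scattering measurements
bound tissue absorption below 0.1 mm^-1 at the red reference wavelength;
half that bound is used as the baseline). The whole-blood spectra packaged
in `inst/extdata/hemoglobin_whole_blood.csv` are a synthetic approximate
compilation of the standard oxy/deoxy-hemoglobin extinction tabulation at
150 g/L hemoglobin on a 450-700 nm grid, linearly interpolated and never
extrapolated. At 473 nm and B = 2.8% the blood term contributes about
0.53 mm^-1, which dominates the baseline; errors of a few percent in the
compiled spectrum move activation depths by far less than the geometric
uncertainty of the phantoms.

Three measured preset tables ship with the package (fresh human, fixed
human, fixed macaque white/gray matter at 633 nm) plus their cross-species
mean; mouse simulations reuse the macaque coefficients, the mouse cord
being too small for direction-resolved measurement.

## What the phantoms emulate - and what they do not

`cord_phantom()` builds a to-scale transverse cross-section: an elliptical
white-matter outline with a butterfly-shaped gray-matter core (two mirrored
dorsal horns, two ventral horns, a central commissure band), extruded
uniformly along the cord axis. The default dimensions (mouse
2.4 x 1.8 mm ellipse with a 0.35 mm dorsal white-matter rim; macaque
8 x 6 mm; human 12 x 8.5 mm, butterfly scaled with the ellipse) are
approximations read off to-scale anatomy, not tabulated measurements - the
activation-geometry checks carry tolerances of tens of percent for exactly
this reason. Voxel pitch defaults to 0.02 mm (mouse) and 0.05 mm
(macaque/human), fine enough that the 105-um fiber face spans several
voxels; cross-section construction uses |x - x0| so bilateral symmetry is
exact at voxel level. The phantoms are straight, uniform extrusions: no
curvature or taper, no rootlets, vasculature, laminar boundaries or CSF
layer. Activation depth is therefore reported in mm from the dorsal
surface rather than by lamina, and agreement of the simulated metrics with
reported values on these phantoms validates the transport physics and the
property model - not any individual animal's anatomy.

## Activation metrics

An intensity map at P mW is thresholded at 1 mW/mm^2 (the conventional
channelrhodopsin activation irradiance) over tissue voxels only. Reported
metrics use voxel centers with no sub-voxel interpolation, so each extent
carries a one-pitch resolution: maximal dorsoventral depth below the
dorsal tissue surface of the voxel's own (x, z) column (the fiber rests on
the surface, so surface-referenced depth is the planning-relevant number;
the fiber-tip-referenced variant differs only through the surface offset),
maximal |z - z_fiber| along the cord, and - for a beam perpendicular to
the fibers - the along-fiber vs across-fiber extent ratio of the same
threshold contour. The elongation statistic compares the two directions of
one anisotropic simulation, the natural reading of "extends further along
the fibers"; the anisotropic-vs-isotropic comparison can be formed by
rerunning with `fiber_axis = "isotropic"`.

## The punch-through estimator

The virtual punch-through experiment mirrors its laboratory counterpart:
the fiber tip is lowered into a slab in steps, and the weight leaving the
bottom face (optionally restricted to a detection objective's acceptance
cone; default collects everything) is recorded against the remaining
thickness, normalized at the shallowest remaining thickness.
`fit_mueff()` fits `T(z) = exp(-mueff z)`: by default an ordinary
least-squares line on `log T` with a free intercept (the intercept absorbs
any normalization), with a fixed-intercept single-parameter Gauss-Newton
fit on T as the alternative; both are exact on noiseless exponentials. A
quadratic lack-of-fit diagnostic flags curvature in `log T` - thin samples
never reach the diffusive regime, and there the fitted constant must be
read as a *relative* decay constant, not as the diffusion-theory
`mueff = sqrt(3 mu_a (mu_a + mu_s'))` returned by `diffusion_mueff()`.
(That square-root form is the standard diffusion result; a dimensionally
inconsistent variant without the square root sometimes appears in print
and is not what this package computes.) The total transmitted power of a
finite slab also carries algebraic prefactors that only flatten once the
remaining thickness spans several `1/mueff`; the test suite's
diffusion-theory comparison therefore uses a deep fit window, and the
white-matter directionality check asserts the robust quantity - the
longitudinal/radial decay-constant ratio (< 0.7) - rather than absolute
values.

## Numerical choices

* Voxel traversal nudges positions 1e-9 mm across faces to avoid
  boundary-sitting; a per-photon path cap (default 1000 mm) guards
  pathological loops, with any killed weight reported separately as
  `lost_fraction`.
* Roulette threshold 1e-4 and survival 0.1 follow common practice in this
  code family; conservation holds to 1e-3 in every tested scenario.
* The direction vector is renormalized after every scatter, keeping |u| = 1
  to 1e-9 over arbitrarily long walks.
* Layered slabs realize thicknesses to the nearest voxel plane;
  zero-thickness layers are skipped with a warning.
* Problem sizes in the tests were chosen as the smallest that leave the
  asserted tolerances statistically meaningful: 1e6 packets for the
  acceptance-grade checks (engine-vs-oracle equivalence, Beer-Lambert,
  activation geometry), 1e4-1e5 for unit-level properties, and 2e4 per
  depth for virtual punch-through profiles.

## Known limitations

* No polarization, coherence, interference or waveguiding physics; the
  hypothesis that myelin sheaths act as optical waveguides is precisely
  the kind of effect a scattering-coefficient model cannot represent.
* No refractive-index mismatch at boundaries (no Fresnel reflection, no
  total internal reflection at the cord surface).
* The axis-resolved model assumes the fiber tracts align with a grid axis;
  arbitrary per-voxel fiber orientations (e.g. from tractography) would
  need a tensor generalization of the combination rule.
* Time-independent transport only; fluence is steady-state per delivered
  watt.
* The whole-blood spectrum is an approximate compilation; users with
  calibrated spectra should supply their own `ExtinctionTable` via the
  `table` argument of `blood_absorption()`.
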