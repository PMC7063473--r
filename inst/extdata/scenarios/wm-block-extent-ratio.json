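{
  "name": "wm-block-extent-ratio",
  "description": "Homogeneous white-matter block (cross-species mean coefficients, fibers along z) probed by the fiber along y: along-fiber vs across-fiber extent of the 1 mW/mm^2 activation contour.",
  "phantom": { "block": { "size_mm": [6, 5, 8], "pitch_mm": 0.04, "tissue": "white_matter" } },
  "tissues": { "preset": "cross_species_mean", "blood_volume_fraction": 0.028, "oxygen_saturation": 0.62 },
  "source": { "position": "dorsal_midline", "core_diameter_mm": 0.105, "na": 0.22, "power": 10, "wavelength": 473 },
  "run": { "n_photons": 1000000, "seed": 30473, "combination_mode": "quadratic" },
  "analysis": { "threshold": 1 }
}
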