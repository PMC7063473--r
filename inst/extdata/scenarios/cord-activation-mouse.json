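{
  "name": "cord-activation-mouse",
  "description": "Mouse cervical cord phantom, 105-um NA-0.22 fiber at the dorsal midline, 10 mW at 473 nm, perfused tissue (2.8% blood, 62% saturation), macaque measured scattering coefficients.",
  "phantom": { "preset": "mouse", "pitch_mm": 0.02, "z_extent_mm": 4 },
  "tissues": { "preset": "macaque_fixed", "blood_volume_fraction": 0.028, "oxygen_saturation": 0.62 },
  "source": { "position": "dorsal_midline", "core_diameter_mm": 0.105, "na": 0.22, "power": 10, "wavelength": 473 },
  "run": { "n_photons": 1000000, "seed": 20473, "combination_mode": "quadratic" },
  "analysis": { "threshold": 1 }
}
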