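# Example synthetic degradation time-course for a 3 mm six-crown/two-link
# Mg-alloy scaffold with 110 um square struts. Times in months, lengths mm.
design:
  nominal_diameter: 3.0
  n_rings: 2            # short test device; use 10 for a full 15 mm scaffold
  crowns_per_ring: 6
  links_between_rings: 2
  strut_width: 0.11
  strut_thickness: 0.11
degradation:
  T_complete: 23.5      # complete degradation period programming k
  substitution_fraction_dense: 0.5
  substitution_fraction_lucent: 0.3
schedule:
  - time: 1
    cut_fraction: 0.02
  - time: 6
    cut_fraction: 0.45
  - time: 12
    cut_fraction: 0.65
  - time: 18
    cut_fraction: 0.98
    dilation: 1.05
rendering:
  spacing: 0.02         # mm/voxel; >= 4 voxels across a strut required
  psf_sigma: 1          # voxels
  noise_sd: 10          # grayvalue units (SNR 10 on the Mg-tissue contrast)
attribution: midpoint
seed: 1
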