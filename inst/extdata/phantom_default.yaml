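# Published three-layer head phantom at 910 nm.
# Coefficients are given in cm^-1 exactly as printed; the loader converts
# to mm^-1. The artery axis runs perpendicular to the source-detector
# line, beneath its midpoint; depth is measured to the axis.
materials:
  skin:  {mu_a_per_cm: 0.37, mu_s_prime_per_cm: 16, g: 0.95}
  skull: {mu_a_per_cm: 0.15, mu_s_prime_per_cm: 18, g: 0.95}
  brain: {mu_a_per_cm: 0.4,  mu_s_prime_per_cm: 21, g: 0.95}
  blood: {mu_a_per_cm: 11,   mu_s_prime_per_cm: 19, g: 0.95}
layers:
  - {name: skin,  thickness_mm: 1.5}
  - {name: skull, thickness_mm: 5.0}
  - {name: brain}            # semi-infinite
artery:
  depth_mm: 3.7
  diameter_mm: 0.4
  offset_mm: 0
  material: blood
domain:
  lateral_mm: 30
  depth_mm: 60
  voxel_mm: 0.05
separation_mm: 11
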