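# Default population parameters of the 177Lu-PSMA-I&T PKPD model.
# Values are in the units as reported; kD_direct (L/day/GBq) and kD_delay
# (L/day/MBq) are converted to per-hour internal units by the package.
pk:
  k10: 0.253        # h^-1, renal excretion
  k12: 0.0105       # h^-1, central -> salivary glands
  k21: 0.0629       # h^-1, salivary glands -> central
  k13: 0.0321       # h^-1, central -> kidneys
  k31: 0.0625       # h^-1, kidneys -> central
  k14: 0.00967      # h^-1, central -> tumor
  k41: 0.0150       # h^-1, tumor -> central
  k15: 0.275        # h^-1, central -> remaining tissue
  k51: 0.0247       # h^-1, remaining tissue -> central
  Bmax_sal: 134     # MBq, salivary binding capacity
  V1: 10.3          # L, central volume (fixed)
  theta_tv_k12: 0.0910
  theta_tv_k14: 1.08
  cycle_fractions:
    cycle2: 0.731
    cycle3: 0.498
    cycle4_7: 0.436
  wt_median: 79     # kg
  tv_median: 0.0443 # L
pd:
  PSA0: 140         # ug/L (fixed typical value)
  theta_tv_PSA0: 57.5
  kG: 0.000408      # h^-1
  kD_direct: 0.00335   # L/day/GBq
  ke0: 0.00128      # h^-1
  kD_delay: 0.0000328  # L/day/MBq
  boxcox_shape: -0.822
iiv_cv:
  k10: 33.1
  k13: 33.4
  k14: 63.4
  k15: 29.1
  Bmax_sal: 67.0
  PSA0: 179
  kG: 90.9
  kD_direct: 140
  kD_delay: 87.5
iov_cv:
  k14: 37.8
ruv:
  central_prop_cv: 55.5
  central_add_sd: 9.57   # MBq/L
  salivary_prop_cv: 39.7
  kidneys_prop_cv: 31.9
  tumor_prop_cv: 32.7
  psa_prop_cv: 29.3
flags:
  cv_mode: exact         # or: direct (omega = CV/100 approximation)
  psa0_form: literal     # or: centered
  decay_mode: corrected  # estimation/observation scale; or: physical (dosimetry)
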