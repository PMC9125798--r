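# SYNTHETIC FIXTURE parameter set for male bowhead length-at-age curves.
# Not published values: calibrated by least squares so that inversion of the
# two-stage curve reproduces the study cohort's printed (body length, age)
# pairs after rounding to whole years, with the two-stage asymptote placed
# between 14.33 m and 14.88 m so that the two largest whales fall back to the
# single-stage curve / comparator averaging, as in the study's age cascade.
VB_II_two_stage:
  L1_inf: 14.79571884
  k1: 0.06006933
  t0: -10.68169458
  transition_age_yr: 28.26925721
  L2_inf: 14.81722388
  k2: 0.05516406
VB_Ia_single_stage:
  L_inf: 15.40
  k: 0.04289275
  t0: -1.0
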