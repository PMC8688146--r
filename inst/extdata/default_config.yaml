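# Default end-to-end pipeline configuration (paired cross-over phantom study)
seed: 1
phantom:
  dims: [20, 20, 10]        # voxels, at 0.4 x 0.4 x 0.8 mm
  n_regions: 8
  n_subjects: 8             # paired: one saline + one insulin scan each
  effect_regions: [MBH]
  effect: 0.7               # insulin multiplies k1 (hence Ce/Cp) by 0.7
  target_cv: 0.05           # median per-frame TAC noise
  vf: 0.6                   # blood-pool volume fraction (mixing & correction)
  subject_sd: 0.1           # log-SD of per-subject k1 multiplier
fit:
  mask_quantile: 0.1
  multistart: 4
  lc: 0.26                  # lumped-constant-type factor in Ce/Cp
stats:
  alpha: 0.05
  min_voxels: 4
  resample_mm: 0.1
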