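# Example apneafuse run configuration: any key omitted here keeps the
# package default (see default_config()).
synthetic:
  n_minutes_per_class: 60
  apnea_rr_swing: 0.1
  hrv_sd: 0.04
  noise_sd: 0.06
  seed: 1
training:
  epochs: 6
  batch_size: 64
  seed: 1
fusion:
  normalize_densities: true
evaluation:
  protocol: two_fold
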