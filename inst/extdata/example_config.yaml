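# Example pipeline configuration (overrides merge onto default_config()).
# Unknown keys are rejected; see load_config().
seed: 20260925
tfr:
  fstep: 2
stats:
  n_perm: 500
rules:
  # the 0.5 f spectral smoothing smears gamma clusters below 40 Hz, so
  # classification uses a lower bounding-box band floor
  pe_band_min_hz: 25
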