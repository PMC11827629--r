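# Example end-to-end pipeline configuration: simulate a small RE31-like
# ensemble, segment and QC the traces, and estimate the kinetic constants.
seed: 11
simulate:
  enabled: true
  n_molecules: 10
  k_on: 1.1e+8     # 1/M/s (YAML floats need a signed exponent)
  c_nM: 5
  k_off: 0.3       # 1/s
  frame_interval: 0.1
  n_frames: 1500
  fret_mode: fixed_2pca
  fret_mean: 0.38
  fret_sd: 0.14
analyze:
  min_frames: 4
  donor_only_cut: 0.15
  min_events: 10
kinetics:
  enabled: true
  min_n: 20
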