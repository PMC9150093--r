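synthetic:
  lipids_per_leaflet: 36
  n_frames: 1
  jitter: 0
  replicates: 2
stages: [thickness, area]
seed: 3
window:
  first: 1
  last: 1
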