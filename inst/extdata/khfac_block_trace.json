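{
  "task": "block-trace",
  "seed": 1,
  "diameter": 10,
  "n_nodes": 51,
  "hfac_freq": 4,
  "electrode_distance": 1000,
  "amplitude_pp": 2000
}
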