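{
  "circuit": {
    "q_gen_lpm": 16,
    "r_val": 60,
    "tube_id_mm": 4.0,
    "leak_size": "ML"
  },
  "pattern": {
    "mode": "spontaneous",
    "a_lpm": 6.3,
    "ti_s": 0.75,
    "te_s": 1.5,
    "n_breaths": 10
  },
  "noise": {
    "sd_pressure_cmh2o": 0.05,
    "sd_flow_lps": 0.002,
    "seed": 1
  }
}
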