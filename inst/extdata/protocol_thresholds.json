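{
  "single_g2": 10,
  "single_g3": 5,
  "sum_g2": 15,
  "min_g2": 5,
  "sum_g3": 5,
  "min_g3": 3.75
}
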