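{
  "preset": "CR1",
  "lambda01": 1,
  "lambda02": 2,
  "beta1": 1,
  "beta2": 1,
  "marker": "X ~ N(0,1), M(t, X) = X"
}
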