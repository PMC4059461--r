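{
  "preset": "CR2",
  "lambda01": 1,
  "lambda02": 0.5,
  "beta1": 2,
  "beta2": -1,
  "marker": "X ~ N(0,1), M(t, X) = X"
}
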