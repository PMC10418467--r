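{
  "kind": "regression",
  "intercept": -42.089,
  "coefficients": {
    "JGI4": 314.536,
    "GGI7": -25.006,
    "Mv": 59.732,
    "X0v": 0.450
  }
}
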