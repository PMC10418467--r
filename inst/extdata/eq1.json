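{
  "kind": "discriminant",
  "intercept": -14.123,
  "coefficients": {
    "nDB": 0.848,
    "nN": 1.680,
    "GGI9": -38.327,
    "JGI4": 392.190
  }
}
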