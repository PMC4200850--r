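{
  "intercept": 1.139556,
  "coef": {
    "quality": -0.403994,
    "sx": 0.199322,
    "au": 0.434889,
    "ot": -0.020189,
    "te": -0.001660
  },
  "cutoff": 0.5,
  "link": "logistic",
  "meta": {
    "N": 2661,
    "Rc": 0.72,
    "chi2": 1913.007,
    "p_level": "<0.005",
    "note": "published reference coefficients; probabilities use the midpoint-0 logistic link as an approximation of the original discriminant posterior",
    "score_midpoint": 0
  }
}
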