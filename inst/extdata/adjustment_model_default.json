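{
  "male": {
    "SouthAsian": {
      "type": "additive_constant",
      "delta": 1.12
    },
    "Black": {
      "type": "banded_linear",
      "bands": [
        {
          "lo": 4,
          "hi": 7,
          "intercept": -0.3,
          "slope": -0.04
        },
        {
          "lo": 7,
          "hi": 10,
          "intercept": -0.4,
          "slope": -0.05
        },
        {
          "lo": 10,
          "hi": 13,
          "intercept": -0.5,
          "slope": -0.06
        }
      ]
    }
  },
  "female": {
    "SouthAsian": {
      "type": "additive_constant",
      "delta": 1.07
    },
    "Black": {
      "type": "banded_linear",
      "bands": [
        {
          "lo": 4,
          "hi": 7,
          "intercept": -0.3,
          "slope": -0.04
        },
        {
          "lo": 7,
          "hi": 10,
          "intercept": -0.4,
          "slope": -0.05
        },
        {
          "lo": 10,
          "hi": 13,
          "intercept": -0.5,
          "slope": -0.06
        }
      ]
    }
  }
}
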