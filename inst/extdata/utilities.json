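{
  "reference": "Remission",
  "horizon": 1,
  "states": [
    {
      "state": "Remission",
      "utility": 0.84999999999999998,
      "alpha": 923,
      "beta": 163
    },
    {
      "state": "Lsever",
      "utility": 0.59999999999999998,
      "alpha": 182,
      "beta": 122
    },
    {
      "state": "Msever",
      "utility": 0.41999999999999998,
      "alpha": 54,
      "beta": 75
    }
  ]
}
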