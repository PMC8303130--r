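{
  "label": "flood early-warning system",
  "threshold": 20000,
  "before": {
    "Msever": 0.055,
    "Lsever": 0.062
  },
  "after": {
    "Msever": 0.033000000000000002,
    "Lsever": 0.037999999999999999
  }
}
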