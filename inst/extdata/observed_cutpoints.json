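{
  "radius_m": 250,
  "statistic": "mean",
  "cutpoints": {
    "city": {"q1": 0.43},
    "borough": {"q1": 0.49},
    "township": {"q1": 0.54}
  },
  "note": "observed community-specific lower tertile cutpoints shipped as a regression fixture for the exposure audit format"
}
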