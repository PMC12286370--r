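{
  "n_men": 497,
  "n_women": 127,
  "activity_men": {"mean": 9, "dispersion": 1.1},
  "activity_women": {"mean": 6, "dispersion": 0.75},
  "desirability_men": {"location": 0, "scale": 0.5, "heavy_tail": false},
  "desirability_women": {"location": 0, "scale": 1, "heavy_tail": true},
  "aspiration_men": 0,
  "aspiration_women": 0,
  "recip_intercept": -40,
  "recip_slope": 0
}
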