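{
  "comment": "Filled vs empty interval. 'peaks' variant: strong isochronous expectations every subdivision; 'background_only' variant: high background rate, no peaks. Interval bounded by events at interval_start and interval_end.",
  "subdivision": 0.25,
  "strength": 2.0,
  "variance": 0.0004,
  "lambda_0": 0.01,
  "bg_rate": 10,
  "interval_start": 0.5,
  "interval_end": 2.5,
  "tail": 0.5,
  "sigma": 0.1,
  "sigma_theta": 0.05,
  "prior_phase_var": 0.0001,
  "prior_tempo_var": 0.01,
  "dt": 0.001
}
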