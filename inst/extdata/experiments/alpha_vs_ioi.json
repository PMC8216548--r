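{
  "comment": "Phase shift at the fourth event of an isochronous sequence, one run per inter-onset interval; alpha is the fraction of the shift absorbed at the next tap.",
  "ioi_grid": [
    0.35,
    0.5,
    0.65,
    0.8,
    0.95,
    1.1
  ],
  "delta": -0.05,
  "shift_event": 4,
  "n_events": 5,
  "strength": 0.2,
  "variance": 0.001,
  "lambda_0": 0.01,
  "sigma": 0.08,
  "sigma_theta": 0.02,
  "prior_phase_var": 0.0001,
  "prior_tempo_var": 0.0001,
  "dt": 0.001
}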