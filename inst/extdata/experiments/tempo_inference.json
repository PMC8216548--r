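{
  "comment": "Metronome with true tempo near the upper end of a wide tempo prior; the filter should lock tempo and phase within the first two events.",
  "period": 0.5,
  "strength": 0.2,
  "variance": 0.001,
  "lambda_0": 0.01,
  "true_tempo": 1.25,
  "prior_tempo_mean": 1.0,
  "prior_tempo_var": 0.04,
  "prior_phase_var": 0.01,
  "n_events": 8,
  "sigma": 0.05,
  "sigma_theta": 0.03,
  "dt": 0.001,
  "t_end": 3.6
}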