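{
  "comment": "Syncopated rhythm on the swing grid: events mostly at weak positions after a long silence. Baseline sigma mis-tracks; sigma_low tracks; adding an isochronous tap stream (own template) tracks.",
  "cycle": 0.5,
  "swing_ratio": [
    3,
    2
  ],
  "strong": {
    "lam": 0.3,
    "v": 0.0004
  },
  "weak": {
    "lam": 0.035,
    "v": 0.0016
  },
  "lambda_0": 0.01,
  "n_cycles": 8,
  "occupancy": [
    1,
    0,
    1,
    0,
    0,
    0,
    0,
    1,
    0,
    1,
    0,
    1,
    0,
    1,
    1,
    0
  ],
  "sigma": 0.08,
  "sigma_low": 0.03,
  "dt": 0.001,
  "V0": 0.0001,
  "t_end": 4.0,
  "tap": {
    "interval": 0.5,
    "n": 9,
    "lam": 0.3,
    "v": 0.0004,
    "lambda_0": 0.01
  }
}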