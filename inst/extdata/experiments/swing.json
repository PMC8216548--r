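{
  "comment": "Swing-grid tracking. Swung eighth-note pairs: one cycle = one pair; the weak peak sits 3/5 of the cycle after the strong one. Occupancy lists which grid positions (alternating strong/weak, in time order) carry a stimulus event.",
  "cycle": 0.5,
  "swing_ratio": [3, 2],
  "strong": {"lam": 0.2, "v": 0.0004},
  "weak": {"lam": 0.05, "v": 0.0016},
  "lambda_0": 0.01,
  "n_cycles": 8,
  "occupancy": [1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 1],
  "sigma": 0.05,
  "dt": 0.001,
  "V0": 0.0001,
  "t_end": 4.0,
  "event_shift": {"index": 6, "delta": -0.04},
  "phase_shift": {"from_index": 6, "delta": -0.05}
}
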