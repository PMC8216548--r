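# Stimulus set shared by the reduction criterion: one deterministic
# stimulus per experiment family, at its frozen configuration.
acceptance_stimuli <- function() {
  swing_tpl <- make_swing_template(0.5, c(3, 2),
                                   strong = list(lam = 0.3, v = 4e-4),
                                   weak = list(lam = 0.035, v = 1.6e-3),
                                   lambda_0 = 0.01, n_cycles = 8)
  grid <- swing_tpl$peaks$phi
  list(
    metronome = list(
      template = make_isochronous_template(0.5, n = 8, strength = 0.2,
                                           variance = 0.001,
                                           lambda_0 = 0.01),
      events = build_stimulus("metronome", list(ioi = 0.5, n = 8)),
      config = filter_config(dt = 0.001, sigma = 0.05, t_end = 4)),
    swing = list(
      template = swing_tpl,
      events = build_stimulus("grid_rhythm",
        list(grid_times = grid,
             occupancy = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 1))),
      config = filter_config(dt = 0.001, sigma = 0.05, t_end = 4)),
    syncopated = list(
      template = swing_tpl,
      events = build_stimulus("grid_rhythm",
        list(grid_times = grid,
             occupancy = c(1, 0, 1, 0, 0, 0, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0))),
      config = filter_config(dt = 0.001, sigma = 0.08, t_end = 4)),
    shifted = list(
      template = make_isochronous_template(0.8, n = NULL, strength = 0.2,
                                           variance = 0.001,
                                           lambda_0 = 0.01),
      events = build_stimulus("phase_shift",
        list(base = build_stimulus("metronome",
                                   list(ioi = 0.8, n = 5, t0 = 0.8)),
             from_index = 4, delta = -0.05)),
      config = filter_config(dt = 0.001, sigma = 0.08, t_end = 4.2)),
    empty_interval = list(
      template = make_isochronous_template(0.25, n = NULL, strength = 2,
                                           variance = 4e-4,
                                           lambda_0 = 0.01),
      events = event_stream(c(0, 0.25, 0.5, 2.5)),
      config = filter_config(dt = 0.001, sigma = 0.1, t_end = 3))
  )
}
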