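# Event update, hazards and the between-event ODE for the 1D filter.

test_that("candidate posterior is the precision-weighted combination", {
  # symmetry: belief mean at the peak mean stays put
  cp <- candidate_posterior(gaussian_belief1d(0.5, 0.037),
                            gaussian_peak(0.5, 0.01, 1))
  expect_equal(cp$mu_hat, 0.5)
  # hand-evaluated precision weighting
  cp <- candidate_posterior(gaussian_belief1d(0.4, 0.01),
                            gaussian_peak(0.5, 0.01, 1))
  expect_equal(cp$mu_hat, 0.45)
  expect_equal(cp$V_hat, 0.005)
  # uninformative prior collapses onto the peak
  cp <- candidate_posterior(gaussian_belief1d(0.1, 1e12),
                            gaussian_peak(0.5, 0.01, 1))
  expect_equal(cp$mu_hat, 0.5, tolerance = 1e-6)
  expect_equal(cp$V_hat, 0.01, tolerance = 1e-6)
})

test_that("hazards convolve peak and belief variances and include lambda_0", {
  b <- gaussian_belief1d(0.3, 0.04)
  tpl <- expectation_template(0.5, list(gaussian_peak(0.5, 0.01, 2)))
  h <- hazards(b, tpl)
  expect_equal(h$per_peak$Lambda_i, 2.3918683193456394) # frozen pdf value
  expect_equal(h$Lambda_total, 0.5 + 2.3918683193456394)
  expect_equal(h$Lambda_total, h$Lambda_0 + sum(h$per_peak$Lambda_i))

  # no peaks: hazard is the background alone
  expect_equal(hazards(b, expectation_template(0.7))$Lambda_total, 0.7)
  # tiny V: the convolved variance tends to the peak's own variance
  h0 <- hazards(gaussian_belief1d(0.3, 1e-14), tpl)
  expect_equal(h0$per_peak$Lambda_i, 2 * dnorm(0.3, 0.5, 0.1),
               tolerance = 1e-9)
})

test_that("event_update matches the quadrature oracle (property)", {
  set.seed(101)
  for (i in 1:60) {
    tpl <- random_template_1d()
    b <- random_belief_1d()
    post <- event_update(b, tpl)
    o <- oracle_event_update_1d(b$mu, b$V, tpl$lambda_0, tpl$peaks)
    expect_equal(post$mu, o$mu, tolerance = 1e-8)
    expect_equal(post$V, o$V, tolerance = 1e-8)
  }
})

test_that("event_update handles the canonical special cases", {
  # single cause, belief at the peak: clean reset to the candidate
  tpl1 <- expectation_template(0, list(gaussian_peak(0.5, 0.01, 3)))
  b <- gaussian_belief1d(0.5, 0.02)
  post <- event_update(b, tpl1)
  expect_equal(post$mu, 0.5)
  expect_equal(post$V, 1 / (1 / 0.02 + 1 / 0.01))
  expect_lt(post$V, b$V)          # single unambiguous cause contracts V

  # event far from the only peak with background: attributed to noise
  tpl2 <- expectation_template(0.5, list(gaussian_peak(5, 0.0001, 1)))
  far <- event_update(gaussian_belief1d(0.5, 0.01), tpl2)
  expect_equal(far$mu, 0.5, tolerance = 1e-10)
  expect_equal(far$V, 0.01, tolerance = 1e-10)

  # liminal zone: causal ambiguity inflates the variance
  tpl3 <- expectation_template(0.5, list(gaussian_peak(0.5, 0.001, 1)))
  lim <- vapply(seq(0.3, 0.48, by = 0.01), function(m)
    event_update(gaussian_belief1d(m, 0.004), tpl3)$V, numeric(1))
  expect_gt(max(lim), 0.004)

  # impossible event
  none <- expectation_template(0, list(gaussian_peak(9, 1e-6, 1)))
  expect_error(event_update(gaussian_belief1d(0, 1e-6), none), "lambda_0")
})

test_that("single-peak correction fraction is V/(V+v1), independent of lam1", {
  phi1 <- 0.5
  frac <- function(mu, V, v1, lam1) {
    tpl <- expectation_template(0, list(gaussian_peak(phi1, v1, lam1)))
    (event_update(gaussian_belief1d(mu, V), tpl)$mu - mu) / (phi1 - mu)
  }
  Vs <- c(0.001, 0.005, 0.02, 0.08)
  v1s <- c(0.001, 0.01, 0.05)
  for (V in Vs) for (v1 in v1s) {
    f <- frac(0.2, V, v1, 1)
    expect_equal(f, V / (V + v1), tolerance = 1e-12)
    # independent of peak strength
    expect_equal(frac(0.2, V, v1, 0.05), f, tolerance = 1e-12)
    expect_equal(frac(0.2, V, v1, 20), f, tolerance = 1e-12)
  }
  # increasing in V, decreasing in v1
  expect_true(all(diff(vapply(Vs, frac, numeric(1), mu = 0.3, v1 = 0.01,
                              lam1 = 1)) > 0))
  expect_true(all(diff(vapply(v1s, function(v) frac(0.3, 0.02, v, 1),
                              numeric(1))) < 0))
})

test_that("with background, correction grows with peak strength", {
  mus <- vapply(c(0.2, 0.5, 1, 2, 5, 20), function(lam1) {
    tpl <- expectation_template(0.5, list(gaussian_peak(0.5, 0.001, lam1)))
    event_update(gaussian_belief1d(0.4, 0.004), tpl)$mu
  }, numeric(1))
  expect_true(all(diff(mus) > 0))   # monotone toward phi1 = 0.5
  expect_true(all(mus > 0.4 & mus < 0.5))
})

test_that("between-event drift opposes the event update", {
  tpl <- expectation_template(0.2, list(gaussian_peak(0.5, 0.002, 1)))
  b <- gaussian_belief1d(0.42, 0.006)
  d <- between_event_derivative(b, tpl, sigma = 0.1)
  push_event <- event_update(b, tpl)$mu - b$mu
  expect_true(sign(d$dmu_dt - 1) == -sign(push_event))
  # just before a strongly expected phase the estimate drags
  expect_lt(d$dmu_dt, 1)

  # no expectations anywhere: pure drift
  far <- between_event_derivative(gaussian_belief1d(0, 1e-4),
    expectation_template(0, list(gaussian_peak(50, 1e-4, 1))), 0.3)
  expect_equal(far$dmu_dt, 1)
  expect_equal(far$dV_dt, 0.09)
})

test_that("run_pippet reproduces the no-event closed form", {
  cfg <- filter_config(dt = 0.001, sigma = 0.2, mu0 = 0.1, V0 = 1e-4,
                       t_end = 2)
  # background-only template: corrections cancel exactly
  tr <- run_pippet(expectation_template(0.8), event_stream(numeric(0)), cfg)
  expect_equal(tr$mu, 0.1 + tr$times, tolerance = 1e-12)
  expect_equal(tr$V, 1e-4 + 0.04 * tr$times, tolerance = 1e-12)
  expect_equal(tr$Lambda, rep(0.8, length(tr$times)))
  # zero-strength peaks behave identically
  tr2 <- run_pippet(make_isochronous_template(0.5, n = 4, strength = 0,
                                              lambda_0 = 0.8),
                    event_stream(numeric(0)), cfg)
  expect_equal(tr2$mu, tr$mu)
  expect_equal(tr2$V, tr$V)
})

test_that("run_pippet responds to timing and phase shifts as expected", {
  tpl <- make_swing_template(0.5, c(3, 2),
                             strong = list(lam = 0.2, v = 4e-4),
                             weak = list(lam = 0.05, v = 1.6e-3),
                             lambda_0 = 0.01, n_cycles = 8)
  cfg <- filter_config(dt = 0.001, sigma = 0.05, mu0 = 0, V0 = 1e-4,
                       t_end = 4)
  base <- build_stimulus("grid_rhythm",
    list(grid_times = tpl$peaks$phi, occupancy = rep(1, 16)))
  shifted <- build_stimulus("event_shift",
    list(base = base, index = 6, delta = -0.04))
  tr <- run_pippet(tpl, shifted, cfg)
  t_ev <- shifted$times[6]
  k <- which.min(abs(tr$times - t_ev))
  err_at_shift <- tr$mu[k] - t_ev
  # partial adjustment toward the early event: mu pulled forward by less
  # than the full shift magnitude
  expect_gt(err_at_shift, 0.005)
  expect_lt(err_at_shift, 0.04)
  # recovery at subsequent events
  expect_lt(abs(tr$mu[length(tr$mu)] - 4), 0.01)

  ph <- build_stimulus("phase_shift",
    list(base = base, from_index = 6, delta = -0.05))
  trp <- run_pippet(tpl, ph, cfg)
  # after the shift the filter converges to the shifted grid: mu - t -> 0.05
  expect_lt(abs(trp$mu[length(trp$mu)] - 4 - 0.05), 0.01)
  # uncertainty is higher after the first early event than after the
  # preceding on-grid event (the early arrival is causally ambiguous)
  k_shift <- which.min(abs(trp$times - ph$times[6]))
  k_prev <- which.min(abs(trp$times - ph$times[5]))
  expect_gt(trp$V[k_shift], trp$V[k_prev])
})

test_that("halving dt barely changes the endpoint (grid refinement)", {
  tpl <- make_swing_template(0.5, c(3, 2),
                             strong = list(lam = 0.2, v = 4e-4),
                             weak = list(lam = 0.05, v = 1.6e-3),
                             lambda_0 = 0.01, n_cycles = 4)
  ev <- build_stimulus("grid_rhythm",
    list(grid_times = tpl$peaks$phi, occupancy = rep(1, 8)))
  run_at <- function(dt) {
    tr <- run_pippet(tpl, ev, filter_config(dt = dt, sigma = 0.05,
                                            t_end = 2))
    c(tr$mu[length(tr$mu)], tr$V[length(tr$V)])
  }
  expect_lt(max(abs(run_at(0.001) - run_at(0.0005))), 1e-3)
})

test_that("multi-stream filtering reduces, adds and rescues", {
  tpl <- make_isochronous_template(0.5, n = 8, strength = 0.2,
                                   variance = 4e-4, lambda_0 = 0.01)
  ev <- build_stimulus("metronome", list(ioi = 0.5, n = 8))
  cfg <- filter_config(dt = 0.001, sigma = 0.05, t_end = 3.6)
  # single stream: identical to the plain filter
  t1 <- run_pippet(tpl, ev, cfg)
  t2 <- run_mpippet(list(a = tpl), event_stream(ev$times,
                                                rep("a", length(ev$times))),
                    cfg)
  expect_identical(t1$mu, t2$mu)
  expect_identical(t1$V, t2$V)

  # disjoint-peak streams: no-event drift corrections add
  tplA <- expectation_template(0, list(gaussian_peak(0.6, 0.002, 1)))
  tplB <- expectation_template(0.3, list(gaussian_peak(0.45, 0.004, 0.7)))
  b <- gaussian_belief1d(0.5, 0.006)
  dA <- between_event_derivative(b, tplA, 0.1)
  dB <- between_event_derivative(b, tplB, 0.1)
  # sum of per-stream corrections (drift terms enter additively)
  combined_dmu <- 1 - ((1 - dA$dmu_dt) + (1 - dB$dmu_dt))
  trM <- run_mpippet(list(A = tplA, B = tplB),
                     event_stream(numeric(0)),
                     filter_config(dt = 0.001, sigma = 0.1, mu0 = 0.5,
                                   V0 = 0.006, t_end = 0.002))
  expect_equal((trM$mu[2] - trM$mu[1]) / 0.001, combined_dmu,
               tolerance = 1e-9)

  # unlabelled events with several templates are rejected
  expect_error(run_mpippet(list(A = tplA, B = tplB),
                           event_stream(c(0.2)), cfg),
               "labelled")
})

test_that("plan_next_tap extrapolates forward at unit rate", {
  taps <- make_isochronous_template(0.5, n = NULL)
  expect_equal(plan_next_tap(gaussian_belief1d(0.4, 0.01), taps, now = 1.0),
               1.1)
  # exactly at a tap phase: the following peak is planned
  expect_equal(plan_next_tap(gaussian_belief1d(0.5, 0.01), taps, now = 1.0),
               1.5)
  # no future peak within horizon
  one <- make_isochronous_template(0.5, n = 2)
  expect_error(plan_next_tap(gaussian_belief1d(2, 0.01), one, now = 2),
               "horizon")
  # over a run, planned taps stay within one tap interval of the grid
  tpl <- make_isochronous_template(0.5, n = 8, strength = 0.2,
                                   variance = 4e-4, lambda_0 = 0.01)
  ev <- build_stimulus("metronome", list(ioi = 0.5, n = 8))
  tr <- run_pippet(tpl, ev, filter_config(dt = 0.001, sigma = 0.08,
                                          t_end = 3.6))
  for (tk in seq(0.25, 3.25, by = 0.5)) {
    k <- which.min(abs(tr$times - tk))
    tap <- plan_next_tap(gaussian_belief1d(tr$mu[k], tr$V[k]), taps,
                         now = tr$times[k])
    nominal <- 0.5 * ceiling(tr$times[k] / 0.5 + 1e-9)
    expect_lt(abs(tap - nominal), 0.5)
  }
})

test_that("events at t = 0 and V-collapse configurations are handled", {
  tpl <- make_isochronous_template(0.5, n = 3, strength = 0.5,
                                   variance = 1e-4, lambda_0 = 0.01)
  tr <- run_pippet(tpl, event_stream(c(0, 0.5)),
                   filter_config(dt = 0.001, sigma = 0.05, mu0 = 0,
                                 V0 = 0.01, t_end = 1))
  expect_equal(tr$event_marks[1], 1L)
  expect_lt(tr$V[1], 0.01)        # the t = 0 event already contracted V
  expect_true(all(tr$V > 0))
})
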