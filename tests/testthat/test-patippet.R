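# Joint phase-and-tempo filter: tempo-scaled rate, 2D moment matching,
# reduction to the 1D filter, covariance hygiene.

test_that("rate_2d scales the 1D rate linearly in tempo", {
  tpl <- expectation_template(0.5, list(gaussian_peak(0.5, 0.01, 1)))
  phases <- c(0.2, 0.5, 0.9)
  expect_equal(rate_2d(tpl, phases, 1), evaluate_rate(tpl, phases))
  expect_equal(rate_2d(tpl, phases, 0), rep(0, 3))
  expect_equal(rate_2d(tpl, 7, 2), 1.0)   # far from peaks: 2 * lambda_0
})

test_that("event_update_2d matches the 2D quadrature oracle (property)", {
  set.seed(202)
  n_checked <- 0
  while (n_checked < 25) {
    tpl <- random_template_1d()
    b <- random_belief_2d()
    post <- event_update_2d(b, tpl)
    o <- oracle_event_update_2d(b$mu2, b$V2, tpl$lambda_0, tpl$peaks)
    expect_equal(post$mu2, o$mu2, tolerance = 1e-6)
    expect_equal(post$V2, o$V2, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
})

test_that("delta-tempo prior reduces the 2D event update to the 1D one", {
  set.seed(303)
  for (i in 1:20) {
    tpl <- random_template_1d()
    b1 <- random_belief_1d()
    b2 <- gaussian_belief2d(c(b1$mu, 1),
                            matrix(c(b1$V, 0, 0, 1e-16), 2, 2))
    p1 <- event_update(b1, tpl)
    p2 <- event_update_2d(b2, tpl)
    expect_equal(p2$mu2[1], p1$mu, tolerance = 1e-6)
    expect_equal(p2$V2[1, 1], p1$V, tolerance = 1e-6)
    expect_equal(p2$mu2[2], 1, tolerance = 1e-8)
  }
})

test_that("2D symmetry: on-expectation event leaves the phase mean alone", {
  tpl <- expectation_template(0, list(gaussian_peak(0.5, 0.003, 1)))
  b <- gaussian_belief2d(c(0.5, 1.1), diag(c(0.01, 0.02)))
  post <- event_update_2d(b, tpl)
  expect_equal(post$mu2[1], 0.5, tolerance = 1e-9)
  expect_lt(post$V2[1, 1], 0.01)
})

test_that("an early event raises the tempo estimate", {
  # the filter believes phase ~ 0.4 when an event expected at phase 0.5
  # arrives; with positive phase-tempo prior coupling absent, the tempo
  # still rises because larger theta explains the early arrival
  tpl <- expectation_template(0.01, list(gaussian_peak(0.5, 0.001, 1)))
  b <- gaussian_belief2d(c(0.4, 1), matrix(c(0.004, 0.004, 0.004, 0.02),
                                           2, 2))
  post <- event_update_2d(b, tpl)
  expect_gt(post$mu2[2], 1)
})

test_that("drift_2d has the linear-Gaussian prediction as its no-hazard limit", {
  cfg <- patippet_config(dt = 0.001, sigma = 0.1, sigma_theta = 0.05,
                         mu2_0 = c(0, 1.2),
                         V2_0 = matrix(c(0.01, 0.002, 0.002, 0.03), 2, 2),
                         t_end = 1)
  faraway <- expectation_template(0, list(gaussian_peak(100, 1e-4, 1)))
  d <- drift_2d(gaussian_belief2d(cfg$mu2_0, cfg$V2_0), faraway, cfg)
  expect_equal(d$dmu2_dt, c(1.2, 0))
  expect_equal(d$dV2_dt,
               matrix(c(2 * 0.002 + 0.01, 0.03, 0.03, 0.0025), 2, 2))

  # integrated: phase variance grows with the t^2 tempo-coupling term
  tr <- run_patippet(faraway, event_stream(numeric(0)), cfg)
  tt <- tr$times
  expect_equal(tr$mu_phi, 1.2 * tt, tolerance = 1e-9)
  closed <- 0.01 + (0.1^2) * tt + 2 * 0.002 * tt + 0.03 * tt^2 +
    (0.05^2) * tt^3 / 3
  expect_lt(max(abs(tr$V_pp - closed)), 1e-4)
})

test_that("PIPPET-reduction configuration reproduces run_pippet", {
  tpl <- make_swing_template(0.5, c(3, 2),
                             strong = list(lam = 0.2, v = 4e-4),
                             weak = list(lam = 0.05, v = 1.6e-3),
                             lambda_0 = 0.01, n_cycles = 8)
  ev <- build_stimulus("grid_rhythm",
    list(grid_times = tpl$peaks$phi,
         occupancy = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 1)))
  cfg1 <- filter_config(dt = 0.001, sigma = 0.05, t_end = 4)
  tr1 <- run_pippet(tpl, ev, cfg1)
  tr2 <- run_patippet(tpl, ev, as_patippet_reduction(cfg1))
  expect_equal(tr2$mu_phi, tr1$mu, tolerance = 1e-6)
  expect_equal(tr2$V_pp, tr1$V, tolerance = 1e-6)
  expect_equal(tr2$mu_theta, rep(1, length(tr1$mu)), tolerance = 1e-9)
  expect_equal(tr2$Lambda, tr1$Lambda, tolerance = 1e-6)
})

test_that("covariance stays symmetric PSD through a tracking run", {
  tpl <- make_isochronous_template(0.5, n = NULL, strength = 0.2,
                                   variance = 0.001, lambda_0 = 0.01)
  ev <- build_stimulus("metronome", list(ioi = 0.4, n = 6, t0 = 0.4))
  cfg <- patippet_config(dt = 0.001, sigma = 0.05, sigma_theta = 0.03,
                         mu2_0 = c(0, 1), V2_0 = diag(c(0.01, 0.04)),
                         t_end = 2.6)
  tr <- run_patippet(tpl, ev, cfg)
  dets <- tr$V_pp * tr$V_tt - tr$V_pt^2
  expect_true(all(tr$V_pp > 0))
  expect_true(all(tr$V_tt > 0))
  expect_true(all(dets > -1e-15))
  # perfectly timed events contract both directions once converged
  marks <- tr$event_marks[-1]
  for (k in marks) {
    expect_lt(tr$V_pp[k], tr$V_pp[k - 1])
    expect_lt(tr$V_tt[k], tr$V_tt[k - 1])
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(gaussian_belief2d(c(0, 1), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive")
  expect_error(gaussian_belief2d(c(0, 1), matrix(c(1, 0.5, 0.2, 1), 2, 2)),
               "symmetric")
  # event with no possible cause
  none <- expectation_template(0, list(gaussian_peak(50, 1e-6, 1)))
  expect_error(event_update_2d(gaussian_belief2d(c(0, 1), diag(c(1e-4, 1e-4))),
                               none),
               "hazard")
})
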