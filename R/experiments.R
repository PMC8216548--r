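# Scripted simulation experiments: event-response surfaces, swing
# tracking, syncopation failure and its rescues, tempo inference,
# period-dependent phase correction (alpha vs IOI), and the
# filled-duration illusion. Each returns an `experiment_result` whose
# summary statistics are computed from its own output tables.

experiment_result <- function(name, params, tables, summaries) {
  stopifnot(is.list(tables), is.numeric(summaries) || length(summaries) == 0)
  structure(list(name = name, params = params, tables = tables,
                 summaries = summaries), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$name, "\n  tables: ",
      paste(names(x$tables), collapse = ", "), "\n", sep = "")
  if (length(x$summaries) > 0) {
    cat("  summaries:\n")
    for (nm in names(x$summaries))
      cat("    ", nm, " = ", signif(x$summaries[[nm]], 6), "\n", sep = "")
  }
  invisible(x)
}

#' Write an experiment result to a directory
#'
#' Each output table becomes `<name>.csv`; the summary statistics go to
#' `summaries.json`.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_result <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    df <- result$tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt9)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(as.list(result$summaries),
                       file.path(dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run a named experiment
#'
#' @param name One of `event_response`, `swing_tracking`, `syncopation`,
#'   `tempo_inference`, `alpha_vs_ioi`, `filled_duration`.
#' @param seed Integer seed for the experiments that draw random numbers
#'   (only `filled_duration`'s background-only filled condition does).
#' @param ... Passed to the experiment function.
#' @return An `experiment_result` (a named list of them for experiments
#'   with several conditions).
#' @export
run_experiment <- function(name, seed = 1L, ...) {
  switch(match.arg(name, c("event_response", "swing_tracking",
                           "syncopation", "tempo_inference",
                           "alpha_vs_ioi", "filled_duration")),
    event_response = exp_event_response(...),
    swing_tracking = exp_swing_tracking(...),
    syncopation = exp_syncopation(...),
    tempo_inference = exp_tempo_inference(...),
    alpha_vs_ioi = exp_alpha_vs_ioi(...),
    filled_duration = exp_filled_duration(seed = seed, ...)
  )
}

exp_config_path <- function(file) {
  p <- system.file("extdata", "experiments", file, package = "pippet")
  if (p == "") stop("missing experiment config: ", file)
  p
}

read_exp_config <- function(file) {
  jsonlite::read_json(exp_config_path(file), simplifyVector = TRUE)
}

# ---------------------------------------------------------------------
# Event-response characterization: how a single event reshapes the
# belief as a function of the prior mean/variance and the peak's
# strength/precision, with and without a background rate.

#' Event-response surfaces for a single expectation peak
#'
#' An event is expected at phase 0.5; an event occurs while the belief
#' mean and variance, the peak strength, and the peak variance are swept
#' one at a time. Emits one table per swept parameter and background
#' level with the post-event mean and variance.
#'
#' @param phi1 Expected event phase (default 0.5).
#' @param lambda_0_values Background rates to run (default 0 and 0.5).
#' @param mu_grid,V_grid,lambda1_grid,v1_grid Sweep grids.
#' @param base Named list of fixed values used while the other
#'   parameters are swept (`mu`, `V`, `lambda1`, `v1`).
#' @return An `experiment_result` with tables `sweep_mu`, `sweep_V`,
#'   `sweep_lambda1`, `sweep_v1`.
#' @export
exp_event_response <- function(phi1 = 0.5,
                               lambda_0_values = c(0, 0.5),
                               mu_grid = seq(0, 1, by = 0.02),
                               V_grid = 10^seq(-3.5, -0.5, length.out = 25),
                               lambda1_grid = 10^seq(-1.5, 1.5,
                                                     length.out = 25),
                               v1_grid = 10^seq(-4, -1, length.out = 25),
                               base = list(mu = 0.4, V = 0.01,
                                           lambda1 = 1, v1 = 0.0025)) {
  one <- function(mu, V, lam1, v1, lam0) {
    tpl <- expectation_template(lam0, data.frame(phi = phi1, v = v1,
                                                 lam = lam1))
    b <- event_update(gaussian_belief1d(mu, V), tpl)
    c(mu_plus = b$mu, V_plus = b$V)
  }
  sweep <- function(var, grid) {
    do.call(rbind, lapply(lambda_0_values, function(lam0) {
      vals <- t(vapply(grid, function(g) {
        a <- base; a[[var]] <- g
        one(a$mu, a$V, a$lambda1, a$v1, lam0)
      }, numeric(2)))
      df <- data.frame(grid, lam0, vals)
      names(df) <- c(var, "lambda_0", "mu_plus", "V_plus")
      df
    }))
  }
  tabs <- list(sweep_mu = sweep("mu", mu_grid),
               sweep_V = sweep("V", V_grid),
               sweep_lambda1 = sweep("lambda1", lambda1_grid),
               sweep_v1 = sweep("v1", v1_grid))
  tmu0 <- tabs$sweep_mu[tabs$sweep_mu$lambda_0 == 0, ]
  # least-squares slope of mu_plus vs mu with no background; the update
  # is exactly linear there with slope 1 - V/(V+v1)
  xc <- tmu0$mu - mean(tmu0$mu); yc <- tmu0$mu_plus - mean(tmu0$mu_plus)
  slope <- sum(xc * yc) / sum(xc^2)
  resid <- yc - slope * xc
  summaries <- c(
    mu_sweep_slope_lam0_0 = slope,
    mu_sweep_max_abs_resid = max(abs(resid))
  )
  experiment_result("event_response",
                    list(phi1 = phi1, base = base,
                         lambda_0_values = lambda_0_values),
                    tabs, summaries)
}

# ---------------------------------------------------------------------
# Swing tracking: a swung eighth-note grid with stronger, more precise
# expectations on the first of every pair; the stimulus populates most
# grid positions and is optionally perturbed.

swing_setup <- function(cfg) {
  tpl <- make_swing_template(cfg$cycle, cfg$swing_ratio,
                             strong = cfg$strong, weak = cfg$weak,
                             lambda_0 = cfg$lambda_0,
                             n_cycles = cfg$n_cycles)
  grid <- tpl$peaks$phi
  list(template = tpl, grid = grid)
}

#' Track a swung rhythm, optionally perturbed
#'
#' @param perturbation `"none"`, `"event_shift"` (one event moved) or
#'   `"phase_shift"` (all events from an index onward moved).
#' @return An `experiment_result` with the trajectory table and
#'   summaries `max_abs_phase_error` and `terminal_phase_error`
#'   (nominal phase advances at rate 1, so the error is `mu - t`).
#' @export
exp_swing_tracking <- function(perturbation = c("none", "event_shift",
                                                "phase_shift")) {
  perturbation <- match.arg(perturbation)
  cfg <- read_exp_config("swing.json")
  su <- swing_setup(cfg)
  events <- build_stimulus("grid_rhythm",
                           list(grid_times = su$grid,
                                occupancy = cfg$occupancy))
  events <- switch(perturbation,
    none = events,
    event_shift = build_stimulus("event_shift",
      list(base = events, index = cfg$event_shift$index,
           delta = cfg$event_shift$delta)),
    phase_shift = build_stimulus("phase_shift",
      list(base = events, from_index = cfg$phase_shift$from_index,
           delta = cfg$phase_shift$delta)))
  config <- filter_config(dt = cfg$dt, sigma = cfg$sigma, mu0 = 0,
                          V0 = cfg$V0, t_end = cfg$t_end)
  traj <- run_pippet(su$template, events, config)
  # nominal phase of the perturbed rhythm: a phase shift moves the whole
  # grid, so the reference becomes t - delta from the shift onward; an
  # event shift is transient and leaves the nominal grid unchanged
  nominal <- traj$times
  if (perturbation == "phase_shift") {
    t_shift <- events$times[cfg$phase_shift$from_index]
    nominal <- ifelse(traj$times >= t_shift,
                      traj$times - cfg$phase_shift$delta, traj$times)
  }
  err <- traj$mu - nominal
  experiment_result("swing_tracking",
    list(perturbation = perturbation, config = cfg),
    list(trajectory = trajectory_df(traj),
         events = data.frame(time = events$times)),
    c(max_abs_phase_error = max(abs(err)),
      terminal_phase_error = abs(err[length(err)])))
}

# ---------------------------------------------------------------------
# Syncopation failure and its two rescues.

#' Syncopated-rhythm tracking: failure and rescues
#'
#' A strongly syncopated rhythm on the swing grid (events mostly at
#' weakly expected positions, with a long silence) is mis-tracked at
#' baseline; it is tracked correctly when the phase noise `sigma^2` is
#' reduced, or when an isochronous stream of finger taps with its own
#' expectation template is added (multi-stream filter).
#'
#' @param condition `"baseline"`, `"low_sigma"` or `"with_taps"`.
#' @return An `experiment_result`; summary `terminal_phase_error` is
#'   `|mu - t|` at the final stimulus event.
#' @export
exp_syncopation <- function(condition = c("baseline", "low_sigma",
                                          "with_taps")) {
  condition <- match.arg(condition)
  cfg <- read_exp_config("syncopation.json")
  su <- swing_setup(cfg)
  events <- build_stimulus("grid_rhythm",
                           list(grid_times = su$grid,
                                occupancy = cfg$occupancy))
  sigma <- if (condition == "low_sigma") cfg$sigma_low else cfg$sigma
  config <- filter_config(dt = cfg$dt, sigma = sigma, mu0 = 0,
                          V0 = cfg$V0, t_end = cfg$t_end)
  if (condition == "with_taps") {
    tap_tpl <- make_isochronous_template(cfg$tap$interval,
                                         n = cfg$tap$n,
                                         strength = cfg$tap$lam,
                                         variance = cfg$tap$v,
                                         lambda_0 = cfg$tap$lambda_0)
    taps <- cfg$tap$interval * (seq_len(cfg$tap$n) - 1)
    all_times <- c(events$times, taps)
    all_labels <- c(rep("audio", length(events$times)),
                    rep("tap", length(taps)))
    o <- order(all_times)
    # drop exact collisions between a tap and an audio event, keep both
    # streams otherwise (strictly increasing times are required)
    keep <- !duplicated(round(all_times[o] / cfg$dt))
    merged <- event_stream(all_times[o][keep], all_labels[o][keep])
    traj <- run_mpippet(list(audio = su$template, tap = tap_tpl),
                        merged, config)
  } else {
    traj <- run_pippet(su$template, events, config)
  }
  t_last <- max(events$times)
  k_last <- which.min(abs(traj$times - t_last))
  err_last <- traj$mu[k_last] - traj$times[k_last]
  experiment_result("syncopation",
    list(condition = condition, config = cfg),
    list(trajectory = trajectory_df(traj),
         events = data.frame(time = events$times)),
    c(terminal_phase_error = abs(err_last),
      terminal_phase_error_signed = err_last))
}

# ---------------------------------------------------------------------
# Tempo inference: metronome with true tempo near the top of a wide
# tempo prior.

#' Joint phase-and-tempo inference on a metronome
#'
#' The filter starts with high tempo uncertainty; the stimulus tempo
#' sits near the upper end of the prior range, so the first events
#' arrive early and pull the tempo estimate up. Summaries report the
#' tempo-mean error after events 0 (prior), 1, 2, and at the end, plus
#' the prior and final tempo variances.
#'
#' @return An `experiment_result`.
#' @export
exp_tempo_inference <- function() {
  cfg <- read_exp_config("tempo_inference.json")
  tpl <- make_isochronous_template(cfg$period, n = NULL,
                                   strength = cfg$strength,
                                   variance = cfg$variance,
                                   lambda_0 = cfg$lambda_0)
  true_theta <- cfg$true_tempo
  ioi <- cfg$period / true_theta
  events <- build_stimulus("metronome", list(ioi = ioi, n = cfg$n_events,
                                             t0 = ioi))
  config <- patippet_config(dt = cfg$dt, sigma = cfg$sigma,
                            sigma_theta = cfg$sigma_theta,
                            mu2_0 = c(0, cfg$prior_tempo_mean),
                            V2_0 = diag(c(cfg$prior_phase_var,
                                          cfg$prior_tempo_var)),
                            t_end = cfg$t_end)
  traj <- run_patippet(tpl, events, config)
  at_event <- function(n) {            # state just after the n-th event
    k <- which.min(abs(traj$times - events$times[n]))
    c(mu_theta = traj$mu_theta[k], V_tt = traj$V_tt[k],
      V_pp = traj$V_pp[k], V_pt = traj$V_pt[k])
  }
  e1 <- at_event(1); e2 <- at_event(2)
  n_end <- length(traj$times)
  dets <- vapply(seq_along(events$times), function(n) {
    s <- at_event(n); s[["V_pp"]] * s[["V_tt"]] - s[["V_pt"]]^2
  }, numeric(1))
  experiment_result("tempo_inference", cfg,
    list(trajectory = trajectory_df(traj),
         events = data.frame(time = events$times),
         cov_det_at_events = data.frame(event = seq_along(events$times),
                                        det = dets)),
    c(tempo_error_initial = abs(cfg$prior_tempo_mean - true_theta),
      tempo_error_after_1 = abs(e1[["mu_theta"]] - true_theta),
      tempo_error_after_2 = abs(e2[["mu_theta"]] - true_theta),
      tempo_error_final = abs(traj$mu_theta[n_end] - true_theta),
      tempo_var_prior = cfg$prior_tempo_var,
      tempo_var_final = traj$V_tt[n_end]))
}

# ---------------------------------------------------------------------
# Period-dependent correction: alpha as a function of inter-onset
# interval.

#' Phase-correction fraction from a trajectory
#'
#' After a phase shift of `delta` seconds in a metronome, the model's
#' next "tap" falls where the mean phase — extrapolated forward from
#' just after the shifted event at the current mean tempo — reaches the
#' next tap-target phase. `alpha` is the proportion of the shift
#' absorbed by that tap: with `T_model` the model tap time and `T_nom`
#' the nominal (unshifted) tap time,
#' \deqn{\alpha = (T_\mathrm{model} - T_\mathrm{nom}) / \Delta,}
#' so a filter that fully resets to the shifted grid gives
#' `alpha = 1` and one that ignores the shift gives `alpha = 0`.
#'
#' @param trajectory A `filter_trajectory` or `filter_trajectory_2d`.
#' @param delta The phase-shift magnitude (seconds, non-zero; negative
#'   means the events moved earlier).
#' @param nominal_tap_time Nominal (unshifted) time of the next tap.
#' @param shift_time Actual time of the shifted event (defaults to
#'   `nominal previous event + delta`, which the caller should supply).
#' @param target_phase Phase the tap aims at (defaults to the nominal
#'   tap time, since nominal phase advances at rate 1).
#' @return `alpha` (scalar).
#' @export
compute_alpha <- function(trajectory, delta, nominal_tap_time, shift_time,
                          target_phase = nominal_tap_time) {
  if (!is.numeric(delta) || delta == 0)
    stop("'delta' must be non-zero; alpha is undefined for a zero shift")
  k <- which.min(abs(trajectory$times - shift_time))
  if (inherits(trajectory, "filter_trajectory_2d")) {
    mu <- trajectory$mu_phi[k]; th <- trajectory$mu_theta[k]
  } else {
    mu <- trajectory$mu[k]; th <- 1
  }
  if (th <= 0 || target_phase <= mu)
    stop("extrapolated mean phase never reaches the tap target")
  t_model <- trajectory$times[k] + (target_phase - mu) / th
  (t_model - nominal_tap_time) / delta
}

#' Alpha as a function of inter-onset interval
#'
#' For each IOI, runs the phase-and-tempo filter on an isochronous
#' sequence with a phase shift at the fourth event and computes the
#' fraction of the shift corrected at the next tap ([compute_alpha()]).
#' Optionally runs the same stimuli under the 1D reduction (delta tempo
#' prior, zero tempo noise), where alpha cannot exceed 1.
#'
#' @param ioi_grid Inter-onset intervals to test (seconds).
#' @param delta Phase-shift magnitude (seconds; negative = earlier).
#' @param reduction If `TRUE`, use the 1D-reduction configuration.
#' @return An `experiment_result` with table `alpha` (columns `ioi`,
#'   `alpha`).
#' @export
exp_alpha_vs_ioi <- function(ioi_grid = NULL, delta = NULL,
                             reduction = FALSE) {
  cfg <- read_exp_config("alpha_vs_ioi.json")
  if (is.null(ioi_grid)) ioi_grid <- cfg$ioi_grid
  if (is.null(delta)) delta <- cfg$delta
  shift_at <- cfg$shift_event          # 1-based index of shifted event
  alphas <- vapply(ioi_grid, function(ioi) {
    n <- cfg$n_events
    base <- build_stimulus("metronome", list(ioi = ioi, n = n, t0 = ioi))
    events <- build_stimulus("phase_shift",
      list(base = base, from_index = shift_at, delta = delta))
    tpl <- make_isochronous_template(ioi, n = NULL,
                                     strength = cfg$strength,
                                     variance = cfg$variance,
                                     lambda_0 = cfg$lambda_0)
    t_end <- ioi * (shift_at + 1)
    config <- patippet_config(dt = cfg$dt, sigma = cfg$sigma,
                              sigma_theta = if (reduction) 0 else
                                cfg$sigma_theta,
                              mu2_0 = c(0, 1),
                              V2_0 = diag(c(cfg$prior_phase_var,
                                            if (reduction) 0 else
                                              cfg$prior_tempo_var)),
                              t_end = t_end)
    traj <- run_patippet(tpl, events, config)
    compute_alpha(traj, delta,
                  nominal_tap_time = ioi * shift_at + ioi,
                  shift_time = ioi * shift_at + delta)
  }, numeric(1))
  tab <- data.frame(ioi = ioi_grid, alpha = alphas)
  experiment_result("alpha_vs_ioi",
    c(cfg, list(reduction = reduction, delta = delta)),
    list(alpha = tab),
    c(alpha_min_ioi = alphas[1],
      alpha_max_ioi = alphas[length(alphas)],
      alpha_monotone = as.numeric(all(diff(alphas) > 0))))
}

# ---------------------------------------------------------------------
# Filled-duration illusion.

#' The filled-duration experiment
#'
#' An interval is marked by events at its endpoints and either
#' subdivided by strongly expected events ("filled") or left "empty".
#' With strong phase-specific expectations (`variant = "peaks"`), the
#' empty interval drags the mean phase at each missed expectation; with
#' `variant = "background_only"` there are no phase-specific peaks but a
#' high background rate, and an empty interval lowers the tempo estimate
#' instead. Summaries report the mean phase-advance rate
#' `(mu_phi(t2) - mu_phi(t1)) / (t2 - t1)` over the interval for both
#' conditions (`t1`, `t2` are the first and last stimulus events
#' bounding the interval; the start value is taken just after the `t1`
#' update and the end value just before the `t2` update).
#'
#' @param variant `"peaks"` or `"background_only"`.
#' @param seed Seed for the background-only filled condition (its filler
#'   events are a seeded Poisson stream).
#' @return An `experiment_result` with tables `trajectory_filled`,
#'   `trajectory_empty` and summaries `advance_rate_filled`,
#'   `advance_rate_empty`, `tempo_drop_empty`.
#' @export
exp_filled_duration <- function(variant = c("peaks", "background_only"),
                                seed = 1L) {
  variant <- match.arg(variant)
  cfg <- read_exp_config("filled_duration.json")
  t1 <- cfg$interval_start; t2 <- cfg$interval_end
  if (variant == "peaks") {
    tpl <- make_isochronous_template(cfg$subdivision, n = NULL,
                                     strength = cfg$strength,
                                     variance = cfg$variance,
                                     lambda_0 = cfg$lambda_0)
    # lead-in from t = 0 establishes tracking before the interval starts
    # (both conditions); the filled condition keeps every expected event,
    # the empty one drops all events strictly inside (t1, t2)
    filled <- build_stimulus("metronome",
      list(ioi = cfg$subdivision,
           n = round(t2 / cfg$subdivision) + 1, t0 = 0))
    empty <- event_stream(c(filled$times[filled$times <= t1 + 1e-9], t2))
  } else {
    tpl <- expectation_template(cfg$bg_rate, period = NULL)
    # seeded Poisson stream at the background rate from t = 0; the empty
    # condition keeps only the events up to t1, plus the closing event
    set.seed(seed)
    n_fill <- stats::rpois(1, cfg$bg_rate * t2)
    fill_times <- sort(stats::runif(n_fill, 1e-3, t2 - 1e-3))
    fill_times <- fill_times[c(TRUE, diff(fill_times) > 2 * cfg$dt)]
    filled <- event_stream(unique(c(fill_times, t2)))
    empty <- event_stream(c(fill_times[fill_times <= t1], t2))
  }
  config <- patippet_config(dt = cfg$dt, sigma = cfg$sigma,
                            sigma_theta = cfg$sigma_theta,
                            mu2_0 = c(0, 1),
                            V2_0 = diag(c(cfg$prior_phase_var,
                                          cfg$prior_tempo_var)),
                            t_end = t2 + cfg$tail)
  run_one <- function(ev) run_patippet(tpl, ev, config)
  traj_f <- run_one(filled)
  traj_e <- run_one(empty)
  # left limits at both endpoints: the interval-bounding events' own
  # updates are excluded, so the rate measures the between-event
  # inference only, symmetrically in both conditions
  advance_rate <- function(traj) {
    k1 <- which.min(abs(traj$times - t1)) - 1L  # just before the t1 update
    k2 <- which.min(abs(traj$times - t2)) - 1L  # just before the t2 update
    (traj$mu_phi[k2] - traj$mu_phi[k1]) /
      (traj$times[k2] - traj$times[k1])
  }
  k1e <- which.min(abs(traj_e$times - t1)) - 1L
  k2e <- which.min(abs(traj_e$times - t2)) - 1L
  experiment_result("filled_duration",
    c(cfg, list(variant = variant, seed = seed)),
    list(trajectory_filled = trajectory_df(traj_f),
         trajectory_empty = trajectory_df(traj_e),
         events_filled = data.frame(time = filled$times),
         events_empty = data.frame(time = empty$times)),
    c(advance_rate_filled = advance_rate(traj_f),
      advance_rate_empty = advance_rate(traj_e),
      tempo_drop_empty = traj_e$mu_theta[k1e] - traj_e$mu_theta[k2e]))
}
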