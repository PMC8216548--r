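# One-dimensional phase filter: Gaussian belief over phase updated in
# continuous time by a between-event ODE and discontinuous event resets.

#' Gaussian belief over phase
#'
#' @param mu Estimated phase (phase units).
#' @param V Phase variance (> 0).
#' @return A `gaussian_belief1d` object.
#' @export
gaussian_belief1d <- function(mu, V) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
    stop("belief variance 'V' must be positive")
  structure(list(mu = mu, V = V), class = "gaussian_belief1d")
}

#' Event-stream container
#'
#' Strictly increasing event times in seconds, optionally labelled by
#' stream for multi-stream filtering.
#'
#' @param times Numeric vector, strictly increasing.
#' @param labels Optional character/factor vector of per-event stream
#'   labels (same length as `times`).
#' @return An `event_stream` object.
#' @export
event_stream <- function(times, labels = NULL) {
  times <- as.numeric(times)
  if (length(times) > 0) {
    if (any(!is.finite(times))) stop("event times must be finite")
    if (is.unsorted(times, strictly = TRUE))
      stop("event times must be strictly increasing")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(times))
      stop("'labels' must match 'times' in length")
  }
  structure(list(times = times, labels = labels), class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat("<event_stream> ", length(x$times), " events",
      if (!is.null(x$labels)) paste0(" in streams {",
        paste(unique(x$labels), collapse = ", "), "}"), "\n", sep = "")
  invisible(x)
}

#' Filter configuration
#'
#' @param dt Integration step (seconds, > 0). The default 0.001 s is well
#'   inside the stable regime for the hazard scales used here.
#' @param sigma Phase noise level \eqn{\sigma} (per square-root second,
#'   >= 0): the belief variance grows at rate `sigma^2` between events.
#' @param mu0,V0 Prior mean and variance at `t = 0`.
#' @param t_end Duration of the run (seconds).
#' @return A `filter_config` object.
#' @export
filter_config <- function(dt = 0.001, sigma = 0.05, mu0 = 0, V0 = 1e-4,
                          t_end = 1) {
  if (dt <= 0) stop("'dt' must be positive")
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (V0 <= 0) stop("'V0' must be positive")
  if (t_end <= 0) stop("'t_end' must be positive")
  structure(list(dt = dt, sigma = sigma, mu0 = mu0, V0 = V0, t_end = t_end),
            class = "filter_config")
}

#' Candidate posterior for one expectation peak
#'
#' The Gaussian posterior on phase that would result if an event were
#' known to be caused by peak `i`: a precision-weighted combination of the
#' current belief and the peak,
#' \deqn{\hat\mu_i = \frac{V^{-1}\mu + v_i^{-1}\phi_i}{V^{-1} + v_i^{-1}},
#'   \qquad \hat V_i = \frac{1}{V^{-1} + v_i^{-1}}.}
#'
#' @param belief A [gaussian_belief1d()].
#' @param peak A [gaussian_peak()] (or any list with `phi` and `v`).
#' @return List with `mu_hat` and `V_hat`.
#' @export
candidate_posterior <- function(belief, peak) {
  w <- belief$V / (belief$V + peak$v)        # = v_i^{-1}/(V^{-1}+v_i^{-1})
  list(mu_hat = belief$mu + w * (peak$phi - belief$mu),
       V_hat = belief$V * peak$v / (belief$V + peak$v))
}

# Core per-peak quantities for a belief/template pair. Returns everything
# the event update and the between-event ODE need:
#   Lambda_i = lam_i * N(mu; phi_i, v_i + V)   (conditional hazards)
#   mu_hat_i, V_hat_i                          (candidate posteriors)
#   Lambda = lambda_0 + sum Lambda_i           (subjective hazard)
# The background is included in Lambda: it is the normalizer of the
# product lambda(phi) * N(phi; mu, V), so the mixture weights
# lambda_0/Lambda, Lambda_i/Lambda sum to one.
peak_moments <- function(belief, template) {
  pk <- relevant_peaks(template, belief$mu, belief$mu, spread = belief$V)
  n <- nrow(pk)
  if (n == 0) {
    return(list(Lambda = template$lambda_0, Lambda_0 = template$lambda_0,
                Lambda_i = numeric(0), mu_hat_i = numeric(0),
                V_hat_i = numeric(0)))
  }
  s2 <- pk$v + belief$V
  Lambda_i <- pk$lam * stats::dnorm(belief$mu, pk$phi, sqrt(s2))
  w <- belief$V / s2
  mu_hat_i <- belief$mu + w * (pk$phi - belief$mu)
  V_hat_i <- belief$V * pk$v / s2
  list(Lambda = template$lambda_0 + sum(Lambda_i),
       Lambda_0 = template$lambda_0,
       Lambda_i = Lambda_i, mu_hat_i = mu_hat_i, V_hat_i = V_hat_i)
}

#' Subjective hazard bundle
#'
#' The subjective hazard rate \eqn{\Lambda} — the instantaneous expected
#' event rate after marginalizing over phase uncertainty — together with
#' the per-peak conditional hazards \eqn{\Lambda_i = \lambda_i\,
#' \varphi(\mu \mid \phi_i, v_i + V)} and the candidate posteriors. The
#' total includes the background: \eqn{\Lambda = \lambda_0 + \sum_i
#' \Lambda_i}.
#'
#' @param belief A [gaussian_belief1d()].
#' @param template An [expectation_template()].
#' @return A `hazard_bundle`: list with `Lambda_total`, `Lambda_0`, and
#'   `per_peak` (data.frame `Lambda_i`, `mu_hat_i`, `V_hat_i`).
#' @export
hazards <- function(belief, template) {
  m <- peak_moments(belief, template)
  structure(list(
    Lambda_total = m$Lambda,
    Lambda_0 = m$Lambda_0,
    per_peak = data.frame(Lambda_i = m$Lambda_i, mu_hat_i = m$mu_hat_i,
                          V_hat_i = m$V_hat_i)
  ), class = "hazard_bundle")
}

# Moment match of the event posterior p(phi) ∝ lambda(phi) N(phi; mu, V):
# mixture over the background cause (weight lambda_0, component = prior)
# and each peak cause (weight Lambda_i, component = candidate posterior).
# The dispersion terms (mu_hat_i - mu_plus)^2 make causal ambiguity
# inflate the posterior variance. mu_plus must be computed before V_plus.
event_posterior_moments <- function(belief, template) {
  m <- peak_moments(belief, template)
  if (m$Lambda <= 0) return(NULL)
  w0 <- m$Lambda_0 / m$Lambda
  wi <- m$Lambda_i / m$Lambda
  mu_plus <- w0 * belief$mu + sum(wi * m$mu_hat_i)
  V_plus <- w0 * (belief$V + (belief$mu - mu_plus)^2) +
    sum(wi * (m$V_hat_i + (m$mu_hat_i - mu_plus)^2))
  list(mu = mu_plus, V = V_plus, Lambda = m$Lambda)
}

#' Discontinuous belief update at an event
#'
#' At an event the belief resets to the Gaussian matching the first two
#' moments of the exact posterior \eqn{p(\phi) \propto \lambda(\phi)\,
#' \varphi(\phi \mid \mu, V)}: a hazard-weighted mixture of the prior
#' (background cause) and the per-peak candidate posteriors, with
#' between-cause dispersion terms that inflate the variance when the
#' cause of the event is ambiguous.
#'
#' @param belief A [gaussian_belief1d()].
#' @param template An [expectation_template()].
#' @return The updated `gaussian_belief1d`.
#' @export
event_update <- function(belief, template) {
  post <- event_posterior_moments(belief, template)
  if (is.null(post))
    stop("event impossible under template (subjective hazard is zero); ",
         "set lambda_0 > 0 to give stray events a background cause")
  gaussian_belief1d(post$mu, post$V)
}

#' Between-event belief derivative
#'
#' The drift of the belief in the absence of events:
#' \deqn{\dot\mu = 1 - \Lambda(\hat\mu - \mu), \qquad
#'   \dot V = \sigma^2 - \Lambda(\hat V - V),}
#' with \eqn{\Lambda, \hat\mu, \hat V} recomputed from the current
#' belief. The absence of an expected event pushes the belief in the
#' opposite direction to the push an event would give.
#'
#' @param belief A [gaussian_belief1d()].
#' @param template An [expectation_template()].
#' @param sigma Phase noise level.
#' @return List with `dmu_dt` and `dV_dt`.
#' @export
between_event_derivative <- function(belief, template, sigma) {
  post <- event_posterior_moments(belief, template)
  if (is.null(post) || post$Lambda <= 0) {
    mu_corr <- 0; V_corr <- 0
  } else {
    mu_corr <- post$Lambda * (post$mu - belief$mu)
    V_corr <- post$Lambda * (post$V - belief$V)
  }
  list(dmu_dt = 1 - mu_corr, dV_dt = sigma^2 - V_corr)
}

# Shared Euler driver for the 1D filter. `stream_templates` is a named
# list of templates; `labels` assigns each event to one of them (single
# unnamed template + NULL labels is the plain single-stream filter).
run_filter_1d <- function(stream_templates, events, config) {
  stopifnot(inherits(events, "event_stream"),
            inherits(config, "filter_config"))
  dt <- config$dt
  n_steps <- round(config$t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  if (length(events$times) > 0 &&
      (min(events$times) < 0 || max(events$times) > config$t_end + dt / 2))
    stop("all event times must lie within [0, t_end]")

  multi <- length(stream_templates) > 1
  if (multi && is.null(events$labels) && length(events$times) > 0)
    stop("events must be labelled when multiple stream templates are configured")
  labels <- if (multi) events$labels else rep(1L, length(events$times))
  if (multi && !all(labels %in% names(stream_templates)))
    stop("every event label needs a configured template")

  # snap events to nearest grid index (error <= dt/2)
  ev_idx <- as.integer(round(events$times / dt)) + 1L
  ev_idx[ev_idx < 1L] <- 1L
  ev_idx[ev_idx > n_steps + 1L] <- n_steps + 1L

  mu <- numeric(n_steps + 1); V <- numeric(n_steps + 1)
  Lam <- numeric(n_steps + 1)
  event_mark <- integer(n_steps + 1)
  mu[1] <- config$mu0; V[1] <- config$V0
  v_floor <- 1e-12
  n_clamped <- 0L

  cur_mu <- config$mu0; cur_V <- config$V0
  ev_at <- split(seq_along(ev_idx), ev_idx)

  # summed hazard and no-event corrections over all streams at a belief;
  # computed once per grid point and reused by the next drift step
  drift_terms <- function(mu_, V_) {
    b <- list(mu = mu_, V = V_)
    Lambda <- 0; mu_corr <- 0; V_corr <- 0
    for (tpl in stream_templates) {
      post <- event_posterior_moments(b, tpl)
      if (is.null(post)) next       # stream hazard is zero: no correction
      Lambda <- Lambda + post$Lambda
      mu_corr <- mu_corr + post$Lambda * (post$mu - mu_)
      V_corr <- V_corr + post$Lambda * (post$V - V_)
    }
    list(Lambda = Lambda, mu_corr = mu_corr, V_corr = V_corr)
  }

  evs0 <- ev_at[["1"]]
  if (!is.null(evs0)) {            # events snapped to t = 0
    for (e in evs0) {
      tpl <- if (multi) stream_templates[[labels[e]]] else
        stream_templates[[1]]
      b <- event_update(list(mu = cur_mu, V = cur_V), tpl)
      cur_mu <- b$mu; cur_V <- max(b$V, v_floor)
    }
    event_mark[1] <- 1L
  }
  terms <- drift_terms(cur_mu, cur_V)
  mu[1] <- cur_mu; V[1] <- cur_V; Lam[1] <- terms$Lambda
  for (k in seq_len(n_steps + 1)[-1]) {
    # drift step (explicit Euler) using terms from the previous grid point
    cur_mu <- cur_mu + dt * (1 - terms$mu_corr)
    cur_V <- cur_V + dt * (config$sigma^2 - terms$V_corr)
    if (cur_V < v_floor) { cur_V <- v_floor; n_clamped <- n_clamped + 1L }
    # events snapped to this grid point, applied after the drift step
    evs <- ev_at[[as.character(k)]]
    if (!is.null(evs)) {
      for (e in evs) {
        tpl <- if (multi) stream_templates[[labels[e]]] else
          stream_templates[[1]]
        b <- event_update(list(mu = cur_mu, V = cur_V), tpl)
        cur_mu <- b$mu; cur_V <- b$V
        if (cur_V < v_floor) { cur_V <- v_floor; n_clamped <- n_clamped + 1L }
      }
      event_mark[k] <- 1L
    }
    terms <- drift_terms(cur_mu, cur_V)
    mu[k] <- cur_mu; V[k] <- cur_V; Lam[k] <- terms$Lambda
  }
  if (n_clamped > 0) {
    if (n_clamped > n_steps / 10)
      stop("variance floor hit persistently (", n_clamped, " of ", n_steps,
           " steps); dt = ", dt, ", sigma = ", config$sigma,
           " is an unstable configuration")
    warning("belief variance clamped at floor 1e-12 on ", n_clamped,
            " step(s)")
  }
  structure(list(times = times, mu = mu, V = V, Lambda = Lam,
                 event_marks = which(event_mark == 1L),
                 event = event_mark, config = config),
            class = "filter_trajectory")
}

#' @export
print.filter_trajectory <- function(x, ...) {
  cat("<filter_trajectory> ", length(x$times), " grid points, ",
      length(x$event_marks), " event bins, t in [0, ",
      x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

#' Run the phase filter over an event stream
#'
#' Explicit-Euler integration of the between-event ODE on a uniform `dt`
#' grid, with the discontinuous event update applied at each event time
#' (snapped to the nearest grid point, after that bin's drift step).
#'
#' @param template An [expectation_template()].
#' @param events An [event_stream()] (labels ignored).
#' @param config A [filter_config()].
#' @return A `filter_trajectory`: list with `times`, `mu`, `V`, `Lambda`,
#'   `event_marks` (grid indices of event bins) and `event` (0/1 per grid
#'   point).
#' @export
run_pippet <- function(template, events, config) {
  stopifnot(inherits(template, "expectation_template"))
  run_filter_1d(list(template), events, config)
}

#' Run the multi-stream phase filter
#'
#' Several labelled event streams share a single underlying phase; each
#' stream `j` has its own expectation template. Between events the drift
#' corrections of all streams add; an event in stream `j` applies the
#' event update using template `j` only.
#'
#' @param templates Named list of [expectation_template()]s, one per
#'   stream label.
#' @param events An [event_stream()] whose labels name streams in
#'   `templates` (labels may be omitted when only one template is given).
#' @param config A [filter_config()].
#' @return A `filter_trajectory`.
#' @export
run_mpippet <- function(templates, events, config) {
  stopifnot(is.list(templates), length(templates) >= 1)
  lapply(templates, function(t)
    stopifnot(inherits(t, "expectation_template")))
  if (length(templates) > 1 && is.null(names(templates)))
    stop("'templates' must be named by stream label")
  run_filter_1d(templates, events, config)
}

#' Plan the next tap by forward extrapolation
#'
#' Given the current belief and a template of expected tap phases,
#' returns the time at which the mean phase, extrapolated forward at unit
#' rate, reaches the next expected tap phase. If the mean is exactly at a
#' tap phase the following peak is scheduled (taps are planned ahead, not
#' issued instantaneously).
#'
#' @param belief A [gaussian_belief1d()].
#' @param tap_template An [expectation_template()] whose peaks are the
#'   expected tap phases.
#' @param now Current time (seconds).
#' @param horizon How far ahead (phase units) to search for a tap peak.
#' @return The planned tap time (> `now`).
#' @export
plan_next_tap <- function(belief, tap_template, now, horizon = 10) {
  pk <- relevant_peaks(tap_template, belief$mu, belief$mu + horizon)
  future <- pk$phi[pk$phi > belief$mu + 1e-12]
  if (length(future) == 0)
    stop("no expected tap phase within the horizon")
  now + (min(future) - belief$mu)
}
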