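# Joint phase-and-tempo filter: 2D Gaussian belief over x = (phi, theta),
# with event rate scaled by tempo so that events arrive at a fixed rate
# per unit *phase* regardless of how fast phase advances.

#' Gaussian belief over phase and tempo
#'
#' @param mu2 Length-2 mean vector `(mu_phi, mu_theta)`.
#' @param V2 2x2 covariance matrix, symmetric positive (semi-)definite.
#' @return A `gaussian_belief2d` object.
#' @export
gaussian_belief2d <- function(mu2, V2) {
  mu2 <- as.numeric(mu2)
  stopifnot(length(mu2) == 2L, all(is.finite(mu2)))
  V2 <- as.matrix(V2)
  stopifnot(all(dim(V2) == c(2L, 2L)), all(is.finite(V2)))
  if (abs(V2[1, 2] - V2[2, 1]) > 1e-9 * (1 + max(abs(V2))))
    stop("covariance must be symmetric")
  V2 <- (V2 + t(V2)) / 2
  if (V2[1, 1] < 0 || V2[2, 2] < 0 || det(V2) < -1e-12 * (1 + max(abs(V2))^2))
    stop("covariance must be positive semi-definite")
  structure(list(mu2 = mu2, V2 = V2), class = "gaussian_belief2d")
}

#' Configuration for the phase-and-tempo filter
#'
#' @param dt Integration step (seconds).
#' @param sigma Phase noise level (per square-root second).
#' @param sigma_theta Tempo noise level (per square-root second).
#' @param mu2_0 Prior mean `(phase, tempo)`; nominal tempo is 1.
#' @param V2_0 Prior 2x2 covariance.
#' @param t_end Duration (seconds).
#' @return A `patippet_config` object.
#' @export
patippet_config <- function(dt = 0.001, sigma = 0.05, sigma_theta = 0.05,
                            mu2_0 = c(0, 1),
                            V2_0 = diag(c(1e-4, 1e-2)), t_end = 1) {
  if (dt <= 0) stop("'dt' must be positive")
  if (sigma < 0 || sigma_theta < 0) stop("noise levels must be non-negative")
  if (t_end <= 0) stop("'t_end' must be positive")
  b <- gaussian_belief2d(mu2_0, V2_0)   # validates the prior
  structure(list(dt = dt, sigma = sigma, sigma_theta = sigma_theta,
                 mu2_0 = b$mu2, V2_0 = b$V2, t_end = t_end),
            class = "patippet_config")
}

#' Tempo-scaled event rate
#'
#' \deqn{\lambda(\phi, \theta) = \theta\,(\lambda_0 + \sum_i \lambda_i\,
#'   \varphi(\phi \mid \phi_i, v_i))}
#' At `tempo = 1` this equals [evaluate_rate()]. The value is negative
#' for negative tempo; the Gaussian posterior is allowed to place mass
#' there (see the package vignette).
#'
#' @param template An [expectation_template()].
#' @param phase,tempo Numeric vectors (recycled to a common length).
#' @return Numeric vector of rates.
#' @export
rate_2d <- function(template, phase, tempo) {
  tempo * evaluate_rate(template, phase)
}

# Per-component unnormalized moments of the event posterior
#   p(x) ∝ theta * lambda_mix(phi) * N(x; mu2, V2).
# Causes: background (weight lambda_0, component = prior) and each peak i
# (weight Lambda_i = lam_i N(mu_phi; phi_i, v_i + V_pp), component = the
# prior conditioned on phi ~ N(phi_i, v_i) via a Kalman step). The tilt
# by theta is handled analytically: for a Gaussian component with mean m,
# covariance W and theta-column c = W[, 2],
#   ∫ theta N(x; m, W) dx            = m_theta
#   E[theta x] = m_theta m + c,  E[theta x x'] = m_theta (W + m m') +
#                                                m c' + c m'.
# Returns sums S0 (normalizer = subjective hazard Lambda), S1 (2-vector),
# S2 (2x2), from which x_hat = S1/S0 and V_hat = S2/S0 - x_hat x_hat'.
patippet_component_sums <- function(belief, template) {
  mu <- belief$mu2; V <- belief$V2
  S0 <- 0; S1 <- c(0, 0); S2 <- matrix(0, 2, 2)
  add_component <- function(w, m, W) {
    mth <- m[2]; cc <- W[, 2]
    S0 <<- S0 + w * mth
    S1 <<- S1 + w * (mth * m + cc)
    S2 <<- S2 + w * (mth * (W + tcrossprod(m)) + tcrossprod(m, cc) +
                       tcrossprod(cc, m))
    invisible(NULL)
  }
  if (template$lambda_0 > 0) add_component(template$lambda_0, mu, V)
  pk <- relevant_peaks(template, mu[1], mu[1], spread = V[1, 1])
  for (i in seq_len(nrow(pk))) {
    S <- V[1, 1] + pk$v[i]
    w <- pk$lam[i] * stats::dnorm(mu[1], pk$phi[i], sqrt(S))
    if (w == 0) next
    K <- V[, 1] / S
    m <- mu + K * (pk$phi[i] - mu[1])
    W <- V - tcrossprod(K, V[, 1])
    add_component(w, m, W)
  }
  list(S0 = S0, S1 = S1, S2 = S2)
}

#' Event update for the phase-and-tempo belief
#'
#' Resets the 2D Gaussian belief to the moment match (mean and
#' covariance) of the exact event posterior \eqn{p(x) \propto
#' \lambda(\phi,\theta)\, \varphi(x \mid \mu, V)}. Because the rate is a
#' mixture of terms linear in \eqn{\theta} times a Gaussian in
#' \eqn{\phi}, the moments are available in closed form (condition each
#' component on its phase Gaussian, then take theta-weighted moments).
#'
#' @param belief A [gaussian_belief2d()].
#' @param template An [expectation_template()].
#' @return The updated `gaussian_belief2d`.
#' @export
event_update_2d <- function(belief, template) {
  s <- patippet_component_sums(belief, template)
  if (!is.finite(s$S0) || s$S0 <= 0)
    stop("event posterior normalizer is non-positive (subjective hazard ",
         signif(s$S0, 4), "); the belief places too much mass at ",
         "non-positive tempo or the event has no cause under the template")
  x_hat <- s$S1 / s$S0
  V_hat <- s$S2 / s$S0 - tcrossprod(x_hat)
  V_hat <- (V_hat + t(V_hat)) / 2
  gaussian_belief2d(x_hat, repair_psd(V_hat))
}

# Symmetrize and clamp negative eigenvalues of a 2x2 covariance at
# `floor`. Standard Kalman hygiene: discretization and moment matching
# can push an eigenvalue slightly negative.
repair_psd <- function(V, floor = 1e-12) {
  V <- (V + t(V)) / 2
  tr <- V[1, 1] + V[2, 2]
  dt_ <- V[1, 1] * V[2, 2] - V[1, 2]^2
  disc <- sqrt(max((tr / 2)^2 - dt_, 0))
  lam_min <- tr / 2 - disc
  if (lam_min >= 0) return(V)
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  V <- e$vectors %*% diag(vals) %*% t(e$vectors)
  (V + t(V)) / 2
}

#' Between-event derivative of the phase-and-tempo belief
#'
#' Prior dynamics (phase advances at the estimated tempo; covariance
#' propagates through the phase-velocity coupling and the noise input)
#' plus the no-event correction that pushes the belief away from what an
#' event would do, in proportion to the subjective hazard:
#' \deqn{\dot\mu = (\mu_\theta, 0) - \Lambda(\hat x - \mu), \qquad
#'   \dot V = A V + V A^\top + Q - \Lambda(\hat V - V)}
#' with \eqn{A} the nilpotent coupling (upper-right entry 1) and
#' \eqn{Q = \mathrm{diag}(\sigma^2, \sigma_\theta^2)}.
#'
#' @param belief A [gaussian_belief2d()].
#' @param template An [expectation_template()].
#' @param config A [patippet_config()].
#' @return List with `dmu2_dt` (length 2) and `dV2_dt` (2x2).
#' @export
drift_2d <- function(belief, template, config) {
  mu <- belief$mu2; V <- belief$V2
  dmu <- c(mu[2], 0)
  AVVA <- matrix(c(2 * V[1, 2], V[2, 2], V[2, 2], 0), 2, 2)
  dV <- AVVA + diag(c(config$sigma^2, config$sigma_theta^2))
  s <- patippet_component_sums(belief, template)
  if (is.finite(s$S0) && s$S0 > 0) {
    # Lambda*(x_hat - mu) = S1 - S0*mu ; Lambda*(V_hat - V) analogous
    dmu <- dmu - (s$S1 - s$S0 * mu)
    dV <- dV - (s$S2 - tcrossprod(s$S1) / s$S0 - s$S0 * V)
  }
  list(dmu2_dt = dmu, dV2_dt = dV)
}

#' Run the phase-and-tempo filter over an event stream
#'
#' Explicit-Euler integration of [drift_2d()] with [event_update_2d()]
#' applied at event times (snapped to the nearest grid point, after that
#' bin's drift step). The covariance is symmetrized and eigenvalue-
#' clamped each step; runs that place more than 1% posterior mass at
#' negative tempo log a warning.
#'
#' @param template An [expectation_template()].
#' @param events An [event_stream()].
#' @param config A [patippet_config()].
#' @return A `filter_trajectory_2d`: list with `times`, `mu_phi`,
#'   `mu_theta`, `V_pp`, `V_pt`, `V_tt`, `Lambda`, `event_marks`,
#'   `event`.
#' @export
run_patippet <- function(template, events, config) {
  stopifnot(inherits(template, "expectation_template"),
            inherits(events, "event_stream"),
            inherits(config, "patippet_config"))
  dt <- config$dt
  n_steps <- round(config$t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  if (length(events$times) > 0 &&
      (min(events$times) < 0 || max(events$times) > config$t_end + dt / 2))
    stop("all event times must lie within [0, t_end]")
  ev_idx <- as.integer(round(events$times / dt)) + 1L
  ev_idx[ev_idx < 1L] <- 1L
  ev_idx[ev_idx > n_steps + 1L] <- n_steps + 1L
  has_event <- rep(FALSE, n_steps + 1L)
  has_event[ev_idx] <- TRUE

  mu_phi <- numeric(n_steps + 1); mu_theta <- numeric(n_steps + 1)
  V_pp <- numeric(n_steps + 1); V_pt <- numeric(n_steps + 1)
  V_tt <- numeric(n_steps + 1)
  Lam <- numeric(n_steps + 1)
  event_mark <- integer(n_steps + 1)

  cur <- list(mu2 = config$mu2_0, V2 = config$V2_0)
  n_neg_tempo <- 0L

  record <- function(k, s0) {
    mu_phi[k] <<- cur$mu2[1]; mu_theta[k] <<- cur$mu2[2]
    V_pp[k] <<- cur$V2[1, 1]; V_pt[k] <<- cur$V2[1, 2]
    V_tt[k] <<- cur$V2[2, 2]
    Lam[k] <<- s0
    if (cur$V2[2, 2] > 0 &&
        stats::pnorm(0, cur$mu2[2], sqrt(cur$V2[2, 2])) > 0.01)
      n_neg_tempo <<- n_neg_tempo + 1L
  }

  apply_events <- function(k) {
    if (has_event[k]) {
      n_here <- sum(ev_idx == k)
      for (j in seq_len(n_here))
        cur <<- unclass(event_update_2d(cur, template))
      event_mark[k] <<- 1L
    }
  }

  apply_events(1L)
  d <- drift_2d(cur, template, config)
  s <- patippet_component_sums(cur, template)
  record(1L, s$S0)
  for (k in seq_len(n_steps + 1)[-1]) {
    cur$mu2 <- cur$mu2 + dt * d$dmu2_dt
    cur$V2 <- repair_psd(cur$V2 + dt * d$dV2_dt)
    apply_events(k)
    d <- drift_2d(cur, template, config)
    s <- patippet_component_sums(cur, template)
    record(k, s$S0)
  }
  if (n_neg_tempo > 0)
    warning("posterior placed > 1% mass at negative tempo on ",
            n_neg_tempo, " recorded step(s)")
  structure(list(times = times, mu_phi = mu_phi, mu_theta = mu_theta,
                 V_pp = V_pp, V_pt = V_pt, V_tt = V_tt, Lambda = Lam,
                 event_marks = which(event_mark == 1L), event = event_mark,
                 config = config),
            class = "filter_trajectory_2d")
}

#' @export
print.filter_trajectory_2d <- function(x, ...) {
  cat("<filter_trajectory_2d> ", length(x$times), " grid points, ",
      length(x$event_marks), " event bins, t in [0, ",
      x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

#' Configuration that reduces the 2D filter to the 1D filter
#'
#' Delta-like tempo prior at tempo 1 with zero tempo noise: with this
#' configuration [run_patippet()] reproduces [run_pippet()] trajectories.
#'
#' @param config A [filter_config()].
#' @return A [patippet_config()].
#' @export
as_patippet_reduction <- function(config) {
  stopifnot(inherits(config, "filter_config"))
  patippet_config(dt = config$dt, sigma = config$sigma, sigma_theta = 0,
                  mu2_0 = c(config$mu0, 1),
                  V2_0 = matrix(c(config$V0, 0, 0, 0), 2, 2),
                  t_end = config$t_end)
}
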