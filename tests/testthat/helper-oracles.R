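# Independent numerical oracles for the event updates, plus small
# fixture builders shared across test files. The oracles integrate the
# exact (non-Gaussian) event posterior on a dense grid and never call
# the closed-form update they are used to check.

# Dense-quadrature moments of p(phi) ∝ lambda(phi) * N(phi; mu, V).
# The grid spans the belief and every peak generously; trapezoid rule.
oracle_event_update_1d <- function(mu, V, lambda_0, peaks, n_grid = 200001) {
  sd <- sqrt(V)
  lo <- mu - 10 * sd; hi <- mu + 10 * sd
  if (nrow(peaks) > 0) {
    lo <- min(lo, min(peaks$phi - 10 * sqrt(peaks$v)))
    hi <- max(hi, max(peaks$phi + 10 * sqrt(peaks$v)))
  }
  phi <- seq(lo, hi, length.out = n_grid)
  lam <- rep(lambda_0, n_grid)
  for (i in seq_len(nrow(peaks)))
    lam <- lam + peaks$lam[i] * dnorm(phi, peaks$phi[i], sqrt(peaks$v[i]))
  w <- lam * dnorm(phi, mu, sd)
  h <- phi[2] - phi[1]
  trap <- function(f) (sum(f) - (f[1] + f[length(f)]) / 2) * h
  Z <- trap(w)
  m1 <- trap(w * phi) / Z
  m2 <- trap(w * (phi - m1)^2) / Z
  list(mu = m1, V = m2, Z = Z)
}

# 2D oracle: moments of p(x) ∝ theta * lambda_mix(phi) * N(x; mu2, V2)
# on a 400x400 grid spanning +/- 8 posterior standard deviations.
oracle_event_update_2d <- function(mu2, V2, lambda_0, peaks, n_grid = 400) {
  sp <- sqrt(V2[1, 1]); st <- sqrt(V2[2, 2])
  lo_p <- mu2[1] - 8 * sp; hi_p <- mu2[1] + 8 * sp
  if (nrow(peaks) > 0) {
    lo_p <- min(lo_p, min(peaks$phi - 8 * sqrt(peaks$v)))
    hi_p <- max(hi_p, max(peaks$phi + 8 * sqrt(peaks$v)))
  }
  phi <- seq(lo_p, hi_p, length.out = n_grid)
  th <- seq(mu2[2] - 8 * st, mu2[2] + 8 * st, length.out = n_grid)
  lam_phi <- rep(lambda_0, n_grid)
  for (i in seq_len(nrow(peaks)))
    lam_phi <- lam_phi + peaks$lam[i] *
      dnorm(phi, peaks$phi[i], sqrt(peaks$v[i]))
  Vi <- solve(V2)
  dp <- outer(phi - mu2[1], rep(1, n_grid))
  dt_ <- outer(rep(1, n_grid), th - mu2[2])
  quad <- Vi[1, 1] * dp^2 + 2 * Vi[1, 2] * dp * dt_ + Vi[2, 2] * dt_^2
  dens <- exp(-quad / 2)
  w <- dens * outer(lam_phi, th, function(a, b) a * b)
  hp <- phi[2] - phi[1]; ht <- th[2] - th[1]
  Z <- sum(w) * hp * ht
  mp <- sum(w * outer(phi, rep(1, n_grid))) * hp * ht / Z
  mt <- sum(w * outer(rep(1, n_grid), th)) * hp * ht / Z
  cp <- outer(phi - mp, rep(1, n_grid))
  ct <- outer(rep(1, n_grid), th - mt)
  Vpp <- sum(w * cp^2) * hp * ht / Z
  Vtt <- sum(w * ct^2) * hp * ht / Z
  Vpt <- sum(w * cp * ct) * hp * ht / Z
  list(mu2 = c(mp, mt), V2 = matrix(c(Vpp, Vpt, Vpt, Vtt), 2, 2))
}

# Random-but-benign fixtures for property tests (seeded by caller).
random_template_1d <- function() {
  n_pk <- sample(0:3, 1)
  peaks <- if (n_pk == 0) {
    data.frame(phi = numeric(0), v = numeric(0), lam = numeric(0))
  } else {
    data.frame(phi = sort(runif(n_pk, -0.5, 1.5)),
               v = runif(n_pk, 0.002, 0.05),
               lam = runif(n_pk, 0.1, 3))
  }
  # keep a positive background so every event has a possible cause
  lam0 <- runif(1, 0.05, 0.8)
  if (n_pk > 1 && any(diff(peaks$phi) < 1e-3))
    peaks$phi <- peaks$phi + cumsum(rep(2e-3, n_pk))
  expectation_template(lam0, peaks)
}

random_belief_1d <- function() {
  gaussian_belief1d(runif(1, -0.2, 1.2), runif(1, 0.001, 0.1))
}

random_belief_2d <- function() {
  a <- runif(1, 0.02, 0.3); b <- runif(1, 0.05, 0.3)
  rho <- runif(1, -0.6, 0.6)
  V <- matrix(c(a^2, rho * a * b, rho * a * b, b^2), 2, 2)
  gaussian_belief2d(c(runif(1, -0.2, 1.2), runif(1, 0.7, 1.3)), V)
}
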