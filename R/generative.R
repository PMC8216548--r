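# Generative side: drift-diffusion phase (and tempo) paths plus
# inhomogeneous point-process event generation, and the deterministic
# stimulus builders used by the experiments.

#' Simulate a drift-diffusion phase path
#'
#' Euler--Maruyama discretization of `dphi = dt + sigma dW`: phase
#' advances at unit rate with Brownian jitter.
#'
#' @param sigma Phase noise level (per square-root second).
#' @param dt Time step (seconds, > 0).
#' @param t_end Duration (seconds).
#' @param seed Integer RNG seed.
#' @param phi0 Initial phase.
#' @return List with `times` and `phi` (equal-length numeric vectors).
#' @export
simulate_phase_path <- function(sigma, dt, t_end, seed, phi0 = 0) {
  stopifnot(dt > 0, t_end > 0, sigma >= 0)
  n <- round(t_end / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  set.seed(seed)
  incr <- dt + sigma * sqrt(dt) * stats::rnorm(n)
  list(times = times, phi = phi0 + c(0, cumsum(incr)))
}

#' Generate events from a phase path by per-bin thinning
#'
#' Each grid bin fires an event with probability `lambda(phi(t)) * dt`
#' (at most one event per bin). The Bernoulli approximation to the
#' inhomogeneous point process requires small per-bin probabilities; the
#' function refuses to run if any bin probability reaches 0.1.
#'
#' @param path A list with `times` and `phi` as returned by
#'   [simulate_phase_path()].
#' @param template An [expectation_template()].
#' @param dt Bin width; must match the path's grid spacing.
#' @param seed Integer RNG seed.
#' @param rate_scale Optional per-bin rate multiplier (e.g. a tempo
#'   path), recycled to the number of bins.
#' @return An [event_stream()].
#' @export
simulate_events <- function(path, template, dt, seed, rate_scale = 1) {
  stopifnot(is.list(path), length(path$times) == length(path$phi))
  p <- evaluate_rate(template, path$phi) * rate_scale * dt
  if (any(p >= 0.1))
    stop("per-bin event probability reaches ", signif(max(p), 3),
         " >= 0.1; use a smaller dt (Bernoulli thinning breaks down)")
  set.seed(seed)
  fire <- stats::runif(length(p)) < p
  event_stream(path$times[fire])
}

#' Simulate a joint phase-and-tempo world with events
#'
#' Tempo follows `dtheta = sigma_theta dW`, phase follows
#' `dphi = theta dt + sigma dW`, and events are generated with the
#' tempo-scaled rate `theta * lambda(phi)` by per-bin thinning.
#'
#' @param config A [patippet_config()]; its prior mean supplies the true
#'   initial phase and tempo of the world.
#' @param template An [expectation_template()].
#' @param seed Integer RNG seed.
#' @return A `sim_world`: list with `times`, `true_phase`, `true_tempo`,
#'   `events` (an [event_stream()]) and `seed`.
#' @export
simulate_patippet_world <- function(config, template, seed) {
  stopifnot(inherits(config, "patippet_config"))
  dt <- config$dt
  n <- round(config$t_end / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  set.seed(seed)
  theta <- config$mu2_0[2] +
    c(0, cumsum(config$sigma_theta * sqrt(dt) * stats::rnorm(n)))
  phi <- config$mu2_0[1] +
    c(0, cumsum(theta[-(n + 1)] * dt + config$sigma * sqrt(dt) *
                  stats::rnorm(n)))
  p <- pmax(rate_2d(template, phi, theta), 0) * dt
  if (any(p >= 0.1))
    stop("per-bin event probability reaches ", signif(max(p), 3),
         " >= 0.1; use a smaller dt")
  fire <- stats::runif(length(p)) < p
  structure(list(times = times, true_phase = phi, true_tempo = theta,
                 events = event_stream(times[fire]), seed = seed),
            class = "sim_world")
}

#' Deterministic stimulus builders
#'
#' Constructs the event streams used in the simulation experiments.
#' `kind` selects the builder:
#' \describe{
#'   \item{`metronome`}{`args = list(ioi, n, t0 = 0)`: `n` events spaced
#'     `ioi` apart starting at `t0`.}
#'   \item{`event_shift`}{`args = list(base, index, delta)`: one event of
#'     the base stream (1-based `index`) moved by `delta` seconds.}
#'   \item{`phase_shift`}{`args = list(base, from_index, delta)`: all
#'     events from `from_index` onward moved by `delta` (a negative
#'     `delta` moves them earlier in time).}
#'   \item{`omission`}{`args = list(base, indices)`: events at `indices`
#'     removed.}
#'   \item{`grid_rhythm`}{`args = list(grid_times, occupancy)`: events at
#'     the grid positions where `occupancy` is 1/TRUE. `grid_times` may
#'     be a numeric vector or an aperiodic [expectation_template()]
#'     (its peak means are the grid).}
#' }
#'
#' @param kind Builder name (see Details).
#' @param args Named list of builder arguments.
#' @return An [event_stream()].
#' @export
#' @examples
#' build_stimulus("metronome", list(ioi = 0.5, n = 4))
#' build_stimulus("phase_shift",
#'   list(base = build_stimulus("metronome", list(ioi = 0.5, n = 6)),
#'        from_index = 4, delta = -0.05))
build_stimulus <- function(kind, args = list()) {
  kind <- match.arg(kind, c("metronome", "event_shift", "phase_shift",
                            "omission", "grid_rhythm"))
  get_base <- function() {
    b <- args$base
    if (inherits(b, "event_stream")) b$times else as.numeric(b)
  }
  times <- switch(kind,
    metronome = {
      stopifnot(args$ioi > 0, args$n >= 1)
      t0 <- if (is.null(args$t0)) 0 else args$t0
      t0 + args$ioi * (seq_len(args$n) - 1)
    },
    event_shift = {
      tt <- get_base()
      if (args$index < 1 || args$index > length(tt))
        stop("'index' out of range")
      tt[args$index] <- tt[args$index] + args$delta
      sort(tt)
    },
    phase_shift = {
      tt <- get_base()
      if (args$from_index < 1 || args$from_index > length(tt))
        stop("'from_index' out of range")
      idx <- seq.int(args$from_index, length(tt))
      tt[idx] <- tt[idx] + args$delta
      sort(tt)
    },
    omission = {
      tt <- get_base()
      if (any(args$indices < 1 | args$indices > length(tt)))
        stop("'indices' out of range")
      tt[-args$indices]
    },
    grid_rhythm = {
      grid <- args$grid_times
      if (inherits(grid, "expectation_template")) {
        if (is_periodic(grid))
          stop("grid template must be aperiodic (tile it first)")
        grid <- grid$peaks$phi
      }
      occ <- as.logical(args$occupancy)
      if (length(occ) != length(grid))
        stop("'occupancy' must match the grid length")
      grid[occ]
    }
  )
  event_stream(times)
}
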