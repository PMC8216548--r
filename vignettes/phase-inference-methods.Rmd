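---
title: "Phase inference from event timing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase inference from event timing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pippet)
```

## The inference problem

`pippet` treats rhythm tracking as continuous Bayesian state estimation.
The generative model has a hidden phase $\phi \in \mathbb{R}$ advancing as
a drift–diffusion process, $d\phi = dt + \sigma\,dW_t$, and an
inhomogeneous point process emitting events at rate
$$\lambda(\phi) = \lambda_0 + \sum_i \lambda_i\,
  \varphi(\phi \mid \phi_i, v_i),$$
a background rate plus Gaussian expectation peaks. Phase lives on the real
line, not the circle: periodic expectations are expressed by a template
whose peak set repeats with a period, aperiodic ones by a finite peak
list, so the same machinery covers metronomes, swung grids, and
non-repeating patterns.

The observer carries a Gaussian posterior $(\mu_t, V_t)$ over phase and
updates it by moment matching: the exact posterior after each
infinitesimal observation interval (an event, or the absence of one) is
projected onto the Gaussian with the same mean and variance — the
minimum-KL Gaussian approximation. Two regimes alternate:

- **Event update.** An event turns $\lambda(\phi)$ into a likelihood; the
  posterior $\propto \lambda(\phi)\,\varphi(\phi \mid \mu, V)$ is a
  mixture over *causes*: each peak $i$ contributes its conditional hazard
  $\Lambda_i = \lambda_i \varphi(\mu \mid \phi_i, v_i + V_t)$ and a
  candidate posterior $(\hat\mu_i, \hat V_i)$ (precision-weighted
  combination of belief and peak); the background contributes weight
  $\lambda_0$ and leaves the prior untouched. The moment-matched variance
  contains between-cause dispersion terms, so an ambiguous event can
  *increase* uncertainty.
- **Between events**, the same quantities enter with opposite sign:
  $\dot\mu = 1 - \Lambda(\hat\mu - \mu)$,
  $\dot V = \sigma^2 - \Lambda(\hat V - V)$. A strongly expected event
  that fails to arrive drags the phase estimate backward and inflates
  uncertainty beyond $\sigma^2$ growth.

**The normalizer.** We define the subjective hazard as
$\Lambda = \lambda_0 + \sum_i \Lambda_i$, i.e. including the background.
This is forced by coherence: the event-update mean is a mixture with
weights $\lambda_0/\Lambda$ and $\Lambda_i/\Lambda$, which must sum to
one, and $\lambda_0 + \sum_i \Lambda_i$ is exactly the normalizer of
$\lambda(\phi)\varphi(\phi\mid\mu,V)$. The package's quadrature-oracle
tests confirm that with this definition the closed-form update reproduces
the true posterior moments to near machine precision.

## Joint phase and tempo

The 2D filter tracks $x = (\phi, \theta)$ with
$dx = (\theta, 0)\,dt + (\sigma\,dW, \sigma_\theta\,dW^\theta)$ and
tempo-scaled rate $\lambda(\phi,\theta) = \theta\,\lambda(\phi)$, so that
events arrive at a fixed rate per unit *phase* regardless of tempo. The
event posterior $\propto \theta\,\lambda(\phi)\,\varphi(x \mid \mu, V)$
is again analytically tractable: each cause contributes a Gaussian
component obtained by conditioning on the peak ($\phi \sim
\mathcal N(\phi_i, v_i)$, a rank-one Kalman step), and the linear tilt by
$\theta$ has closed-form Gaussian moments
($\mathbb E[\theta x] = m_\theta m + c$, etc., with $c$ the
$\theta$-column of the component covariance). `event_update_2d()`
assembles the mixture moments from these per-component sums; a
400×400-point quadrature oracle over ±8 posterior standard deviations
checks it to 1e-6 in the test suite. Between events the prior dynamics
are the standard linear-Gaussian prediction
($\dot V = AV + VA^\top + Q$ with nilpotent phase–velocity coupling
$A$ and $Q = \mathrm{diag}(\sigma^2, \sigma_\theta^2)$) minus the same
$\Lambda$-proportional no-event correction.

With $\sigma_\theta = 0$ and a delta-like tempo prior at $\theta = 1$ the
2D filter reduces exactly to the 1D filter; the suite verifies this on
every experiment stimulus to 1e-6 (`as_patippet_reduction()`).

**Negative tempo.** The rate $\theta\lambda(\phi)$ is negative for
$\theta < 0$, where the model is not meaningful. We keep the Gaussian
posterior untouched (no clamping or truncation of $\theta$), matching the
model's Gaussian commitment, and log a warning whenever more than 1% of
posterior mass sits at $\theta < 0$. None of the shipped experiment
configurations triggers it. An event whose posterior normalizer is
non-positive (possible in that pathological regime) raises an error.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `sigma` | phase / √s | 0.05–0.12 | expected phase noise; sets how fast uncertainty accumulates in silence, hence how aggressively events correct the estimate |
| `sigma_theta` | tempo / √s | 0.02–0.05 | expected tempo drift; governs period correction and tempo-mediated over-correction |
| `v_i` | s² | 4e-4–2.5e-3 | temporal (im)precision of each expectation; $\sqrt{v_i}$ of 20–50 ms matches auditory timing precision |
| `lambda_i` | – | 0.03–2 | expectation strength; relative values set which peaks win causal attribution |
| `lambda_0` | events/s | 0.01 | background rate; absorbs stray events and guarantees every event has a cause |
| `dt` | s | 0.001 | Euler step; events snap to the grid (error ≤ dt/2) |
| `V0`, `V2_0` | s² | 1e-4 prior phase var | initial certainty |

## Numerical choices

- **Integration** is explicit Euler at `dt = 0.001` s; event updates are
  applied after the drift step of the event's (nearest-grid) bin. A
  grid-refinement test checks that halving `dt` moves endpoint estimates
  by < 1e-3. Beliefs stay left-continuous in the sense that recorded
  values at event bins are post-update.
- **Peak truncation**: a peak (or periodic copy) contributes only within
  ±8 standard deviations (including belief spread), a relative truncation
  error below 1e-14; periodic templates are lazily tiled by the same
  rule, and `tile_periodic()` makes the unrolling explicit.
- **Variance hygiene**: the 1D variance is floored at 1e-12 (warning;
  persistent flooring aborts with the offending configuration named).
  The 2D covariance is symmetrized each step and negative eigenvalues are
  clamped at 1e-12 — standard Kalman hygiene for discretized dynamics.
- **Tie-break in tap planning**: if the mean phase sits exactly on a tap
  peak, the *next* peak is scheduled — taps are planned ahead, never
  issued for the instant the plan is made.
- **Degenerate inputs**: an event with zero subjective hazard is an error
  (advising `lambda_0 > 0`) rather than a silent no-op, because it
  signals a misconfigured template.

## What the generators emulate

`simulate_phase_path()` / `simulate_events()` /
`simulate_patippet_world()` sample the model's own world: Euler–Maruyama
phase (and tempo) paths and per-bin Bernoulli thinning of the
inhomogeneous point process (at most one event per bin; the run refuses
bin probabilities ≥ 0.1, where the Bernoulli approximation to Poisson
counts degrades). They emulate clean laboratory stimuli — precisely
controlled event times around a latent clock — not real audio: there is
no onset-detection noise, no amplitude or timbre information, and no
history-dependent structure. A green self-consistency test (tracking
error falling as expectation strength rises, averaged over 50 seeds)
therefore establishes that the filter exploits informative event timing
from its own model class, not that it tracks real music.

The *experiment* stimuli are deterministic (noise enters only through the
filter's model of the world), matching the clean event grids of the
phenomena being reproduced; seeds appear only where a stimulus is itself
random (the background-only filled-duration filler stream).

## Calibrated experiment configurations

The published figure parameters live in supplementary material that is
not available here, so each experiment's configuration was calibrated
once against the qualitative claims it must reproduce and frozen under
`inst/extdata/experiments/`:

- **Swing grid** (tracking and syncopation): 0.5 s cycles split 3:2
  (long–short), strong peaks λ = 0.3, √v = 20 ms; weak peaks λ = 0.035,
  √v = 40 ms. The syncopated pattern — events mostly at weak positions
  after a 1.3 s silence — yields a clean capture failure at σ = 0.08
  (terminal phase overestimated by ≈ 0.25 s, about one weak-grid
  offset); σ = 0.03 or an added isochronous tap stream rescues tracking.
- **Tempo inference**: prior tempo mean 1, variance 0.04; true tempo 1.25
  (upper end of the prior); the tempo error falls from 0.25 to ≈ 0.07
  within two events.
- **Alpha vs IOI**: 50 ms early phase shift at the fourth event; with
  σ = 0.08, σθ = 0.02 the correction fraction α rises monotonically from
  0.77 (IOI 0.35 s) through 1 (≈ 0.8 s) to 1.11 (1.1 s); the 1D
  reduction caps at α ≤ 1 because full phase reset is its strongest
  possible correction.
- **Filled duration**: 0.25 s subdivisions with λ = 2 inside a 2 s
  interval. Advance-rate endpoints are *left limits at both bounding
  events*, so the statistic measures between-event inference symmetrically
  in the filled and empty conditions; with asymmetric endpoints the
  filled rate would carry one sawtooth segment of lag. Filled ≈ 0.993,
  empty ≈ 0.76; the background-only variant (λ0 = 10 /s, no peaks) slows
  instead by lowering its tempo estimate (drop ≈ 0.33).

These values are a *stated world*, not tuning knobs: they were fixed
before the acceptance assertions were frozen and are not revisited.

## Known limitations

- Off-grid event times are snapped to the Euler grid; there is no
  adaptive stepping or exact inter-event integration.
- Phase is linear, not circular; indefinitely long periodic stimuli rely
  on lazy tiling rather than wrapped phase.
- Expectation peaks are symmetric Gaussians; asymmetric likelihoods
  (events can only be perceived after they occur) would require numerical
  updates.
- Templates are history-independent: an event does not change the
  expectancy of later events. Grammar-like rhythmic structure is out of
  scope.
- The multi-stream generalization is implemented for the 1D filter only;
  the 2D filter is single-stream.
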