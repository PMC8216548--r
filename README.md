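# pippet: continuous-time Bayesian phase and tempo inference from event timing

`pippet` implements a family of point-process filters for *rhythmic
entrainment*: estimating, moment by moment, the phase (and optionally the
tempo) of a hidden temporal process from nothing but the precise times of
discrete events — the computational problem a listener solves when tracking
a beat through a complex, syncopated, or perturbed rhythm. It is aimed at
computational neuroscientists and music-cognition researchers who want a
normative (Bayesian) model of beat tracking, and at anyone who needs a
principled online phase/tempo tracker for event streams.

## The model

A hidden phase advances as a drift–diffusion process,
`dφ = dt + σ dW`, and events are emitted by an inhomogeneous point process
whose rate is an **expectation template**

```
λ(φ) = λ0 + Σi λi · N(φ; φi, vi)
```

— a uniform background rate `λ0` plus Gaussian peaks at the phases `φi`
where events are expected, with strengths `λi` and temporal variances
`vi`. The filter maintains a Gaussian posterior over phase (mean `μ`,
variance `V`) by moment matching:

- **Between events**, `μ̇ = 1 − Λ(μ̂ − μ)`, `V̇ = σ² − Λ(V̂ − V)`, where
  `Λ = λ0 + Σi Λi` is the *subjective hazard rate* — the expected event
  rate under the current belief, with per-peak conditional hazards
  `Λi = λi · N(μ; φi, vi + V)`. Silence is informative: a strongly
  expected event that fails to arrive drags the phase estimate back.
- **At an event**, the belief resets to the Gaussian matching the moments
  of `λ(φ)·N(φ; μ, V)`: a mixture over possible causes (each peak, or the
  background), whose between-cause dispersion can *increase* `V` when the
  cause of the event is ambiguous.

The two-dimensional variant tracks `x = (φ, θ)` jointly, with tempo
`θ` driving phase (`dφ = θ dt`) and scaling the event rate
(`λ(φ,θ) = θ·λ(φ)`); its event update is the exact 2D Gaussian moment
match, available in closed form. A multi-stream variant gives each labelled
event stream (say, audio and one's own taps) its own template over a shared
phase.

## Worked example

Track a metronome whose later events are phase-shifted 50 ms early:

```r
library(pippet)
template <- make_isochronous_template(0.5, n = 8, strength = 0.2,
                                      variance = 4e-4, lambda_0 = 0.01)
events <- build_stimulus("phase_shift",
  list(base = build_stimulus("metronome", list(ioi = 0.5, n = 8)),
       from_index = 5, delta = -0.05))
config <- filter_config(dt = 0.001, sigma = 0.05, t_end = 4)
traj <- run_pippet(template, events, config)
traj
#> <filter_trajectory> 4001 grid points, 8 event bins, t in [0, 4]
k <- which.min(abs(traj$times - events$times[5]))
traj$mu[k] - events$times[5]   # phase error just after the early event
#> [1] 0.03899536
tail(traj$mu, 1)               # terminal phase estimate at t = 4
#> [1] 4.050781
```

Just after the first early event the estimate has absorbed only part of
the 50 ms shift (it still reads ~39 ms "ahead" of the new grid); by the
end of the run `μ − t = 0.0508`, i.e. the filter has locked onto the
shifted grid (which runs 50 ms ahead of elapsed time). Joint
phase-and-tempo inference on a metronome whose tempo sits near the top of
a wide prior:

```r
exp_tempo_inference()
#> <experiment_result> tempo_inference
#>   summaries:
#>     tempo_error_initial = 0.25
#>     tempo_error_after_1 = 0.152918
#>     tempo_error_after_2 = 0.0673976
#>     tempo_error_final = 0.00190097
#>     tempo_var_prior = 0.04
#>     tempo_var_final = 0.0023157
```

The tempo estimate covers most of the 25% initial tempo error within two
events and ends with ~6% of the prior tempo variance.

## Experiments and CLI

Six scripted experiments reproduce the package's core phenomena from
frozen configurations (`inst/extdata/experiments/*.json`):
`event_response`, `swing_tracking`, `syncopation` (failure plus two
rescues), `tempo_inference`, `alpha_vs_ioi` (period-dependent
over-correction), `filled_duration`. Run them from R
(`run_experiment("syncopation", condition = "baseline")`) or the CLI:

```sh
Rscript inst/cli/pippet experiment tempo_inference --out out/
Rscript inst/cli/pippet filter --config cfg.json --template tpl.json \
        --events events.csv --out out/
```

Every CLI run writes a `manifest.json` (config echo, seeds, warnings)
sufficient to replay it bit-exactly.

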