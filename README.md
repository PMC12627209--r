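# ffreport

Simulation and analysis tools for **feature frequency report (FFR)**
experiments in ensemble perception. In the FFR paradigm an observer briefly
sees 36 colored disks drawn from a circular 48-hue wheel (neighboring hues
~1 JND apart) and reports, on a 0–8 slider, how many disks had a postcued
color. Because the three stimulus conditions — Gaussian, uniform and
bimodal exemplar-count profiles — are matched on item count, color range
and mean, the *shape* of the response curve over probe offsets separates
two accounts of ensemble perception: observers who only access summary
statistics (mean, variance) cannot track the profile, while observers with
access to the feature distribution can.

The package is aimed at researchers who want to simulate FFR sessions,
run the standard analysis chain on simulated or real trial tables, and
test the sub-sampling alternative explanation quantitatively.

## What it computes

* **Stimulus generation** — sessions of intermixed Gaussian / uniform /
  bimodal trials on the 48-hue circular space, with probes at
  0, ±3, …, ±21 JND from the mean (`generate_session()`).
* **Observer models** — the *sub-sampling observer*: each disk is perceived
  with circular Gaussian hue noise (SD σ, JND), a uniformly random subset
  of N ≤ 36 disks is attended, matches to the probe are counted, and the
  count is scaled by a uniform random integer multiplier in 1…⌊36/N⌋,
  clipped to the slider (`simulate_subsampling_response()`); plus a
  veridical-noisy fixture observer for validating the analysis stages.
* **Response curves** — folding by absolute probe offset, per-observer and
  aggregated curves with SEM, and paired t-tests of the offset-0 mean
  against every other offset (`fold_and_average()`, `aggregate_curves()`,
  `compare_mean_vs_offsets()`).
* **Segmented regression** — the two-segment model
  *y = β₀ + β₁x + β₂(x − ψ)₊* with the break point ψ estimated by Muggeo's
  iterative linearization, delta-method CIs, the conservative Davies test
  for the existence of a break, fixed-break per-observer slopes and group
  slope tests (`fit_broken_line()`, `davies_test()`,
  `slopes_at_fixed_break()`, `group_slope_test()`).
* **Exact model fitting** — the exact response PMF of the sub-sampling
  observer via dynamic programming (hypergeometric subset weighting ×
  Bernoulli matches; Poisson-binomial at N = 36), maximum-likelihood
  fitting over (N, σ), and a parameter-recovery study
  (`response_pmf()`, `fit_mle()`, `parameter_recovery()`).
* **Pipeline** — file-level commands with config snapshots
  (`ffr_simulate()`, `ffr_analyze()`, `ffr_fit()`, `ffr_recover()`) and a
  thin CLI wrapper at `inst/cli/ffr.R` with subcommands
  `simulate | analyze | fit | recover`.

## Worked example

```r
library(ffreport)

session <- generate_session(450, observer_id = "obs01", seed = 1)
session <- simulate_dataset(session, subsampling_params(N = 28, sigma = 5),
                            seed = 2)
fit_mle(session)
#> Sub-sampling model maximum-likelihood fit
#>   N = 25, sigma = 4.094 JND  (NLL = 397.933 over 450 trials)
```

A single 450-trial session recovers the generating parameters (N = 28,
σ = 5) to within a few units — the NLL profile over N (in `fit$profile`)
shows how sharply N is identified. The folded response curve tracks the
presented distribution; for this observer's bimodal trials it rises toward
the ±12 JND edge and falls outside the presented range, and the segmented
fit localizes the turn:

```r
bi <- session$condition == "bimodal"
fit_broken_line(abs(session$test_offset[bi]), session$response[bi])
#> Two-segment broken-line fit
#>   break point psi = 11.350 JND, 95% CI [8.269, 14.430]
#>   slope before    = +0.0519, CI [0.0132, 0.0906]
#>   slope after     = -0.1173, CI [-0.1716, -0.0629]
#>   Davies test for a break: p = 0.0006455
#>   n = 150, RSS = 92.5, 2 iteration(s)
```

The positive-then-negative slope pair around a break near the distribution
edge is the bimodal signature; uniform sessions give a flat-then-negative
pair and Gaussian sessions a negative-then-flat one.

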