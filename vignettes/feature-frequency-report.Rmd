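---
title: "Simulating and analyzing feature frequency report experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing feature frequency report experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffreport)
```

## The paradigm

In a feature frequency report (FFR) experiment an observer briefly views 36
colored disks and then reports, on a slider from 0 to 8, how many disks had
a postcued color. The colors live on a circular wheel of 48 hues spaced
about one just-noticeable difference (JND) apart, so all offsets and noise
magnitudes in this package are measured in JND and all hue arithmetic is
circular (modulo 48).

Each display realizes one of three fixed, symmetric exemplar-count profiles
around a per-trial random mean hue:

| offset from mean (JND) | 0 | ±3 | ±6 | ±9 | ±12 |
|---|---|---|---|---|---|
| gaussian | 8 | 7 | 4 | 2 | 1 |
| uniform  | 4 | 4 | 4 | 4 | 4 |
| bimodal  | 0 | 2 | 3 | 6 | 7 |

All three conditions share the total count (36), the color range (±12 JND)
and a mean offset of zero, so they are deliberately matched on the summary
statistics that a mean-plus-variance account of ensemble perception would
use. The probed color sits at a signed offset of 0, ±3, …, ±12 (a presented
value) or ±15, ±18, ±21 (outside the range) from the mean. If observers can
only access summary statistics, their response curves cannot track which of
the three profiles was shown; if they represent the distribution itself,
the folded response curve should follow the table above.

## What the generator emulates, and what it does not

`generate_session()` produces trial tables: a uniformly random mean hue, a
condition, and a probed offset per trial. Three choices are configuration,
not claims about any particular experiment:

* **Offset sampling** is uniform over the 15 signed values. Real designs
  may oversample some offsets; the probabilities are a config field.
* **Condition intermixing** uses balanced random blocks of three, so
  condition counts are equal to within one block while remaining
  unpredictable trial to trial.
* **Session length** defaults to 450 trials, i.e. about 30 trials per
  folded offset × condition cell — enough for stable cell means while
  staying within a realistic single-session budget for a human observer.

A display is represented as a multiset of hue indices only. Spatial
positions, disk sizes, exposure time, color calibration, response times and
lapses are not modeled; the frequency report depends only on hue counts, so
none of these affect the quantities this package computes. Consequently,
passing tests here validate the *analysis machinery and the observer
models*, not any claim about human vision.

## Observer models

`simulate_veridical_response()` is a test fixture: the true count at the
probed hue plus additive Gaussian response noise, rounded and clipped to
the slider. With zero noise it reproduces the ground-truth curve exactly,
which pins down the folding and aggregation stages end to end.

`simulate_subsampling_response()` implements the sub-sampling account of
ensemble reports: the observer perceives every disk with independent
Gaussian hue noise (SD σ, in JND), attends a uniformly random subset of
N of the 36 disks, counts how many of those look identical to the probe,
and scales the count up by a uniform random integer multiplier in
1…⌊36/N⌋ to compensate for the unattended disks. Numerical choices:

* **Matching rule.** A noised hue "looks identical" to the probe when it
  rounds to the probed hue on the wheel, i.e. lands within half a wheel
  step (±0.5 JND) circularly. The 48 hues are ~1 JND apart, so rounding to
  the wheel is the natural discretization of "same color".
* **Multiplier domain.** When N does not divide 36 the multiplier is a
  uniform integer on 1…⌊36/N⌋ (identically 1 for N ≥ 19).
* **Clipping.** Responses are clipped to the slider range [0, 8]; the
  response device cannot express larger values.
* **Wrap-around.** Noise is applied on the circle and wrapped before
  rounding. This only matters for large σ, but it makes the per-hue match
  probabilities an exact partition of unity.

## Exact likelihood and fitting

For a trial, disk *i* matches the probe with probability
*p*ᵢ = Φ((−dᵢ+0.5)/σ) − Φ((−dᵢ−0.5)/σ) (plus wrap terms), where *d*ᵢ is the
disk's circular offset from the probe. The number of matches within a
uniformly random size-N subset has an exact distribution computed by
dynamic programming over disks with state (selected, matches), weighting
selections hypergeometrically — with N = 36 it reduces to the
Poisson-binomial distribution. The response PMF mixes that distribution
over the multiplier and clips to the slider. The test suite checks the DP
against brute-force subset enumeration on small toys and against
Monte-Carlo frequencies of the generative simulator.

An exact likelihood was chosen over a simulated one because it is
deterministic and fast: trials sharing a condition and probe offset share
their PMF, so a session collapses to at most 45 profiles regardless of
length. `negative_log_likelihood()` adds a floor of 10⁻¹² inside the
logarithm so that a response the model deems impossible (a lapse, in human
data) cannot produce an infinite objective; the floor is configurable.

`fit_mle()` searches N = 1…36 exhaustively and, for each N, minimizes the
negative log-likelihood over σ with a bounded one-dimensional search on
[0.05, 20] JND (tolerance 10⁻³). Ties across N break toward the smaller N.
The σ bounds comfortably bracket every plausible value: below 0.05 JND the
model is effectively noiseless, above 20 JND (nearly the half-wheel) the
responses are indistinguishable from colour-blind guessing.

`parameter_recovery()` draws N uniformly on {1, …, 36} and σ uniformly on
[0.5, 10] JND, simulates one 450-trial session per pair with the generative
observer, refits, and correlates true with fitted values. The σ range
covers the values typically estimated for human observers (roughly 3–8
JND) with margin on both sides. A caveat worth knowing: when N is small
the random multiplier dominates the response and the likelihood becomes
very flat in σ (profiling shows basins several JND wide within one
log-likelihood unit), so σ recovery is intrinsically noisy in that corner
of the parameter space even though N itself recovers almost perfectly.
Restricting the draws to the regime actually estimated for humans
(N ≥ ~19) makes σ recovery near-perfect; the wide default is kept because
it is the more demanding and more informative check.

## Response-curve analysis

`fold_and_average()` exploits the symmetry of all three distributions:
responses at +k and −k JND are averaged within observer and condition
(offset 0 is not double-counted), and every folded cell must contain at
least one trial — empty cells are a hard error naming the cells rather
than a silent NA. `aggregate_curves()` averages folded curves across
observers with SEM = SD/√n. `compare_mean_vs_offsets()` runs paired
t-tests of the offset-0 mean against every other offset across observers
(two-tailed by default; the tail is configurable), with Cohen's d the mean
paired difference over its SD. Zero-variance differences are flagged
rather than silently producing infinite t.

## Segmented regression

The folded curves are summarized by a two-segment linear model
y = β₀ + β₁x + β₂(x − ψ)₊ with break point ψ. `fit_broken_line()` uses the
iterative linearization of Muggeo: at a working ψ the model is refit with
the gap covariate V = −1(x > ψ), and ψ is updated by γ̂/β̂₂. Three
implementation details matter in practice:

* **Step halving.** The raw update can overshoot; the step is halved until
  the three-parameter RSS does not increase, making the iteration monotone.
* **Kinks.** The RSS profile in ψ is piecewise smooth with kinks at the
  data x values. When the minimizer sits exactly at a kink no step can
  decrease the RSS; a stalled halving is therefore convergence, not
  failure.
* **Starts.** The midpoint of the x range is tried first, then the 25% and
  75% quantiles of the distinct x values; the best converged solution by
  RSS is kept. Exactly linear data raise an explicit
  "break unidentified" error.

Confidence intervals are delta-method Wald intervals,
SE(ψ) = SE(γ̂)/|β̂₂| from the final working model. Simulation in the test
suite shows ~95% coverage where the design is dense (continuous x,
n = 600); on the coarse 8-level offset grid with few trials the interval
under-covers by a few percentage points, a known finite-sample property of
Wald intervals for break points. A bootstrap is a reasonable cross-check
when the CI matters substantively.

`davies_test()` addresses the fact that ψ is only identified under the
alternative: the slope-change t statistic is evaluated at k = 10 evenly
spaced interior candidates and Davies' (1987) adjusted upper bound
p ≤ Φ(−M) + V·e^(−M²/2)/√(8π) (doubled for the two-sided test) is returned,
where M is the extremal statistic and V the total variation across
candidates. The bound is conservative; a 1000-run simulation under a flat
null in the test suite confirms the empirical size stays below the nominal
5%.

For the individual-observer analysis, `slopes_at_fixed_break()` refits each
observer with ψ *fixed* at the value estimated from the aggregated data
(ψ is an input there, never re-estimated), and `group_slope_test()`
compares the per-observer slopes against zero with a one-sample t-test,
reporting |mean|/SD as Cohen's d. The aggregated fits default to per-trial
responses (rather than per-offset means) because that uses all degrees of
freedom; both modes are available via `ffr_analyze(per_trial = )`.

## Problem sizes used in the test suite

The bundled tests simulate ten observers × 450 trials for the end-to-end
shape-recovery check, 400 parameter pairs × 450 trials for the recovery
study, 1000 datasets for the Davies size simulation and for break-point CI
coverage, and 100,000 Monte-Carlo draws per case for the
simulator-vs-likelihood cross-checks. These sizes give Monte-Carlo error
comfortably below the tolerances being asserted while keeping a full run
of the suite in the ten-minute range on a single core.

## Known limitations

* The observer models contain no lapses, no response-time structure, no
  motor noise on the slider, and no serial dependence between trials.
* The sub-sampling model's σ is weakly identified at small N, as discussed
  above; fitted σ values for observers estimated at small N should be read
  with their profile likelihood in mind (`fit_mle()` returns the per-N
  profile for exactly this purpose).
* The break-point CI is asymptotic; on 8-level designs with few trials
  prefer the bootstrap or report the Davies p-value alongside.
* Hue indices are abstract; mapping them to rendered colors (calibration,
  CIE coordinates) is outside the package's scope.
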