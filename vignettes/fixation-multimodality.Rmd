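---
title: "Multimodality-aware fixation accuracy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodality-aware fixation accuracy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixmodal)
```

# Scope

`fixmodal` analyzes the *within-fixation* distribution of angular offsets
between gaze and target in random-saccade-task eye-tracking data. Its central
claim of interest is statistical: whether that distribution has one mode or
several, and what an accuracy number should mean in each case. This vignette
documents the model, every tunable parameter with units and defaults, the
numerical choices, and the limitations.

# Data model and geometry

A recording (`gaze_recording`) is a uniformly sampled time series (default
1000 Hz) of gaze position and target position, both in degrees of visual
angle, with missing samples as `NaN`. A position $(x, y)$ in degrees maps to
the direction vector $(\tan x, \tan y, 1)$, L2-normalized (tangent-plane
convention at unit viewing distance). The angular offset between gaze and
target is the angle between their direction vectors,
$\arccos(\mathbf{u} \cdot \mathbf{v})$ in degrees, with the dot product
clamped to $[-1, 1]$. Along a meridian this equals the coordinate difference
exactly; the planar Euclidean distance (also provided) is about 0.5% high at
a 10-degree separation and is useful only as a cross-check.

# Synthetic generator

`generate_recording()` emulates a random-saccade task well enough to give
every downstream stage a ground-truth oracle; it is an *emulation of task
phenomenology*, not a biomechanical eye model. Components:

* **Targets** (`generate_target_sequence`): uniform over ±15° × ±9°,
  consecutive steps ≥ 2°, 1 s dwell per target.
* **Latency**: per-trial saccade latency drawn from N(237, 17²) ms truncated
  to [192, 316] ms (all configurable). The planted latency is defined as the
  delay from the target jump to the *midpoint* of the saccade: because the
  minimum-jerk profile is time-symmetric, the offset-minimizing alignment
  shift recovers exactly this quantity, which is what the latency estimator
  measures.
* **Saccades**: minimum-jerk position profiles
  ($10\tau^3 - 15\tau^4 + 6\tau^5$) with a main-sequence duration rule,
  duration = 21 ms + 2.2 ms/deg of amplitude. Peak radial velocity exceeds
  55°/s for amplitudes ≥ 2° under this rule.
* **Fixation offsets**: each trial gets an offset direction and, per mixture
  component, a magnitude drawn from the scenario's Gaussian mixture
  (truncated at zero). Multi-component specs are realized as contiguous
  within-trial blocks with lengths proportional to the weights, joined by
  60 ms minimum-jerk ramps, so the within-fixation offset *distribution* is
  the requested mixture while the *trajectory* stays physically continuous.
* **Noise and drift**: white positional noise (default SD 0.05°) and an
  optional within-fixation sinusoidal drift of the offset magnitude.
* **Blinks**: NaN blocks of 50–300 ms flanked by ±3–10° vertical transients
  over 20 ms, mimicking eyelid-driven artifacts around signal loss.
* **Anticipatory saccades**: with per-trial probability min(1, slope × trial),
  gaze jumps to the *next* target 150–300 ms before the actual target jump.

All randomness flows through a private, restorable RNG stream derived from
(scenario seed, subject, session), so recordings are reproducible and
independent across subjects. Ground truth (latencies, saccade spans, blink
spans, anticipatory events, per-sample component labels) is attached as an
attribute and serialized alongside the CSV by `write_gaze_csv()`.

# Preprocessing

`preprocess_recording()` applies, in order (`pipeline_config()` holds all
defaults):

1. **Latency removal** (`estimate_latency`, `shift_gaze`): the gaze signal is
   advanced by the integer shift in 1..800 samples that minimizes the mean
   angular offset (ties to the smallest shift); the recording is truncated by
   the shift, dropping the final shortened fixation.
2. **Blink-saccade removal** (`remove_blink_saccades`): velocities come from
   a Savitzky–Golay differentiator (order 2, window 7, per contiguous non-NaN
   segment). A per-recording fixation velocity threshold (*FixVelT*) is the
   90th percentile of radial velocity after discarding stretches whose peak
   exceeds 55°/s, blocks shorter than 40 ms, and 4 samples at each block end.
   Around every NaN block the algorithm marches outward until three
   contiguous samples fall below FixVelT and removes everything strictly
   between the marks; at recording boundaries the whole stretch is removed.
3. **Velocity-based saccade removal** (`remove_saccades_velocity`): every
   block with radial velocity above 55°/s is expanded to the nearest local
   minima below 30°/s (inclusive) and set to NaN.
4. **Quadratic-window removal** (`remove_saccades_quadratic`): in each
   sliding 27-sample window, each position channel is regressed on the
   squared window index ($1^2..27^2$, i.e. 1..729) with an intercept. Windows
   with $r^2 > 0.6$ *and* $|\beta| \times 1000 > 0.55$ are flagged; the union
   of flagged windows over both channels is removed. The two gates separate
   saccade-like parabolic structure (high curvature per sample) from ordinary
   slow drift, which has high $r^2$ but a tiny slope.
5. **Anticipatory-saccade removal** (`remove_anticipatory`): per-trial runs
   where |horizontal| or |vertical| offset exceeds 2° for at least 100 ms and
   which overlap the analysis window are removed and logged.

The **analysis window** is the contiguous 500 samples of the trial with the
lowest mean offset curve, computed across fixations that have no NaN and no
sample above 60° (cohort-level unless `fixed_window` is set). A fixation is
**included** if its window retains ≥ 400 valid samples in ≤ 4 NaN blocks + 1
segments; subjects with any session under 20 included fixations are dropped
(`min_good_fixations`).

# Multimodality

## Bayesian mixture with unknown k

`fit_rjmcmc()` samples a univariate Gaussian mixture with
$k \in \{1..k_{\max}\}$ ($k_{\max} = 5$) components using the
reversible-jump formulation: conjugate Gibbs sweeps for weights
(Dirichlet $\delta = 1$), order-preserving means
($\mu_j \sim N(\xi, \kappa^{-1})$ with $\xi$ the data midrange and
$\kappa = R^{-2}$, $R$ the range), variances
($\sigma_j^{-2} \sim \Gamma(\alpha = 2, \beta)$ with hyperprior
$\beta \sim \Gamma(0.2, 10 / R^2)$) and allocations, alternating with a
split/merge move (adjacency-constrained, full acceptance ratio including the
Jacobian) and a birth/death move for empty components whose newborn
parameters are drawn from the prior. Defaults: 2000 retained iterations after
500 burn-in. A `likelihood = FALSE` switch turns off the data term everywhere
so the chain must reproduce the uniform prior over $k$ — a detailed-balance
diagnostic enforced in the test suite.

The **Bayes factor** for multimodality is
$\mathrm{BF} = \frac{P(k > 1 \mid y) / P(k = 1 \mid y)}{P(k > 1) / P(k = 1)}$,
reported as a natural log. Two sentinels handle degenerate posteriors: if
$P(k > 1 \mid y) = 0$ the value is $\log(0.003)$; if $P(k = 1 \mid y) = 0$ it
is $+\infty$, replaced at report time (`histogram_report`) by the largest
finite value in the batch. Evidence classes: $\le 1$ unimodal, $(1, 3]$
positive, $(3, 5]$ strong, $> 5$ very strong.

## Frequentist cross-check

`acr_test()` computes the excess-mass statistic
$\max_\lambda \{E_2(\lambda) - E_1(\lambda)\}$, where $E_m(\lambda)$ is the
largest empirical mass minus $\lambda \times$ length attainable with $m$
disjoint intervals with endpoints at data points. Each $E_m(\lambda)$ is
computed exactly in $O(n)$ by cumulative max/min recursions (verified against
brute-force enumeration in the tests); $\lambda$ runs over a fixed 201-point
linear grid from 0 to twice the maximum of a Gaussian KDE of the sample — the
excess-mass difference vanishes at both endpoints, so a bounded grid loses
nothing, and the grid makes the statistic deterministic and cheap. The null
distribution comes from a smoothed bootstrap at the *critical bandwidth* (the
smallest bandwidth making the KDE unimodal, found by bisection),
variance-rescaled so null samples keep the data's variance; the p-value uses
the add-one convention $(1 + \#\{T^* \ge T\}) / (B + 1)$.

# Normality screen and accuracy metrics

At $n = 500$ formal normality tests reject almost any real sample, so
`simulate_limits()` builds empirical 5th–95th percentile bands for
moment-based sample skewness and (non-excess) kurtosis from 10,000
standard-normal samples of the analysis-window length. A fixation passes the
screen iff both statistics fall inside both bands (two 90% bands jointly pass
roughly 84% of truly normal samples — the screen is deliberately
conservative).

Per fixation, `accuracy_metrics()` reports: **ClassicAccuracy** (mean offset,
always), **MaxCompMean** (mean of the heaviest mixture component, ties to the
smaller mean — the recommended accuracy for multimodal fixations),
**MedianAccuracy** (unimodal fixations only) and **MeanAccuracy** (unimodal
*and* normal fixations only).

# Drift

For single-segment fixations with exactly 500 valid samples, `drift_r2()`
subtracts the sample mean, zero-pads the residual to a 512-point FFT, keeps
only bins 2 and 3 (1.95 and 3.91 Hz at 1000 Hz) and their conjugates, inverts
the transform, adds the mean back, and regresses the offsets on this
reconstruction plus a linear time term; the fit's $r^2$ is the drift
statistic. Demeaning before padding matters: padding the raw series leaks the
DC step into every bin and caps the achievable $r^2$ for genuinely in-band
signals. `drift_vs_multimodality()` then regresses the log Bayes factor on
the drift $r^2$ across fixations (infinite values excluded).

# Numerical and design choices

* Quantiles use R's default type 7 throughout.
* The latency search is exhaustive over integer shifts; ties go to the
  smallest shift, and the window search ties go to the earliest start —
  both so results are deterministic.
* The quadratic detector's $27^2 = 729$ end-of-window regressor and the two
  gates (r² 0.6, |β|×1000 at 0.55) are taken as fixed thresholds of the
  method; the sliding sums are computed by convolution filters so the
  detector is $O(n)$ per channel.
* The mixture point estimate conditions on the modal $k$ and averages the
  retained draws of that dimension (components sorted by mean); with
  order-preserving mean updates, label switching within a fixed $k$ is not a
  practical concern at these separations.
* Every randomized stage derives its seed from the master seed and stable
  integer tags (recording index, trial, stage), all below $2^{31}$, and
  restores the caller's RNG state afterwards.
* Problem sizes used in the examples and tests (cohort sizes, iteration
  counts, bootstrap replicates) are this package's own choices, balanced for
  test-time determinism; production analyses should scale them up.

# Limitations

* The sampler's split/merge move uses Beta(2,2)/Beta(2,2)/Beta(1,1)
  auxiliary draws with an adjacency constraint; for heavily overlapping
  components (separation below ~2 SD) the posterior over $k$ is honest but
  indecisive, and the Bayes factor will sit in the "positive" band rather
  than resolving the truth.
* The excess-mass calibration tests the *unimodal* null; it says nothing
  about 2 vs 3 modes.
* The generator is a task-level emulation: it does not model smooth pursuit,
  the main-sequence velocity–amplitude curvature, pupil-size artifacts, or
  tracker-specific noise spectra.
* The drift statistic is only defined for clean single-segment windows, so
  drift–multimodality regressions are restricted to that (biased) subset.
* Euclidean offsets are supplied for comparison but all pipeline decisions
  use the angular metric.

# Minimal end-to-end example

```{r example, eval = FALSE}
seqs <- generate_target_sequence(8, seed = 101)
comp <- list(means = c(0.6, 2.0), sds = c(0.05, 0.05), weights = c(0.8, 0.2))
sc   <- synthetic_scenario(seed = 101, components = comp)
recs <- lapply(1:3, function(s) generate_recording(seqs, sc, subject = s))
cfg  <- pipeline_config(fixed_window = c(192, 691), min_good_fixations = 2,
                        seed = 101)
res  <- run_pipeline(recs, cfg, run_acr = FALSE)
res$summary
```
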