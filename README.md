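# fixmodal

Multimodality-aware accuracy analysis for eye-tracking fixations.

## The problem

The spatial accuracy of an eye tracker is usually summarized as the mean (or
median) angular offset between gaze and target during fixation. That summary
silently assumes the offsets within a fixation form one well-behaved cluster.
In practice they often do not: slow drift, micro-movements and post-saccadic
shifts split the within-fixation offset distribution into two or more modes,
and a single mean then describes a position the eye never occupied. `fixmodal`
provides the full chain needed to study this on random-saccade-task data:

1. **Synthetic generator** — seeded random-saccade recordings (targets on a
   ±15° × ±9° grid, 1 s dwell, 1000 Hz) with planted saccade latencies,
   minimum-jerk saccades, blinks, anticipatory saccades, sinusoidal drift and
   arbitrary within-fixation offset mixtures, all with ground truth attached.
2. **Angular geometry** — gaze positions in degrees are mapped to 3-D
   direction vectors; the angular offset is the angle between gaze and target
   directions (with the planar Euclidean offset as a cross-check).
3. **Preprocessing** — latency alignment (offset-minimizing shift over 1–800
   samples), blink-saccade removal around NaN blocks using a per-recording
   fixation velocity threshold, velocity-based saccade removal (55°/s peaks
   expanded to sub-30°/s local minima), a sliding 27-sample quadratic
   detector for residual saccade pieces, anticipatory-saccade plateau removal,
   analysis-window selection (the contiguous 500 samples with the lowest mean
   offset) and per-fixation inclusion rules (≥ 400 valid samples, ≤ 4 NaN
   blocks).
4. **Multimodality** — a reversible-jump MCMC sampler for a univariate
   Gaussian mixture with an unknown number of components (1–5), giving a
   posterior over the number of components and a Bayes factor for "more than
   one component"; plus a frequentist excess-mass test calibrated by a
   smoothed bootstrap at the critical bandwidth.
5. **Normality screen** — simulation-based acceptance bands for sample
   skewness and kurtosis at the analysis-window length, because formal
   normality tests reject trivially at n = 500.
6. **Accuracy metrics** — `ClassicAccuracy` (the conventional mean),
   `MaxCompMean` (the mean of the heaviest mixture component),
   `MedianAccuracy` (unimodal fixations) and `MeanAccuracy` (unimodal and
   normal fixations).
7. **Drift analysis** — per-fixation r² of the offsets against a
   reconstruction from the two slowest nonzero FFT bins plus a linear trend,
   and the regression of the log Bayes factor on that drift statistic.

## Worked example

```r
library(fixmodal)

# a small cohort with a planted 80/20 offset mixture at 0.6 and 2.0 degrees
seqs <- generate_target_sequence(8, seed = 101)
comp <- list(means = c(0.6, 2.0), sds = c(0.05, 0.05), weights = c(0.8, 0.2))
sc   <- synthetic_scenario(seed = 101, components = comp)
recs <- lapply(1:3, function(s) generate_recording(seqs, sc, subject = s))

cfg <- pipeline_config(fixed_window = c(192, 691), min_good_fixations = 2,
                       seed = 101)
res <- run_pipeline(recs, cfg, run_acr = FALSE)

res$summary
#>   n_segments n_fixations pct_unimodal pct_positive pct_strong pct_very_strong
#>            1           0           NA           NA         NA              NA
#>            2          21            0            0          0             100
#> ...
#>        total          21            0            0          0             100

inc <- res$fixations[res$fixations$included, ]
round(c(classic = mean(inc$classic), max_comp = mean(inc$max_comp_mean)), 3)
#>  classic max_comp
#>    0.962    0.593
```

Every included fixation is flagged as very strong evidence for multimodality
(log Bayes factor > 5). The conventional mean offset (0.962°) lands between
the two true components, describing a position the eye rarely occupied; the
heaviest-component mean (0.593°) recovers the planted dominant offset of
0.6°.

Single fixations can be analyzed directly:

```r
x <- generate_offset_sample(comp, 500, seed = 7)
fit <- fit_rjmcmc(x, seed = 7)
fit
#> <mixture_posterior> n=500, modal k=2, log(BF)=Inf [very_strong]
acr_test(x, n_boot = 200, seed = 7)$p_value
#> [1] 0.004975124
```

## Documentation

The methods vignette (`vignettes/fixation-multimodality.Rmd`) describes the
statistical model, every tunable parameter with units and defaults, the
numerical choices and the known limitations.
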