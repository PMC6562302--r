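# urbanmove

Movement-behavior states and home-range complexity for territorial
carnivores along an urbanization gradient.

Urban landscapes confront resident carnivores (the motivating system is
resident urban coyotes, *Canis latrans*) with fragmented habitat and
pervasive human presence. Two questions follow from GPS telemetry: *how*
do animals move (how much time is spent encamped, foraging, traveling?),
and *what* space do they use (how large, and how fragmented, are their
home ranges?). `urbanmove` is an R package for both halves of that
analysis, aimed at movement ecologists working with collar data in
projected (planar, meters) coordinates.

## What it implements

**Movement behavior.** Bursts of 15-min fixes lasting at least 24 h are
converted to step lengths `L_t` (m) and turning angles `φ_t ∈ (−π, π]`,
and modeled with a K-state hidden Markov model: states follow a Markov
chain with transition matrix Γ started from its stationary distribution δ
(δΓ = δ), and each state k emits

    L_t ~ z_k·1[L = 0] + (1 − z_k)·Gamma(mean μ_k, SD σ_k)
    φ_t ~ vonMises(m_k, κ_k)

(zero-inflated gamma steps, von Mises angles). The likelihood is maximized
by multi-start quasi-Newton optimization over a grid of starting values;
states are decoded with the Viterbi algorithm and forward-backward
smoothing. Fitted models are assessed by the three criteria used in this
field: biological plausibility of the state parameters, a
predictive-power index (mean maximum posterior probability; ≥ 0.90 is
strongly predictive), and AIC.

**Space use.** Fixes subsampled to one per 7.25 h feed two home-range
estimators at the 95% (home range) and 50% (core) isopleths: percent
minimum convex polygons (MCP, overall extent) and the adaptive local
convex hull (a-LoCoH, useable space) with the sphere-of-influence `a` set
to the maximum pairwise distance between locations. Their relative
difference is the home-range complexity index

    C = (MCP − LoCoH) / MCP ∈ [0, 1)

(0 = identical estimates, → 1 as the useable space fragments), reported
together with the number of noncontiguous isopleth polygons. Home ranges
overlapping > 90% of the smaller range are deduplicated (same social
group), and each home range is classified by mean surface imperviousness
inside its 95% isopleth: natural fragment (< 20%), suburban (20–50%),
highly urbanized (> 50%).

**Telemetry cleaning.** Fixes implicated in movement speeds > 50 km/h
(impossible for the species) are removed by an iterative out-and-back
spike test; speeds > 10 km/h flag fixes for review without removing them.

**Synthetic data.** A generative simulator (HMM-driven tracks with known
states, territorial anchoring, fix schedules with dropout, teleportation
spikes, imperviousness rasters) provides ground truth for every stage, so
the estimators are validated by parameter recovery and brute-force
oracles rather than by unreleased field data.

## Worked example

Simulate a 2-state track at field-realistic parameters, refit, and decode:

```r
library(urbanmove)

cfg <- sim_config(
  n_states = 2, mu = c(7.6, 319), sigma = c(7.2, 256),
  zmass = c(0.01, 0.01), angle_mean = c(pi, 0), kappa = c(0.5, 1.5),
  Gamma = persistent_gamma(c(0.58, 0.42), 0.8),
  n_steps = 5001, seed = 71)
track <- simulate_hmm_track(cfg)
series <- steps_and_angles(track$fixes)
fit <- fit_hmm(series, K = 2)
fit
#> 2-state movement model fit: logL = -32385.45, AIC = 64794.91, p = 12
#> predictive power 0.993 (strong); plausible: TRUE
#> 2-state movement model
#>      mu_m sigma_m zero_mass angle_mean  kappa
#> 1   7.521   7.101  0.008470  -3.136086 0.5511
#> 2 320.266 255.470  0.009729   0.002039 1.5097
#> transition matrix:
#>        [,1]   [,2]
#> [1,] 0.9153 0.0847
#> [2,] 0.1172 0.8828
#> stationary distribution: 0.5805 0.4195
```

The fitted state means (7.5 m encamped, 320 m moving) recover the
generating values (7.6, 319) within a few percent, as do the angular
parameters (encamped turns concentrated near ±π, moving near 0) and the
stationary time budget (0.58/0.42). Decoding labels each step:

```r
decoded <- decode(series, fit$params)
time_budget(decoded, K = 2, labels = state_labels(fit$params))$proportions
#>  encamped    moving
#> 0.5814837 0.4185163
```

The full pipeline (clean → home ranges → classify → fit/assess → decode →
summarize) runs on the packaged synthetic three-landscape study:

```r
demo <- demo_study(seed = 1)
report <- run_pipeline(demo$tracks, demo$raster, demo_pipeline_config(1))
write_report(report, "report")
```

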