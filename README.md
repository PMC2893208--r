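# sleepbouts

Sleep-stage **bout-duration dynamics** from epoch-coded hypnograms: how long
do runs of wake after sleep onset (WASO), NREM and REM sleep persist before
the next stage transition, and what survival law governs them?

Routine polysomnographic summaries (stage percentages, sleep efficiency)
can look normal while sleep is badly fragmented. A more informative view
treats the duration of each stage bout — a maximal run of identical 30-s
epochs — as a random dwell time and asks what distribution it follows.
`sleepbouts` implements that analysis for researchers working with scored
hypnograms (e.g. SHHS-style per-epoch stage files) or with simulated sleep
architecture:

- run-length **bout extraction** with WASO definition (wake bouts at or
  after sleep onset) and right-censoring of the final bout;
- pooled, one-epoch-binned relative-frequency **histograms** normalized to
  the maximal bin;
- **multi-exponential fitting**: unweighted least squares of
  `Y(X) = Σᵢ Y₀ᵢ·e^(−kᵢX)` (plateau fixed at 0, kᵢ > 0, 1–4 components,
  bounded Levenberg–Marquardt with multi-start) with sequential nested
  selection by the extra sum-of-squares F-test
  `F = ((SS₁−SS₂)/(df₁−df₂))/(SS₂/df₂)` and
  `AICc = N·ln(SS/N) + 2K + 2K(K+1)/(N−K−1)`, plus an identifiability
  (parameter-dependency) guard against redundant components;
- derived summaries: per-component time constants `τᵢ = 1/kᵢ` with 95% CIs,
  relative contributions `100·Y₀ᵢ/ΣY₀`, and the Y₀-weighted mean τ;
- **power-law** fitting `Y = A·X^B` on the linear scale and non-nested
  comparison (AICc and raw SS verdicts, reported separately);
- three **normality tests** for duration samples (D'Agostino–Pearson
  omnibus, Shapiro–Wilk, Lilliefors-corrected Kolmogorov–Smirnov);
- a **semi-Markov hypnogram simulator** whose stage dwell times follow
  exponential mixtures, used for the under-sampling and power-law-mimicry
  experiments and parameterized by published control/mild-OSA/severe-OSA
  fit tables (`osa_cohort_params()`).

## Worked example

Draw 100,000 REM-like bouts from the published control-group two-component
mixture (τ = 3.8 and 19.0 epochs; Y₀ contributions 40.5%/59.5%, converted
internally to per-bout event probabilities), rebuild the histogram, and let
sequential selection find the model:

```r
library(sleepbouts)
bouts <- draw_mixture_bouts(cohort_mixture("control", "REM"), 1e5,
                            seed = 601, quantize = TRUE)
hist <- build_histogram(bout_set("REM", bouts))
sel <- select_model(hist)
print(sel)
#> <model_selection> selected 2 component(s), stop: no_convergence
#>   simpler richer        F             p delta_aicc preferred
#> 1       1      2 3584.387 4.524936e-181  -840.0715         2
fit <- sel$fits[[sel$selected]]
print(fit)
#> <multiexp_fit> 2 component(s), r2 = 0.9996, SS = 0.001827
#>   tau = 3.38 epochs  (41.9% contribution)
#>   tau = 18.7 epochs  (58.1% contribution)
weighted_tau(fit)
#> 12.3 epochs
```

Selection adds a second exponential (the F-test against the
mono-exponential is overwhelming), then stops: the three-component fit is
refused because its parameters are no longer identifiable. The recovered
time constants sit inside the published 95% CIs (fast 2.8–5.8, slow
17.4–20.9 epochs) and the Y₀-weighted τ of ≈ 12.3 epochs is the
single-number summary comparable to a forced mono-exponential fit.

## Analysis scripts

The numbered drivers under `analysis/` rerun the full study on simulated
cohorts and write their tables under `results/`:

| script | what it shows |
| --- | --- |
| `01_cohort_fits.R` | control/mild/severe cohorts (374/496/338 subjects): 3 exponentials for WASO and NREM, 2 for REM; weighted τ shrinks with OSA severity while mono-exponential r² stays ≥ 0.95 |
| `02_undersampling.R` | ~65% of 10-event exponential samples pass normality testing, ~20% at 30 events, none past ~75 — single nights under-sample the dynamics |
| `03_powerlaw_mimicry.R` | a known 3-exponential mixture (τ = 1, 5, 25) looks linear on log-log axes; model comparison resolves it at n = 10,000 but is unstable at n = 100 |
| `04_subsample_stability.R` | 30-subject subsets lose the rare slow components; single-subject fits fail outright |

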