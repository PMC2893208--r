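---
title: "Modelling sleep-stage bout-duration dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sleep-stage bout-duration dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A scored hypnogram is a sequence of 30-s epochs, each labelled wake (W),
NREM (sub-stages N1–N4, or a single merged N) or REM (R). A *bout* is a
maximal run of identical labels; its length in epochs is a dwell time. If
leaving a stage were governed by a single constant hazard, bout durations
would be exponential; the package's working model is a *mixture* of such
processes. The pooled bout-duration histogram is fitted with

$$Y(X) = \sum_{i=1}^{m} Y_{0i}\, e^{-k_i X}, \qquad m \in \{1,\dots,4\},$$

where $X$ is duration in epochs, $k_i > 0$ are decay rate constants
($\tau_i = 1/k_i$), and the plateau is fixed at zero (a bout always ends
eventually). The $Y_{0i}$ intercepts are reported as *relative
contributions* $100\,Y_{0i}/\sum_j Y_{0j}$. Two caveats are built into the
interpretation and into `y0_contribs_to_event_probs()`: a component's
contribution is neither its share of events (which scales as
$Y_{0i}\tau_i$) nor its area under the curve. The competing heavy-tailed
alternative is the power law $Y = A\,X^{B}$, fitted on the linear scale —
not by regressing log–log coordinates — because least squares on logs
re-weights the data.

Fitting targets the histogram, not the raw durations: counts per one-epoch
bin, divided by the total, then divided by the maximal relative frequency
so the tallest bin has height 1. Zero-count bins are retained out to the
longest observed bout (dropping them would silently change the residual
degrees of freedom); the abscissa of bin $j$ is the integer $j$. This
binned-least-squares route mirrors standard curve-fitting practice for
these data; maximum-likelihood mixture fitting of unbinned durations is a
different estimator and deliberately out of scope.

## Bout extraction rules

* **Sleep onset** is the first epoch scored as any non-wake stage; wake
  bouts beginning at or after onset count as WASO. The leading wake run
  (sleep latency) is never a WASO bout.
* **Right-censoring**: the final bout of a recording is truncated by the
  end of monitoring, so its true duration is unobserved. The default
  policy (`drop_final`) excludes it from bout sets; `keep_final` is
  available because pooled-histogram analyses are often insensitive to one
  bout per record.
* Epoch indices are 0-based; durations are epoch counts.

## Numerical choices in the fitting

* Optimizer: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
  residuals, with $k_i \in (10^{-8}, 50)$ and $Y_{0i} \ge 0$. Positivity is
  enforced by the bounds.
* Multi-start: $\tau$ guesses log-spaced over $[0.5, X_{\max}]$, six
  overlapping windows, amplitudes split equally; the best start by residual
  SS wins. Sums of exponentials have a rugged SS surface, and a single
  start frequently lands in a local minimum.
* Tolerances `ftol = ptol = 1e-15` with an iteration cap of 3000 exposed as
  `max_iterations` (applied per start up to the optimizer's internal
  1024-iteration limit); a fit that exhausts iterations is flagged
  `converged = FALSE`.
* No residual weighting. With histograms spanning three orders of
  magnitude, $Y$-value weighting makes these fits unstable, and the
  unweighted convention is what the reference results use.
* 95% CIs are asymptotic, from the parameter covariance at the solution;
  a singular covariance flags the CIs unavailable rather than inventing
  them.

### Identifiability guard

Sequential selection compares 1-vs-2, 2-vs-3, 3-vs-4 components with the
extra sum-of-squares F-test (richer model accepted when $p < \alpha$,
default 0.05), recording AICc differences alongside; on disagreement the
F-test governs and a message is logged. Selection stops at the first
non-significant comparison, at a non-convergent fit, or at the component
cap of 4.

One further rule is essential on large simulated samples. The unweighted
F-test assumes homoscedastic residuals, but histogram noise is
multinomial: the tallest bins carry most of the absolute counting noise
while hundreds of near-empty tail bins pin the residual variance near
zero. An extra, redundant exponential can then "significantly" absorb the
tallest bin's noise. The package therefore computes, at every solution,
the maximum Prism-style parameter *dependency* $1 - 1/\mathrm{VIF}$ from
the Jacobian correlation matrix, and `select_model()` refuses a richer fit
whose dependency reaches 0.999, treating it as a failure to converge to an
acceptable model. The threshold sits in a wide empirical gap: in this
package's simulations, correctly-specified 2–3 component fits show
dependencies up to about 0.997, while redundant extra components sit at
0.9995–1. Without the guard, roughly a third of $10^5$-bout
three-component datasets would spuriously select four components; with it,
a fourth exponential never wins, and genuine components are never
rejected in the regimes exercised by the tests.

### AICc convention

$\mathrm{AICc} = N\ln(SS/N) + 2K + 2K(K+1)/(N-K-1)$ with $N$ the number of
fitted bins and $K$ the number of fitted parameters (2 per exponential
component; 2 for the power law). The non-nested power-law comparison uses
AICc as the primary verdict — an F-test is invalid there — and reports the
raw SS verdict separately because the two can disagree, which is itself a
finding worth surfacing.

## Normality testing

`normality_tests()` bundles the three classical tests used for duration
samples:

* **D'Agostino–Pearson omnibus** $K^2 = Z_1^2 + Z_2^2$, implemented from
  the 1990 transformed-moment formulas (valid from $n = 8$) and verified
  against an independent reference implementation;
* **Shapiro–Wilk** via `stats::shapiro.test`, whose p-value approximation
  stops at $n = 5000$; larger samples are tested on their first 5000
  values, a valid i.i.d. subsample for exchangeable input;
* **Kolmogorov–Smirnov with the Lilliefors correction**
  (`nortest::lillie.test`), since naive KS with estimated mean/SD is
  anticonservative.

The under-sampling experiment draws *continuous* exponential variates (no
epoch quantization), matching random-variate simulation practice; pass
rates are scale-free in $\tau$, and the experiment defaults to the omnibus
test at $\alpha = 0.05$.

## The semi-Markov generator

Because the cohort data behind the reference tables are not
redistributable, `simulate_hypnogram()` stands in for them. Each subject
gets a leading wake run (exponential, mean 45 epochs ≈ 22.5 min, matching
typical control sleep latency) and then alternates stages: W→N always,
N→{R: 0.3, W: 0.7}, R→{N: 0.5, W: 0.5}, with stage dwell times drawn from
per-stage exponential mixtures (`osa_cohort_params()` supplies the
published control/mild/severe parameterizations) and quantized by ceiling
to a minimum of one epoch. Recordings are truncated at 840 epochs (7 h).

Chosen once and fixed: the transition probabilities make REM ≈ 20% of
sleep time under the control mixtures, matching typical control
architecture; the latency and recording length follow the same source.
Known departures from real data, and hence limits on what passing tests
demonstrate:

* Simulated sleep efficiency (~87%) exceeds the ~81% of real controls: the
  pooled WASO mixture's mean bout (~2.1 epochs) is too short to produce
  19% wake time under any no-self-transition rule. The generator
  reproduces pooled *bout-duration distributions*, not time-in-stage
  budgets.
* Dwell quantization by ceiling slightly inflates the shortest bin
  relative to a continuous mixture.
* No circadian or homeostatic modulation, no inter-subject heterogeneity
  (every simulated subject shares one parameter set), no arousal
  micro-structure. Parameter-recovery results on this generator therefore
  show the estimator works when the model is true; they cannot show the
  model is true of real sleep.

## Problem sizes

The test suite and the acceptance script use $10^5$ bouts for parameter
recovery and selection checks (recovered slow time constants fall within
the published 95% CIs), 1,000 trials for normality pass-rates, 20 seeds
for the small-sample ambiguity scan, and cohorts of up to 374 simulated
subjects in the analysis drivers — the full-size control cohort is cheap
to simulate, while unit tests use 10–120 subjects to stay quick.

## Known limitations

* Binned least squares is less efficient than unbinned maximum likelihood
  and inherits the heteroscedasticity discussed above; the dependency
  guard mitigates, but does not remove, the resulting anticonservatism of
  the nested F-test on very clean data.
* The final-bout censoring policy is a convention, not an estimator;
  survival-analysis treatments of censoring are out of scope.
* Power-law comparison is least-squares on the histogram; tail-focused
  maximum-likelihood power-law machinery (x_min estimation) is a different
  question and not implemented.
* With fewer than roughly $10^3$ pooled bouts per stage, selection
  outcomes are unstable by design of the problem, not of the code — that
  instability is one of the package's own results.
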