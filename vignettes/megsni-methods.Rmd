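---
title: "Synchronous neural interactions: model, estimation and design choices"
author: "megsni"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronous neural interactions: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistic, the estimation decisions behind each stage, what the
synthetic cohort generator does and does not emulate, and the known
limitations. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from external data.

## 1. The SNI statistic

The object of interest is the *synchronous neural interaction* between a
pair of MEG sensors: the Fisher z-transformed zero-lag partial
cross-correlation of their prewhitened time series,

$$\mathrm{SNI}_{ij} \;=\; z^0_{ij} \;=\; \operatorname{atanh}\!\big(\mathrm{PCC}^0_{ij}\big),$$

where $\mathrm{PCC}^0_{ij}$ is the correlation of sensors $i$ and $j$ at
simultaneous samples after (a) removing each sensor's own temporal
structure and (b) partialling out all remaining sensors. The motivation is
that raw MEG sensor series are heavily autocorrelated; two sensors can
correlate strongly at lag zero merely because both are smooth. Prewhitening
reduces each series to its innovations, so that surviving zero-lag
correlation reflects instantaneous coupling, and the partialization
removes network-mediated (indirect) correlation. The atanh transform
stabilises the variance of the correlation scale.

Assumptions worth keeping in view:

* each sensor's series is adequately described by a univariate
  ARIMA model over the recording (stationarity after differencing);
* coupling is instantaneous and linear — lagged or nonlinear dependence is
  invisible to this statistic;
* the partial correlation conditions on *all* remaining sensors, which
  requires the innovation correlation matrix to be well conditioned
  (hence the ridge parameter below when the sample size does not dwarf the
  sensor count).

## 2. Stage-by-stage estimation decisions

### Prewhitening (`prewhiten`, `prewhiten_config`)

* **Order** `(p, d, q)`, default **(50, 1, 3)** — a high AR order with one
  difference, appropriate for ~61,000-sample recordings at ~1 kHz.
  Desk-scale analyses (thousands of samples) use smaller orders such as
  (10, 1, 3); the acceptance benchmark does exactly that. The fit must
  satisfy $m > 10\max(p, q)$ samples after differencing.
* **Estimation method**, default **`"hr"`** (Hannan–Rissanen two-stage
  least squares): a long autoregression (Yule–Walker) supplies lagged
  residual regressors, then the ARMA coefficients come from a single OLS of
  the differenced series on its own lags and the lagged residuals, and the
  innovations from the corresponding recursive filter. The pipeline fits
  *hundreds to thousands* of high-order models per cohort, and only the
  innovations — not the coefficients — are consumed downstream, so a
  consistent closed-form estimator is the right default. On this package's
  simulated data the resulting innovations pass a $5/\sqrt{m}$
  autocorrelation bound at lags 1–5 and shrink mean |lag-1| autocorrelation
  more than five-fold (both asserted in the test suite).
  `"css"` and `"css-ml"` call `stats::arima` for conditional-sum-of-squares
  and CSS-plus-likelihood estimation; they are one to two orders of
  magnitude slower at high orders and serve as a cross-check (the test
  suite verifies that both whiten an AR(1) with coefficient 0.9).
* **Fallback order**, default (10, 1, 3): sensors whose primary fit fails
  are refit at the fallback order and flagged in the diagnostics; an error
  is raised only if both fail.
* **Alignment**: residuals are truncated uniformly across sensors by
  $d + \max(p+q)$ initial samples, so every zero-lag correlation uses
  identical time indices (the first residuals of the recursive filter sit
  on a zero-initialised transient).

### Partial correlations (`partial_corr_matrix`)

Computed from the precision matrix, $\mathrm{PCC}_{ij} = -\Omega_{ij} /
\sqrt{\Omega_{ii}\Omega_{jj}}$, which equals the correlation of the
residuals from regressing $i$ and $j$ on all remaining sensors (the test
suite checks this equivalence to $10^{-8}$ on random instances). The
**ridge** parameter (default $10^{-6}$, in correlation units, added to the
diagonal before inversion) exists for desk-scale settings where $m \gg n$
may fail; with `ridge = 0` a singular matrix produces an error reporting
the condition number. The matrix diagonal is masked (`NA`) throughout —
self-correlation is undefined for this statistic, and masking rather than
zeroing prevents it from ever entering the min/max features.

### Fisher transform (`fisher_z_matrix`)

Inputs are clipped to $|r| \le 1 - 10^{-12}$ before `atanh`, so the SNI
matrix is finite everywhere and `tanh` recovers the partial correlation to
$10^{-9}$.

### Covariate adjustment (`fit_adjustment`, `apply_adjustment`)

Per sensor pair, OLS of the SNI value on centred age (slope per year) and
an additive gender indicator. Design choices, where the functional form
was genuinely open:

* fitted on the **combined reference sample** (control + case), because
  that is the sample the discriminant is built on; held-out groups are
  adjusted with the reference coefficients;
* **linear in age, additive in gender, no interactions** — the minimal
  model for "age- and gender-adjusted";
* the per-pair **intercept is retained**, so adjusted values stay on the
  SNI scale; a subject at the training mean age with reference gender is
  returned unchanged;
* a single-gender training sample drops the gender term with a warning;
  constant age yields zero slopes.

### Features and stepwise LDA (`extract_minmax_features`, `stepwise_select`, `fit_lda`)

Each sensor contributes the minimum and maximum of its $n-1$ SNI values
(all minima in sensor order, then all maxima; $2n$ features, 496 at
$n=248$). Selection is classical Wilks'-lambda stepwise discriminant
analysis: at each step, in-model features whose partial $F$ falls below
**F-to-remove (2.71)** are removed, then the candidate with the largest
partial $F$ enters if it reaches **F-to-enter (3.84)**. These thresholds
are the long-standing defaults of classical stepwise discriminant
software and are fully configurable. Ties break toward the lowest feature
index, and a removal immediately after entry is impossible because the
removal $F$ of a just-entered feature equals its entry $F$. Log-scale
determinants are not needed at the package's problem sizes; a candidate
whose lambda underflows ($<10^{-14}$) is treated as infinitely
informative.

The discriminant itself is the two-class closed form: direction
$\Sigma^{-1}(\mu_2 - \mu_1)$ under the pooled within-group covariance,
equal priors, constant placing the boundary midway between centroids. The
test suite verifies both the closed form ($10^{-6}$) and proportionality
to `MASS::lda`'s direction. A singular pooled covariance is ridge-loaded
by $10^{-8}\,\mathrm{tr}(\Sigma)/p$ and flagged.

### Distances and assignment (`score_case`, `normalize_d2`)

Mahalanobis $D^2$ is computed **in the selected-feature space under the
pooled covariance**, not along the 1-D discriminant axis: multi-feature
models produce $D^2$ values far larger than 1, and the two views are
linked by $D^2_1 - D^2_2 = 2 \cdot \mathrm{score}$, so the score's sign,
the larger posterior and the smaller $D^2$ always agree (asserted for
every scored case). Posteriors are equal-prior Gaussian,
$p_g \propto \exp(-D^2_g/2)$, computed with a max-shift to avoid
underflow. Normalized distances divide each $D^2$ by the sum of the two,
giving complementary values in $[0, 1]$. Ties ($D^2$ exactly equal)
assign the reference (control) group, for determinism.

### Cross-validation (`loocv`)

Selection is re-run **inside every fold**; reporting the resubstitution
accuracy of a single selection would be optimistically biased. Folds whose
selection is empty are classified by the prior (tie → control) and
flagged. Degenerate training sets at minimal $n$ (a singleton group) are
treated the same way.

### Network thresholding (`threshold_network`)

Over the connections among the feature-sensors, the configured percentile
(default 25, linear interpolation, `quantile` type 7) of the $|SNI|$
distribution is the threshold; retained edges are **strictly** above it,
and connected components are reported (breadth-first search; isolated
sensors are labelled 0). Percentile 0 retains every connection.

### Severity statistics (`severity_association`, `group_ttest`)

Pearson association between severity scores and the distance from the
*control* centroid, with incomplete pairs dropped pairwise and the
remaining $n$ reported. Group comparison defaults to **Welch's**
unequal-variance $t$ (group sizes and variances in this design are
typically unbalanced); the pooled variant sits behind a flag and the
output labels which was used. SEM is $s/\sqrt{n}$, undefined (`NA`) for
singleton strata.

## 3. What the synthetic cohort emulates — and what it does not

`generate_cohort()` stands in for a clinical MEG study whose raw data
cannot be distributed. It emulates, at configurable scale:

* **Acquisition shape**: 248 sensors × 1017.25 Hz × 60 s at full scale
  (defaults of `cohort_config()`), with `desk_config()` giving the
  24-sensor, 4,000-sample scale used in tests and the acceptance script;
* **Group structure**: control, case, subthreshold (planted factor 0.8),
  partial recovery (a 75%/25% on/off mixture) and full recovery (50%/50%),
  reflecting mixed recovery outcomes; full-scale default group sizes are
  87/88/13/19/12;
* **Autocorrelated sensors**: latent AR(1) sources with persistence 0.95,
  so prewhitening is non-trivial (generated sensors have lag-1
  autocorrelation > 0.3 by construction). The acquisition band-filter is
  approximated by the AR spectrum — prewhitening removes the spectral
  shape regardless, so no digital filter is simulated;
* **Planted connectivity**: effects live in the partial-correlation
  domain. The precision matrix gets off-diagonal entries
  $-\tanh(z_e)$ on a randomly drawn, sensor-disjoint matching of effect
  edges, so the planted SNI values are *exact* partial correlations of the
  innovation process. Per subject,
  $z_e = \text{effect\_shift}\times\text{magnitude} +
  \mathcal{N}(0, \text{edge\_noise\_sd}^2)$. Nuisance edges (disjoint from
  effect edges) carry a linear age trend (0.005 z/yr), an additive female
  offset (0.2 z) and the same between-subject noise. When nuisance edges
  chain onto effect sensors and threaten positive definiteness, only the
  nuisance entries are shrunk (bisection on the smallest eigenvalue) — the
  planted effect partials are never distorted; an irreparably indefinite
  configuration errors, naming the offending eigenvalue;
* **Sensor noise**: independent white noise (SD 0.1 in innovation units)
  on top of the mixed sources. This attenuates recovered SNI by roughly
  10% at the desk scale — the test suite asserts that the case–control
  difference on planted edges recovers the planted 1.0 z-shift within
  0.15;
* **Severity**: score = 12 + 38 × planted magnitude + $\mathcal{N}(0,
  8^2)$, clipped to the 0–80 instrument range; controls carry no score.
  The parameters place typical full-effect cases around 50 and off-effect
  subjects near the low teens, so the positive severity–distance
  association emerges qualitatively;
* **Reproducibility**: one master seed; per-subject streams are derived by
  a counter-based split keyed on (group, index), so subject *k* of a group
  is bit-identical regardless of the other groups' sizes.

Not emulated: biophysical forward modelling (sensor geometry, source
anatomy), task structure, artifacts beyond what the amplitude of the AR
sources produces, nonstationarity within a recording, and any spatial
correlation structure among noise sources. Consequently, passing tests
demonstrate that the *pipeline* recovers what it is supposed to recover
from data with the assumed covariance structure — they do not certify
performance on real recordings, where artifact handling and model mis-match
dominate.

Generator parameters that the study design does not pin down (age range
30–70, the nuisance-edge count 8, the severity model, the gender
proportion 0.15, sensor noise 0.1) were chosen once as plausible for a
veteran cohort and are not tuned.

## 4. Problem sizes used by the tests

The validation suite exercises the full pipeline at the 24-sensor,
4,000-sample, 30+30-subject scale (one shared cohort, seed 7, ARIMA
(10, 1, 3)) and the property suites at 6–16 sensors with 300–2,000
samples: 20-seed null-calibration and severity-recovery batteries,
100-instance brute-force partial-correlation checks, and 10–20-instance
closed-form LDA checks. These sizes keep the whole suite under about a
minute while leaving every statistical property testable; the full
248-sensor scale changes only constant factors (the 50-lag ARIMA fit per
sensor dominates).

## 5. Known limitations

* The stepwise procedure selects a *minimal sufficient* feature set: once
  group separation is essentially complete the partial $F$ of further
  informative features collapses, so with strong planted effects only a
  subset of effect edges is represented among the selected sensors
  (selection precision, by contrast, is perfect in the tested regimes —
  noise sensors do not enter before informative ones). Interpreting the
  selected-feature network as *the* set of affected connections is
  therefore an over-read; it is one sufficient set.
* With $F$-thresholds fixed, stepwise outcomes depend on sample size;
  near-threshold features enter or stay out by chance.
* Classification is strictly two-class; held-out groups are assigned to
  one of the two reference centroids, never to a third category.
* The Hannan–Rissanen default trades a small amount of estimation
  efficiency for a large speed factor; for publication-grade single-subject
  modelling of coefficient values, use `"css-ml"`.
* Equal priors are assumed throughout; with strongly unbalanced reference
  groups the posterior (but not the $D^2$ ranking) would shift.
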