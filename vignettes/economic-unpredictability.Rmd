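---
title: "Quantifying economic unpredictability and its effect on early self-regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying economic unpredictability and its effect on early self-regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hardshipdyn)
```

## The problem this package addresses

Families' economic hardship is usually summarized by a single level — income,
poverty status, or a mean hardship score. But hardship *fluctuates*, and the
temporal texture of those fluctuations (how often conditions shift, how
abruptly, how irregularly) may matter for children's developing
self-regulation independently of how severe hardship is on average.
`hardshipdyn` implements an environmental-statistics workflow for
densely-sampled subjective hardship reports:

1. **Ingest**: six binary "hard to pay for" items (food, housing, utilities,
   healthcare, childcare, socioemotional well-being) are summed per response
   (0–6), averaged within calendar month, and shifted by +1 to a 1–7 scale so
   ratio statistics are defined. Families with at least 15 observed months
   enter the analysis.
2. **Unpredictability indices**, per family: the coefficient of variation
   (CV = s/x̄), penalized changepoint counts in mean and in variance (PELT),
   and the noise color — the spectral exponent β of what remains after
   removing trend, annual seasonality, and a drifting variance scale.
3. **Dimension reduction**: the four standardized indices are
   eigendecomposed; a composite weights the retained component scores by
   their proportions of variance explained.
4. **Exposure effects**: severity (time-mean hardship) and the composite are
   each related to a one-time child self-regulation outcome using balancing
   weights for continuous exposures (15 dummy-coded confounders), then
   weighted least squares with HC3 robust errors.

Because the motivating cohort's data are restricted, the package ships a
synthetic cohort generator with a complete planted ground truth; every stage
is validated against plantings, closed forms, or independent oracles.

## The statistics, precisely

### Changepoints

For a series $y_{1:n}$, a segmentation with changepoints
$\tau_1 < \dots < \tau_m$ minimizes
$\sum_{s} \mathcal{C}(y_{\tau_{s-1}+1:\tau_s}) + m\,\lambda$.

* **Mean kind**: $\mathcal{C}$ is the segment residual sum of squares scaled
  by a global noise variance $\hat\sigma^2$ estimated robustly from first
  differences (squared MAD of $\Delta y$, halved). A level shift barely
  moves a difference-based scale estimate, so the changepoints themselves do
  not inflate $\hat\sigma^2$ and mask one another. Discrete 1–7 series often
  have a majority of zero differences, which zeroes the MAD; the estimator
  then falls back to half the difference variance.
* **Variance kind**: $\mathcal{C} = n_s(\log\hat\sigma^2_s + 1)$ with
  deviations taken about the *global* series mean, minimum segment length 2
  (a variance needs two points; the mean kind allows singletons).
* **Penalty**: $\lambda = 3\log n$ per changepoint by default (the stricter
  convention for short noisy series), with $2\log n$ ("bic") available.
  On 30-point white noise the default yields zero changepoints in roughly
  95% of series while a shift of four noise standard deviations is localized
  to within one position in over 99%.

Two searches are provided: `segment_optimal()`, an exhaustive
optimal-partitioning dynamic program, and `detect_changepoints()` (PELT),
which prunes candidate segment starts but is exact — the suite verifies
identical changepoint sets and costs across hundreds of random series. Ties
in the argmin are broken toward fewer changepoints, then earlier boundaries,
identically in both searches, so results are deterministic.

### Noise color

`detrend_for_noise()` prepares a regular monthly grid: internal gaps are
linearly interpolated (flagged when more than 20% of the grid is
interpolated), an OLS fit removes intercept, linear trend and one annual
harmonic pair (sin/cos of calendar month — series as short as 15 points
cannot support month dummies), and residuals are divided by a linear fit to
$|r_t|$ floored at one-tenth of the median absolute residual, equalizing a
drifting variance. `noise_color()` regresses log periodogram power on log
frequency over the Fourier frequencies $j/n$, $j = 1..\lfloor(n-1)/2\rfloor$;
$\hat\beta$ is the negated slope: 0 is white (maximally random), 2 is red
(slow, predictable), negative is blue (fast but regular).

The instrument's wording fixes only the *direction* of the unpredictability
transform (higher = more unpredictable). The default here is
$-|\hat\beta|$: the unique simple monotone map that treats white noise as
the most unpredictable and both predictable extremes symmetrically. Plain
$-\hat\beta$ and $2-\hat\beta$ are available (`noise_transform = "neg"`,
`"shift"`) for sensitivity analyses. A perfectly flat series (possible in
the synthetic cohort when a family's hardship is clipped at the floor every
month) has no stochastic component; it is scored at the fully-predictable
red limit ($\beta = 2$) rather than erroring.

At cohort lengths (15–36 months) $\hat\beta$ is biased toward zero and
noisy; the suite documents this rather than hiding it, requiring only that
the $\beta = 0$ and $\beta = 2$ sampling distributions separate cleanly at
n = 36 while demanding tight calibration at n = 1024.

### PCA composite

Indices are z-scored (sample sd) and the correlation matrix
eigendecomposed — exactly what "standardize, then take eigenvectors of the
covariance" implies. Components are sorted by eigenvalue and sign-fixed so
the loading on the variance-changepoint index is non-negative; two
components are retained by default. The composite is the weighted average
of retained scores with variance-explained proportions as weights,
normalized to sum to one ("weighted average" implies normalization; the
unnormalized variant is a flag). Scores use unit-norm eigenvectors;
eigenvalue-scaled loadings would rescale each score by a positive constant,
which normalized weighting absorbs only partially — a documented, fixed
choice. No rotation is applied.

### Balancing weights and effect models

Both balancing methods target the same estimand: a pseudo-population in
which the continuous exposure is uncorrelated with all 15 confounders.

* `gps_weights()`: stabilized density-ratio weights from a normal linear
  exposure model — marginal density over conditional density, normalized to
  mean 1. Correct in expectation, but leaves finite-sample imbalance of
  order $1/\sqrt{\mathrm{ESS}}$ per confounder.
* `entropy_balance_weights()`: minimum Kullback–Leibler divergence from
  uniform subject to *exact* moment constraints — weighted confounder and
  exposure means equal their unweighted means, weighted
  exposure–confounder covariances exactly zero. Solved via the convex dual
  (weights are log-linear in the constraint functions) with damped Newton
  and backtracking; convergence requires every standardized violation below
  1e-8. With a discrete, low-cardinality exposure and rare dummy
  confounders the constraint system can be near-infeasible at n = 125; a
  failed method is reported with the offending constraint and the search
  proceeds with the remaining candidates.

`select_method()` picks the candidate balancing the most confounders at the
|weighted r| ≤ 0.10 convention, breaking ties by smaller maximum |r|, then
larger effective sample size $(\sum w)^2 / \sum w^2$.

Effect models are weighted least squares of the outcome on one exposure and
an intercept — adjustment lives in the weights, not in covariates — with
HC3 sandwich errors (weights are estimated, so a model-based variance would
be too optimistic) and normal-approximation intervals. Standardized slopes
use unweighted sample sds of exposure and outcome so differently-scaled
exposures compare. Full weight-estimation uncertainty propagation
(bootstrap) is deliberately out of scope; under the planted null the
realized test size of the default estimator is about 0.06 at n = 125.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults define the study conditions: 321 families, a
36-month window, 15–36 observed months per family (per-family missingness
rates drawn Uniform(0, 2·`missing_rate`), capped for eligibility-guaranteed
families so the retry loop can succeed), six-item binary responses whose
sums equal the planted monthly score exactly, piecewise-constant mean paths
(Poisson changepoint counts, Gaussian jumps), piecewise variance scales, an
annual harmonic (amplitude 0.25 hardship units), and spectrally synthesized
1/f^β noise with deterministic amplitudes and random phases.

A single SES latent drives everything that should be confounded: hardship
level (coupling 0.6, chosen so latent exposure–confounder correlations span
the minimal-to-moderate range, up to about 0.36), education, income band,
race/ethnicity, and disability category membership, and — through a
correlated instability latent (link 0.5) — changepoint rates, noise scale,
and noise whiteness. The child outcome is linear in planted severity
(default slope 0.36) and the instability latent (0.21), plus fifteen
dummy-coded confounder effects with conventional SES gradients and Gaussian
noise (sd 0.7); its intercept centers the cohort mean near 0.14. The
outcome is observed for a 125-family subsample, mirroring the two-stage
design. Confounder dummies drop the first declared level — the lowest SES
category — rather than the alphabetical first, so gradients read naturally;
the rule is fixed and documented.

Known gaps between emulation and the motivating data, deliberate and
documented:

* Discretization to the 1–7 grid lifts and compresses severity: the cohort
  realizes mean ≈ 1.83, sd ≈ 0.84 against the instrument's reported
  1.63/1.04. Floor effects make both targets unreachable simultaneously
  under this generative structure.
* Rounding manufactures apparent variance regimes (runs of identical
  values), so variance-changepoint counts on the ordinal scale exceed the
  continuous detector's false-positive rate by an order of magnitude. This
  artifact very likely affects coarse ordinal instruments generally; the
  suite tests the detector's null behaviour on continuous noise separately.
* The measured index intercorrelations, the two-component variance split,
  and the severity–composite correlation are weaker than their printed
  analogues: short discretized series attenuate every index, most severely
  the noise exponent. Passing tests therefore certify the *methods* under
  known structure, not that real hardship data would reproduce any
  particular printed coefficient.
* Missingness is MCAR by default; survey cadence shifts and fraud patterns
  are not modeled.

## Numerical and design choices

* Severity and CV/changepoints use observed months only, in observed order;
  only the spectral stage interpolates (it needs equal spacing). This
  mirrors computing statistics on available monthly scores.
* A response with any missing item is dropped, not prorated — partial sums
  would deflate severity. Dropped counts are reported.
* Eligibility counts observed months, not span length.
* Changepoint cost floors (segment variance, global scale) are 1e-8;
  argmin ties break toward fewer changepoints then earlier boundaries.
* The entropy-balancing dual standardizes all constraint columns before
  optimization for conditioning; weights are invariant to that scaling.
* All randomness flows from the single config seed; identical configs give
  byte-identical artifacts, and `run_report.json` records MD5 checksums of
  every written table.
* Test problem sizes: oracle equivalence runs 200 random series (n ≤ 50);
  recovery and null calibration use 500 planted series; effect recovery 200
  cohort replicates at n = 125 and test size 500 replicates; the end-to-end
  determinism check runs the full 321-family cohort twice. These sizes give
  Monte-Carlo error well inside each asserted margin.

## Limitations

Beyond the emulation gaps above: the noise exponent on 15–36 points is a
coarse measurement (bias toward white documented in the tests); balancing
counts as balanced anything at |weighted r| ≤ 0.10, a convention rather than
a guarantee; and the effect models are deliberately marginal — one exposure
at a time, as the weighting philosophy dictates — so estimates for
correlated exposures (severity and the composite, planted r ≈ 0.5 on the
latent scale) are total, not mutually adjusted, associations.
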