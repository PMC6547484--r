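---
title: "Measuring wealth-related inequity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wealth-related inequity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concindex)
```

## The estimand

Let $h_i \ge 0$ be a health variable (ANC visit count, number of postnatal
reviews, a facility-delivery indicator), $w_i$ normalized sampling weights,
and $r_i$ the weighted fractional rank of individual $i$ in the
living-standards ordering,
$r_i = \sum_{j<i} w_j + w_i/2$. The concentration index is

$$\mathrm{CI} \;=\; \frac{2}{\mu}\sum_i w_i\,h_i\,(r_i-\bar r),
\qquad \mu=\sum_i w_i h_i,$$

twice the weighted covariance between outcome and rank over the mean;
equivalently twice the area between the concentration curve and the line of
equality. CI is positive when the variable is concentrated among the rich,
zero under an equal distribution, and bounded by $\pm 1$. It is invariant
to positive rescaling of $h$, to rescaling of the weights, and to any
strictly monotone transform of the wealth index — only the ordering (and
its ties) matter.

Three estimation routes are provided and are held to agree:

* `ci_covariance()` — the plug-in formula, the package's internal oracle;
* `ci_regression()` — WLS of $2\sigma_r^2 h_i/\mu$ on $r_i$ with weights
  $w_i$, where $\sigma_r^2$ is the weighted rank variance. The slope equals
  the covariance formula *algebraically* (to floating-point error, which the
  property suite bounds at $10^{-10}$), and the conventional slope standard
  error is the CI's standard error;
* `ci_area()` — trapezoid integration of the curve. With untied
  individual-level data this, too, reproduces the covariance formula; with
  quintile grouping it is the five-point tabulation construction, and the
  residual discretization error is the price of grouping.

### Standard errors and their assumptions

The convenient-regression standard error treats records as independent
given rank. Under cluster sampling with cluster-level covariate effects it
is an underestimate; a heteroskedasticity-robust (HC1) option is available
via `robust = TRUE`, but cluster-robust/design-based variance (DHS
jackknife style) is deliberately out of scope. The empirical-size test in
the suite therefore runs on a *self-representing* design (one stratum,
equal weights, outcomes depending on wealth rank only), where the
independence assumption actually holds; under the default clustered
two-stratum design the nominal test would over-reject and the robust flag
is the appropriate choice.

## Covariate standardization

`ci_adjusted()` (and `concindex(..., adjust = ~ ...)`) fits a weighted GLM
of $h$ on wealth terms plus controls, then predicts each record with **its
own wealth terms but every control column frozen at its weighted mean**.
The CI of those predictions is the standardized index: the wealth gradient
net of the controls. This is a partial (direct) standardization of the
wealth–outcome relation; the classical indirect standardization
$h_i-\hat h_i+\bar h$ is available as `mode = "indirect"`.

The standard error comes from a second regression in which the *regressor*
rather than the outcome is transformed: the standardized outcome is
regressed on $RW_i = \mu\,r_i/(2\sigma_r^2)$. Because
$\mathrm{slope} = \mathrm{cov}_w(h,c\,r)/\mathrm{var}_w(c\,r) =
\mathrm{cov}_w(h,r)/(c\,\sigma_r^2)$, the scaling $c=\mu/(2\sigma_r^2)$ is
the unique one making the slope equal $2\,\mathrm{cov}_w(h,r)/\mu$, i.e.
the CI itself; the property suite pins this identity at $10^{-10}$. The
rank variance depends only on the weights, so it is treated as a constant
and the conventional slope standard error is reported.

Three genuinely open choices, and what this package does:

* **How wealth enters the prediction model.** Quintile indicators are the
  default (`wealth_terms = "quintile"`), matching how such models are
  usually tabulated; the continuous score and the fractional rank are
  config options. With rank entry and no controls the standardized index
  reduces to the unadjusted one *exactly*; with quintile entry the
  reduction would hold only up to within-quintile covariance, so the
  no-control case bypasses prediction altogether and uses the raw outcome —
  the only reading under which "no controls" means "no adjustment".
* **Link function.** Identity is the default even for counts — the
  convenient-regression framework is linear, and identity-link predictions
  keep $\mu$ interpretable. Log and logit links are available; their
  predictions are mapped back to the response scale before ranking.
  Identity-link predictions can be negative in pathological designs; they
  are not clipped, and a non-positive standardized mean raises an error
  rather than a silent fix.
* **Degenerate designs.** Rank-deficient design matrices are rejected with
  the collinear columns named, not silently dropped.

## Recoded analysis variables

* ANC visit counts map to `none` / `up_to_four` (1–4) / `more_than_four`
  (5+). Whether *exactly four* belongs in the middle or the upper category
  is ambiguous between a literal "more than four" and the WHO
  "four-or-more" benchmark; the literal reading is the default and
  `four_in_upper = TRUE` gives the WHO split. The concentration analysis
  itself uses the raw count, so this choice affects tabulations only.
* PNC is `complete` only when all four reviews (post-delivery,
  pre-discharge, week after, six weeks) were attended. For concentration
  curves the 0–4 *count* of reviews is used — a sum over quintiles needs a
  quantity, and the count is the natural one — while the binary
  completeness feeds utilization-rate tables.
* Weighted wealth quintiles cut the cumulative normalized weight at 0.2,
  0.4, 0.6, 0.8. A tied block of scores is assigned to the quintile
  containing the midpoint of its cumulative-weight span; the same midpoint
  rule gives tied blocks their shared fractional rank, which makes ranks,
  quintiles and hence every downstream estimate invariant to record order.
  An all-tied input degenerates to a single quintile with a warning.

## What the synthetic generator emulates — and what it does not

`generate_population()` mimics a two-stage cluster-sampled women's survey:
353 enumeration areas by default (41% urban, mirroring a 145/208 split), 85
households listed and 22 sampled per EA, and one eligible woman per sampled
household with probability 0.5, giving roughly 3 800 records per round —
the scale of a national survey's analysis subset. Weights are inverse
selection probabilities of the two stages; the urban stratum is oversampled
relative to a notional frame of 3 000 urban / 7 000 rural EAs, so the
weighted population is ~30% urban while the sample is ~41% urban, a typical
DHS pattern.

The wealth score is standard log-normal with an additive urban shift
(default 1.5); since only ranks matter to the CI, the family is a free
choice and was made for its realistic right skew. Covariate prevalences
default to a West-African profile (~70% no education, ~70% rural weighted,
~80% Muslim, seven five-year age bands). Outcomes follow GLMs in the
centred fractional rank: Poisson ANC counts (log link, baseline mean 4.3),
Bernoulli postnatal-review components (logit, baseline 0.55 per component)
and facility delivery (logit, baseline 0.35), each with a configurable
wealth gradient plus modest education/residence effects. Residence is the
built-in confounder: it shifts both wealth and outcomes, which is what
makes the standardization tests informative. One root seed drives
deterministic per-cluster substreams, so records are bitwise reproducible
and early clusters are unchanged when `n_clusters` grows.

`calibrate_gradient_to_ci()` bisects the gradient of one outcome against
the covariance-formula CI measured on a fixed-seed large sample (the
default tolerance is 0.002 on the CI scale), so populations can be dialed
to a known inequity level and recovery checked on fresh seeds.

What the generator does *not* emulate: asset-index construction by PCA,
non-response, within-cluster outcome correlation beyond shared covariates,
inter-covariate dependence (education is drawn independently of wealth),
and item missingness. Passing tests therefore demonstrate estimator
correctness and calibration under a clean DHS-like design — not robustness
to the messiness of real recode files.

## Inference conventions

* The change in a CI between rounds is tested with
  $z=|CI_a-CI_b|/\sqrt{SE_a^2+SE_b^2}$ against the standard normal,
  two-sided by default.
* The rich–poor odds-ratio equality test works on the **OR scale**, not the
  log scale: published tabulations of this test report OR-scale standard
  errors, and only on that scale do such printed pairs reproduce their
  printed statistics. It is one-sided (upper tail) by default; a log-scale
  variant is provided and documented as generally disagreeing.
* Logistic fits apply sampling weights as frequency-style weights
  normalized to sum to $n$, with the model-based variance; `robust = TRUE`
  gives sandwich variance. Separation is reported as an error naming the
  offending level (coefficients past ±30 or non-convergence), and a
  constant outcome is rejected outright.
* Curve dominance is classified on the union grid of abscissae with linear
  interpolation; ordinate differences below $10^{-9}$ count as coincident.
  Empirical individual-level curves from moderate samples wiggle at the
  tails, so dominance readings are best made on quintile-grouped curves,
  as the end-to-end tests do.

## Problem sizes used by the test suite

Chosen as the package's own validation design: estimator identities on 200
random weighted datasets of up to 500 records; calibration targets
$\{-0.05, 0, +0.10\}$ recovered within $\pm 0.01$ on fresh ~50 000-record
populations (calibration itself on ~22 000); the logistic wealth effect
recovered within 3 standard errors at ~5 000 records; and the
index-difference test's size estimated from 1 000 null replicates of two
~440-record samples, expected in $0.05 \pm 0.02$. The two-round
sign-reversal scenario uses targets $+0.08$ and $-0.02$ at ~4 400 records
per round: reversal magnitudes an order of magnitude smaller are real in
national surveys but need sample sizes far beyond a validation suite to
reach significance, so the scenario preserves the qualitative contrast at
tractable scale.

## Known limitations

No Erreygers/Wagstaff normalization for bounded outcomes (the plain CI of
a binary variable has a mean-dependent feasible range); no decomposition of
the CI into covariate contributions; no design-based (jackknife) variance;
no statistical test of curve dominance — the classification is descriptive.
These are the natural next steps for a package of this kind, and their
absence is a scope decision, not an oversight.
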