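---
title: "Measurement methods behind the dvmsq package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methods behind the dvmsq package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvmsq)
```

## The instrument and its diagnostic algorithm

The Duke-Vanderbilt Misophonia Screening Questionnaire (DVMSQ) is a brief
self-report screen for misophonia, a disorder of decreased sound tolerance in
which specific "trigger" sounds (chewing, tapping, sniffling, ...) evoke
intense anger, irritation, or disgust out of proportion to the stimulus. The
questionnaire opens with a yes/no screening gate; respondents who answer "No"
skip everything else, which produces the zero-inflated score distribution
characteristic of this design. Twenty Likert items follow, twelve on symptom
frequency ("Never" ... "Very often", coded 0-4) and eight on functional
impairment over the past week ("Not at all" ... "An extreme amount", also
0-4).

Seventeen of the twenty items are scored: a total score (0-68), a symptom
score over ten items (0-40), and an impairment score over seven items (0-28).
Items 3 (fear/panic), 11 (perceived excessiveness), and 17 (concentration)
are administered and stored but never scored: fear/panic marks phonophobia
rather than misophonia, and the other two proved redundant with the retained
items during the instrument's structural evaluation.

Caseness is criterion-based rather than cutoff-based. Criteria A-F
operationalize a consensus-style definition: an affirmative screen (A),
intense emotional reactions (B: item 1, 2, or 4 at "Often"+), avoidance or
distressed endurance (C: item 12 at "Sometimes"+, or item 5 or 6 at
"Often"+), loss of self-control (D: item 8 or 7 at "Sometimes"+), a
six-month duration criterion not assessed by the instrument and assumed true
when everything else holds (E), and clinically significant impairment (F: at
least two of the seven scored impairment items at "A moderate amount"+).
Meeting A-F is classified *clinical*; A-D without F is *subclinical*;
anything else *none*. `classify_misophonia()` treats missing
criterion-relevant answers as non-endorsement and flags the row as
incomplete rather than failing: a screening tool must degrade gracefully on
partial data. Scoring, by contrast, does not prorate: a screen-positive
respondent missing any scored item gets `NA` scores and `valid = FALSE`,
while screen-negative respondents are scored all-zero, matching how
full-sample correlations treat the zero-inflated design.

## The measurement model

Item responses are modelled with a logistic graded response model (GRM) under
a bifactor structure. For item $j$ with slopes $a_j$ over the latent vector
$\theta$ and strictly decreasing intercepts $d_{j1} > \dots > d_{j4}$,

$$P(X_j \ge k \mid \theta) = \mathrm{logistic}(a_j^\top \theta + d_{jk}),
\qquad k = 1, \dots, 4,$$

with category probabilities obtained by differencing. All latent variables
are orthogonal standard normal: one general misophonia factor plus four
specific factors (anger/aggression; distress/avoidance; overall impairment;
global impact). The package ships two calibrated parameter sets as YAML
fixtures — `dvmsq_model("prolific")` for a general-population sample and
`dvmsq_model("spark")` for a sample of autistic adults — with the published
slopes and intercepts stored verbatim; slope cells absent from the published
table are structural zeros fixed by the loading pattern.

Standardized loadings are derived from slopes by
$\lambda = a^*/\sqrt{1 + \sum a^{*2}}$ with $a^* = a/1.702$; the
logistic-to-probit constant is exposed as an argument because the convention
behind any particular published loading table is rarely stated. From the
loadings, `bifactor_indices()` computes model-based reliability
($\omega_T$), general-factor saturation ($\omega_H$), per-subscale
saturation ($\omega_{HS}$), and explained common variance (ECV). On the
packaged general-population parameters these land within a few hundredths of
the values reported for that calibration; exact agreement is not expected
because rounding of the printed slopes and the conversion convention both
move the indices at the second decimal, so the package's tests check them
only to ±0.05.

## The synthetic-respondent generator

`simulate_responses()` generates data with exactly the structure the model
assumes: orthogonal normal traits, GRM responses drawn per item, and a
screening gate. Screening is either an independent Bernoulli coin or, by
default, a logistic function of the general trait (slope 1.5, intercept 0.3),
so screen-positives are trait-enriched — the mechanism that makes
full-sample and completer-subsample analyses genuinely different, as they
are in real administration. No screening model was reported for the original
data; the default link was chosen once so that roughly the observed
screen-positive fraction arises when the latent mean is near zero, and so
that the gate is informative rather than ignorable. External scales are
linear in the general trait plus Gaussian noise — the simplest structure
that supports convergent-validity testing.

What the generator does *not* emulate: response styles, careless responding,
item-level missingness other than the gate, non-normal trait distributions,
and the real joint distribution of traits and demographics. Passing tests on
simulated data therefore validate the estimation and decision machinery,
not the instrument's field behaviour; observed caseness rates, for example,
are checked only against a broad plausibility band.

## Calibration

`fit_grm()` estimates parameters by maximum marginal likelihood with the
Bock-Aitkin EM algorithm. The latent density is integrated on a fixed
rectangular grid on $[-6, 6]$ with weights proportional to the normal
density: 49 nodes per dimension for one- and two-dimensional blocks,
dropping to 15 per dimension when cross-loading items merge specific factors
into blocks of three or more joint dimensions (in the full DVMSQ pattern,
item 4 merges the two symptom specifics and items 18-20 merge the two
impairment specifics, giving two three-dimensional blocks). A deterministic
grid was preferred over stochastic integration because it makes every fit,
test statistic, and bootstrap cutoff exactly reproducible; the grid
likelihood was verified against adaptive numerical integration to $10^{-6}$
per response pattern. The E-step uses bifactor dimension reduction —
conditional on the general factor, blocks are integrated independently — so
cost grows with block size, not total factor count; the block kernels are
implemented in C++.

M-step updates maximize each item's expected complete-data log-likelihood by
BFGS with analytic gradients, with intercepts reparameterized as
$d_k = d_1 - \sum_{l \le k} e^{t_l}$ so strict ordering can never be
violated. Start values are unit slopes and intercepts from inverse-logistic
cumulative category frequencies. Convergence is declared when the largest
absolute parameter change falls below $10^{-4}$ (or 500 cycles). Because EM
crawls on flat ridges, successive steps that shrink geometrically trigger a
Ramsay-style extrapolation along the step direction, guarded by a
monotonicity check that rejects any proposal that lowers the likelihood —
the recorded log-likelihood trace is non-decreasing by construction, and the
tests assert it. Categories never observed in the data are collapsed out
per item before fitting; an item observed in fewer than two categories is an
error. Standard errors come from the outer product of per-respondent score
vectors (cross-product information), which is the covariance the Wald DIF
tests consume.

One caution learned during development and worth recording: a bifactor
pattern in which *every* item also loads a specific factor is empirically
close to under-identified — the general factor can partially rotate into the
specifics, EM slows to a crawl, and freed cross-loadings wander. The DVMSQ
pattern avoids this (items 8 and 9 are pure general-factor markers), and the
package's cross-loading recovery tests use designs with such anchor items.

`fit_multigroup()` extends the engine to two groups: reference latents are
standard normal; the focal group's general-factor mean and variance are
estimated (via the discretized-normal likelihood on the same grid) or fixed,
and specific-factor moments stay fixed at 0/1 in both groups, mirroring the
constraint used to keep such models tractable. Items can be equated
(shared parameters, expected counts pooled) or free per group.

## Local fit diagnostics

`residual_diagnostics()` operationalizes "standardized residuals" as
observed-minus-implied item-score correlations: the implied correlation of
each item pair is computed by quadrature over the pair's joint latent
dimensions (pairs sharing no specific factor need only the general-factor
margin). SRMR is the root mean square of the lower triangle. The
conventional flag thresholds |r_res| > 0.1 (strict) and > 0.15 (relaxed, for
large models) are arguments, not constants. Local dependence is measured by
Yen's Q3 — correlations of residuals around EAP-predicted scores, with EAP
computed on the full joint grid — and judged against a parametric-bootstrap
critical value: `q3_bootstrap_cutoff()` simulates replicate datasets of the
original size from the fitted model, recomputes all pairwise Q3, and takes
the 99th percentile of the pooled |Q3| distribution (pooling across
replicates by default; a per-replicate-maximum variant is available, since
published descriptions of this procedure rarely say which was used). Q3 is
slightly negative in expectation under the null; the bootstrap cutoff
absorbs that bias automatically.

## Differential item and test functioning

DIF testing follows the iterative anchor-purification Wald ("Wald-2")
procedure. Stage 1 equates all items to estimate focal impact; stage 2 fixes
the group distributions, frees every item, and tests each with an omnibus
Wald test on the between-group parameter difference (delta-method covariance
from the joint fit). Items that are non-significant at $\alpha = 0.05$
(uncorrected) *or* have a negligible effect size (|ESSD| < 0.2) become
anchors; the model is refit with anchors equated and candidates retested,
iterating until every tested candidate shows DIF. The final table carries
Benjamini-Hochberg corrected p-values over the full item family, and an item
is flagged as practically significant only when $p_{FDR} < 0.05$ *and*
|ESSD| > 0.5. Significant items are followed up with slope-only and
intercept-only Wald tests to label DIF non-uniform or uniform.

Effect sizes follow the Meade taxonomy. With $d_j(\theta)$ the focal-minus-
reference expected-score difference at equal trait, SIDS is its mean over
the focal latent distribution, UIDS the mean absolute value, and ESSD
standardizes SIDS by the pooled model-implied item SD (equal group weights).
Model-implied rather than observed SDs keep the statistic computable from
parameter sets alone; this is a documented divergence from sample-based
variants, and a trait-sample route (`method = "sample"`) is provided to
match "in the sample" semantics. The test level sums item effects: STDS,
UETSDS (mean |total difference|, computed over a seeded Monte-Carlo trait
sample because the absolute value couples all latent dimensions), and ETSSD
(STDS over the pooled model-implied total-score SD), with |ETSSD| > 0.1 the
conventional practical-DTF threshold. A pure focal mean shift ("impact") is
not DIF and produces exactly zero effect sizes when parameters are equal —
one of the package's invariant tests. Note that a slope-only parameter
change can carry a near-zero ESSD when the groups have equal trait means;
such items can legitimately end up anchored by the effect-size rule, which
is a property of the published procedure, not a defect of the
implementation.

## Validity statistics

Polyserial and polychoric correlations use the two-step estimator:
thresholds fixed at inverse-normal cumulative margins (and the continuous
variable standardized by sample moments), then a one-dimensional likelihood
maximization over the latent correlation, with bivariate-normal rectangle
probabilities from the `mvtnorm` machinery and a $10^{-8}$ optimization
tolerance — standard and fully adequate at questionnaire sample sizes.
Coefficient alpha is the usual variance-ratio form. Dependent overlapping
correlations are compared with Zou's confidence-interval procedure
(per-correlation Fisher limits combined through the asymptotic correlation
of the two estimates). Subgroup-versus-complement contrasts are recovered
from reported moments by exact sum-of-squares decomposition before computing
Cohen's d with $n-1$ pooled weights and a normal-approximation CI (the CI
method behind published values of this kind is typically unstated; the
normal approximation reproduces them to the printed precision). Odds ratios
use the Woolf logit CI with no continuity correction, erroring on zero cells
with a suggestion rather than silently correcting.

## Problem sizes and what the tests show

The test suite calibrates at the scale a desk validation needs, chosen as
the smallest sizes at which the checked properties are stable: parameter
recovery at $n = 2000$ (unidimensional) and $n = 3000$ (full bifactor
pattern); DIF power and specificity over 25 replicates at $n = 2000$ per
group with a planted intercept shift of $-1.5$; Wald type-I error over 200
null replicates at $n = 500$ per group; Q3 bootstrap cutoffs at 100-200
replicates; Zou CI coverage over 1000 trivariate-normal replicates. All
stochastic tests run under fixed seeds. These sizes demonstrate correctness
of the machinery; they are not power analyses for real studies.

## Known limitations

The EM engine handles listwise-complete screen-positive rows only; there is
no missing-data E-step. Latent structures are restricted to orthogonal
bifactor patterns (no correlated factors, no nominal or partial-credit
models). The limited-information C2 family of global fit statistics is not
implemented; global fit is judged through residual correlations and SRMR.
Reported DIF results on real respondents depend on the real joint trait
distribution and cannot be reproduced from parameter tables alone; the
package's DIF tests therefore validate the procedure on synthetic data
rather than reproducing published test statistics.
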