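---
title: "Graded-response calibration and hybrid ordinal-logistic DIF screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded-response calibration and hybrid ordinal-logistic DIF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmdif)
library(dplyr)
```

## The measurement problem

Short ordinal symptom scales such as the 21-item Beck Depression
Inventory-II (BDI-II) are usually summarized by a sum score, which treats
"changes in sleep" and "suicidal thoughts" as interchangeable one-point
increments. Item response theory replaces the sum with a latent severity
$\theta$ and describes each item by how strongly it discriminates along
$\theta$ and how severe a state it takes to endorse it. Two questions then
become answerable at the item level:

1. **Calibration** — where along the severity continuum does each item (and
   each response option) become likely?
2. **Differential item functioning (DIF)** — do respondents with the *same*
   severity but different group membership (here: gender, age group) answer
   an item differently? DIF is distinct from *impact*, a genuine group
   difference in the severity distribution; a sound screen must separate
   the two.

`grmdif` implements the full workflow: simulation of graded responses with
known structure, graded-response-model calibration, EAP scoring, classical
reliability statistics, the iterative hybrid ordinal-logistic-regression
DIF screen, and characteristic-curve summaries of DIF impact.

## The graded response model

For item $j$ with four ordered response options scored $0\ldots3$,
Samejima's graded response model specifies boundary (cumulative)
probabilities

$$P^{*}_{jk}(\theta) = \frac{1}{1 + \exp\{-a_j(\theta - b_{jk})\}},\qquad
k = 1, 2, 3,$$

with discrimination $a_j > 0$ and strictly ordered severity thresholds
$b_{j1} < b_{j2} < b_{j3}$. Category probabilities are the adjacent
differences $P_{jk} = P^{*}_{jk} - P^{*}_{j,k+1}$ (with $P^{*}_{j0}=1$,
$P^{*}_{j4}=0$).

The parameters live on the **logistic metric without the 1.702 scaling
constant**. This is a deliberate, checkable choice: the packaged published
item bank reproduces the published population response-proportion table
and the published mean total score only under this convention
(`implied_marginals()`, `implied_moments()` make the check a one-liner).
The estimation software behind published banks does not always state its
metric; when importing parameters from elsewhere, verify marginals the
same way before trusting them.

```{r implied}
bank <- bdi2_bank()
implied_moments(bank)[c("total_mean", "total_sd", "alpha")]
```

### Calibration by marginal maximum likelihood

`fit_grm()` integrates $\theta$ out of the pattern likelihood over a fixed
quadrature grid (default: 61 equally spaced nodes on $[-5, 5]$ with
standard-normal weights, renormalized) and maximizes the marginal
likelihood by EM:

* **E-step** — each person's posterior weight over the grid nodes under the
  $N(0,1)$ prior, which identifies the latent scale (no post-hoc
  standardization).
* **M-step** — per item, quasi-Newton ascent of the expected complete-data
  log-likelihood in the parameterization $(\log a,\; b_1,\;
  \log(b_2-b_1),\; \log(b_3-b_2))$, so positivity of $a$ and threshold
  ordering hold *structurally* at every iterate rather than being patched
  after the fact. Analytic gradients are supplied.

Convergence is declared when the largest absolute parameter change in an
iteration drops below `tol` (default $10^{-4}$; at the study's sample size
this takes roughly 60 iterations). Starting values are $a = 1$ with
thresholds at the logits of the observed cumulative proportions. The
marginal log-likelihood is recorded every iteration and is asserted
non-decreasing in the test suite — a property any correct EM must have,
and a sensitive canary for M-step bugs.

Standard errors use the outer-product-of-gradients (empirical
cross-product) approximation of the information matrix, computed from the
per-person posterior-averaged score vectors. They are approximate — good
at survey sample sizes, optimistic at small $N$ — and are documented as
such wherever they surface.

Two degenerate-input rules: an item with fewer than two observed
categories stops calibration with an error naming the item; a
never-observed interior or top category is collapsed into the adjacent
lower category with a warning (`collapse = TRUE`, the default), the
collapsed item keeping trailing-`NA` thresholds in the returned bank.
Missing responses are treated as ignorable and skipped in the pattern
likelihood; no imputation.

### Scoring

`eap_score()` returns the posterior mean and SD of $\theta$ per person
over the same grid. EAP estimates shrink toward the prior mean — the
regression of EAP on a known generating $\theta$ has slope below 1 — which
is expected behaviour, not bias to fix, and is what makes them stable
conditioning variables for the DIF models. An all-missing pattern falls
back to the prior ($\theta = 0$, SD 1) and is flagged.

## Classical statistics

`cronbach_alpha()`, `item_descriptives()`, `classify_cutoff()` and
`compare_groups()` reproduce the standard item-total analysis: means, SDs,
Pearson's CV ($SD/M$), alpha-if-item-deleted, proportions above a
screening cut-off, and unweighted Welch / two-proportion comparisons
between groups. Choices worth knowing:

* The cut-off is **strict**: "cut-off 13" classifies totals $> 13$ (i.e.
  14+), matching the conventional 0–13 "minimal" band; `strict = FALSE`
  switches to $\geq$.
* Alpha uses listwise deletion (reported via a message). The emulated
  survey was essentially complete, so nothing more elaborate is warranted.
* CV is reported as 0 (and flagged) for a constant item, `NA` for a
  non-positive mean.

## The hybrid OLR DIF screen

For each item, four nested proportional-odds (cumulative-logit) models of
the response $y \in \{0\ldots3\}$:

| model | predictors |
|-------|-----------------------------|
| 0 | intercepts only |
| 1 | $\theta$ |
| 2 | $\theta$ + group |
| 3 | $\theta$ + group + $\theta\times$group |

The conditioning variable is the **IRT-derived trait score**, not the raw
sum — the "hybrid" in the name — which is what lets the screen separate
impact from DIF. The decision rules, per item:

* **flagged** iff the pseudo-$R^2$ gain from model 1 to model 3 exceeds
  0.02;
* **uniform** DIF iff the 1-vs-2 gain exceeds the threshold (a constant
  group effect), **non-uniform** iff the 2-vs-3 gain does (effect varying
  with $\theta$), **mixed** if both; a flagged item whose sub-comparisons
  both stay under the threshold is reported uniform, the constant-effect
  reading of its signature.

Three pseudo-$R^2$ flavors are computed and reported (McFadden,
Cox–Snell, Nagelkerke). The *rule* defaults to McFadden because it is the
only one of the three guaranteed non-negative for nested ML fits, which
makes the threshold comparison well-defined; the flavor is selectable.
An alternative significance rule (likelihood-ratio 1-vs-3 at
$\alpha = 0.01$, Bonferroni-divided across items) is available via
`flag_rule = "lr"`.

The proportional-odds fits are full Newton–Raphson with step-halving on
the analytic score (Hessian by central differences of the score), started
at the observed cumulative logits. The intercept-only fit reproduces the
observed cumulative logits exactly; the test suite cross-checks the
general fit against both `MASS::polr` and a brute-force likelihood grid.
Categories with fewer than `min_cell = 5` observations in either group
are collapsed into an adjacent category before fitting — low-frequency
top options are endemic in non-clinical samples and otherwise destabilize
the cutpoints.

The 0.02 rule is deliberately conservative: under the null at survey
sample sizes the per-item flag rate is far below 1%, and realistic
non-uniform effects (a discrimination change) often stay under the
threshold. That behaviour is characterized, not hidden, in the test
suite.

### Purification

`dif_analysis()` iterates: calibrate pooled → score → screen → if items
are flagged, recalibrate giving the flagged items **group-specific**
parameters while anchor items stay shared across groups (anchors fix the
latent metric), rescore each person with their group's bank, rescreen —
until the flagged set is unchanged or `max_purification_iters = 10`. An
empty flag set on the first screen needs no purification round (the
report shows 0 iterations). If every item is flagged there is no anchor
left and the analysis aborts with a diagnostic rather than returning an
uninterpretable result. A lighter `anchor_mode = "anchors_only"` rescores
$\theta$ from the unflagged items alone instead of refitting
group-specific parameters.

## Characteristic curves and DIF impact

`icc()` and `tcc()` tabulate expected item/test scores and category
probabilities on a $\theta$ grid (default 201 points on $[-4, 4]$);
`autoplot()` renders them. `dif_impact()` takes the reference and focal
banks from a purification refit and reports the focal-minus-reference
difference of expected total scores — over all items and over the DIF
items alone (identical when anchors are truly shared, which is asserted)
— with the maximum absolute difference and its location. This is the
quantitative version of the question "does the flagged item actually move
the total score?": a single 4-category item bounds the difference by 3
raw-score points out of 63, and a realistic uniform shift moves it far
less.

## The simulator: what it emulates, and what it does not

`simulate_responses()` draws gender and age group independently
(fractions default to the emulated survey: 44.9/55.1% and 85.9/14.1%),
then $\theta \sim N(\mu_{\text{gender}} + \delta_{\text{age}},\,
\sigma_{\text{gender}})$, then responses item by item from the GRM — one
seeded stream, so identical spec + seed gives byte-identical data. DIF is
injected per item as a constant threshold shift for the focal group
(uniform) and/or a discrimination multiplier (non-uniform).

`make_study_fixture()` reproduces the emulated study's headline structure:
12,677 respondents whose group latent means are found by inverting the
population test characteristic curve (`calibrate_group_mean()`, monotone
root-finding to $10^{-6}$) so that expected total scores match the
published group means (men 5.92, women 7.85, younger 7.17, older 5.83).
Gender and age are independent attributes, so those four marginal targets
over-determine an additive shift model; the age shifts are calibrated
first and centered, then the gender means are solved exactly on the age
mixture — gender means are matched in expectation, age means
approximately. The latent trait is standard normal in the reference
population; the source study never states its trait distribution, and
$N(0,1)$ is the MML identification convention.

What the simulator does **not** emulate: the survey's two-stage cluster
sampling (all draws are i.i.d.), item-level missingness structure beyond
an optional MCAR mask, any residual multidimensionality, and the
(unpublished) magnitudes of the real gender/age DIF. Passing tests
therefore demonstrate that the *methods* recover known structure from
data that satisfy the model's assumptions — not that real BDI-II data do.

## Numerical choices, in one place

* Quadrature: 61 nodes on $[-5,5]$; implied marginals move by under
  $10^{-6}$ between 41 and 61 nodes, so grid error is negligible at
  reporting precision.
* EM: `tol = 1e-4` on the max parameter change, `max_iter = 500`;
  per-item M-step BFGS with analytic gradients, warm-started.
* Proportional odds: Newton with step-halving (up to 30 halvings),
  convergence on log-likelihood change $< 10^{-10}$; a separation-like
  failure to ascend stops with the current point and a warning.
* Probabilities are floored at $10^{-300}$ inside logs; posterior
  normalization is done on the max-shifted log scale.
* Root-finding for group calibration brackets $[-6, 6]$ and extends
  upward if needed; targets outside the open achievable range error.

## Problem sizes used for verification

The package's own checks run: implied-quantity comparisons at quadrature
precision; parameter recovery on one simulated dataset of 12,677 persons
(all 21 discriminations within $3\times$(published SE + estimation SE),
spot checks on the most and least discriminating items); reliability on
the same dataset; DIF operating characteristics at $N = 2{,}000$ with 50
null and 40 injected-DIF replicates, conditioning on EAP scores from the
generating bank (the screen's own surface) so the replication loop stays
light; and full `dif_analysis()` end-to-end — internal calibration,
purification, group-specific refit — at $N = 3{,}000$–$4{,}000$. These
sizes give Monte-Carlo error comfortably inside every asserted tolerance.

## Known limitations

* Unidimensionality is assumed, not tested here; the factor-analytic
  screen of the source analysis is out of scope.
* OPG standard errors understate uncertainty for very sparse top
  categories.
* The DIF screen handles exactly two groups; polytomous groupings need
  dummy recoding and multiple runs.
* Survey design (weights, clustering) is ignored throughout; comparisons
  are descriptive.
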