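---
title: "Two-group resilience-factor network analysis with rfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-group resilience-factor network analysis with rfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfnet)
```

## The model

`rfnet` estimates and compares Gaussian graphical models (GGMs) of
psychometric resilience-factor data for two groups — typically persons
exposed and not exposed to childhood adversity. In a GGM the nodes are
measured constructs (resilience factors such as friendship support or
self-esteem, plus optionally a general-distress criterion) and an edge
between nodes $i$ and $j$ carries their partial correlation

$$ w_{ij} \;=\; -\,\frac{K_{ij}}{\sqrt{K_{ii}\,K_{jj}}}, $$

where $K = \Sigma^{-1}$ is the precision matrix: the association between
two variables after conditioning on every other variable in the network.
A zero entry in $K$ is a conditional independence, so a sparse $K$ *is*
the network structure.

Because a $p$-node network estimates $p(p-1)/2$ interrelations at once,
the package regularizes with the graphical lasso,

$$ \hat K \;=\; \arg\max_{K \succ 0}\;
   \log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|, $$

which sets weak partial correlations exactly to zero. The penalty
$\lambda$ is chosen by the extended Bayesian information criterion
(EBIC) along a path of candidate penalties.

## Data preparation

Raw questionnaire data are mixed-type: ordinal item responses, binary
indicators for scales with a restricted range, and continuous factor
scores. The preparation pipeline mirrors standard psychometric network
practice:

* **Mixed correlations.** `auto_correlation_matrix()` picks the
  estimator per pair from the declared variable types: Pearson for two
  continuous variables, polychoric for two ordinal/binary variables,
  polyserial for a mixed pair. The polychoric and polyserial estimators
  are two-step: thresholds are fixed at inverse-normal marginal
  cumulative proportions, then the latent correlation maximizes the
  bivariate-normal likelihood by bounded scalar search (tolerance
  `1e-6`). Bivariate rectangle probabilities use a Gauss–Legendre
  quadrature of the Genz type with absolute error far below `1e-7`.
  Full maximum likelihood would re-estimate thresholds jointly; the
  two-step estimator is the standard fast choice and is adequate at the
  sample sizes this design targets (hundreds per group), which the
  parameter-recovery tests confirm (latent $\rho$ recovered within
  $\pm 0.03$ at $n = 10{,}000$).
* **Factor scores.** Each multi-item construct is scored by a one-factor
  CFA fitted to the item polychoric matrix by unweighted least squares
  (minimizing $\sum_{i<j}(s_{ij} - \lambda_i\lambda_j)^2$), with a fixed
  deterministic multi-start (first principal component, its negation, a
  flat 0.5 vector) so results never depend on random initialization.
  Persons are scored by the Thurstone regression method on standardized
  item codes; persons with partially missing items are scored from the
  observed subset's sub-model. Scores are standardized on the pooled
  sample. Constructs measured by fewer than three items cannot support
  a CFA; the estimator refuses them and the standardized item itself is
  used instead.
* **Nonparanormal transformation.** Continuous scores are gaussianized
  by `nonparanormal_transform()`: ranks $\to$ empirical CDF $r/(n+1)$,
  truncated to $[\delta_n, 1-\delta_n]$ with
  $\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$, then mapped through the
  normal quantile function and rescaled to unit sample variance. The
  truncation clips the most extreme ranks to a common value, so the map
  is monotone but not strictly so at the tails.
* **Pooled-then-split.** All transformations are applied to the pooled
  two-group sample *before* splitting
  (`pooled_transform_then_split()`). This puts both groups on one
  common scale, which the permutation comparison tests require for
  exchangeability.
* **Dichotomization.** Range-restricted scales are collapsed by
  `dichotomize_restricted()`, coding the protective (modal, restricted)
  level 1 and everything else 0; degenerate all-one/all-zero outcomes
  are an error.

If the assembled mixed correlation matrix is not positive definite
(possible under pairwise deletion), its eigenvalues are clipped at a
floor of `1e-6` and the matrix renormalized to unit diagonal; the
output flags this repair. Under pairwise deletion the EBIC sample size
is the minimum pairwise $n$ — the conservative choice.

## Network estimation and EBIC scoring

`ebic_glasso_network()` fits a warm-started graphical-lasso path of 100
log-spaced penalties from $\lambda_{\max} = \max_{i<j} |S_{ij}|$ down to
$0.01\,\lambda_{\max}$ and scores each candidate with

$$ \mathrm{EBIC}(\lambda) = -2 L + E \log n + 4 E \gamma \log p, $$

where $E$ counts selected edges and $\gamma = 0.5$ by default. Two
numerical choices matter here and both are deliberate:

* **Refit scoring.** $L$ is the Gaussian log-likelihood of the
  *support-restricted maximum-likelihood* precision matrix, not of the
  penalized estimate — the construction of the original EBIC proposal
  for GGMs. Scoring the penalized estimate instead lets the shrinkage
  of true edges masquerade as likelihood loss, which in our recovery
  experiments made the criterion keep several tiny spurious edges even
  at $n = 5000$; with refit scoring the chain-graph support is
  recovered without errors.
* **Tie-breaking.** Under refit scoring every $\lambda$ with the same
  support scores identically, so EBIC ties are resolved first toward
  the sparser support (regularization's purpose is conservatism) and
  then, within one support, toward the smallest penalty, so the
  reported weights carry the least shrinkage compatible with the chosen
  structure. The network's edge weights are the regularized partial
  correlations at that penalty.

`association_network()` gives the unregularized zero-order counterpart,
and `remove_node()` implements the distress-corrected construction:
deleting the general-distress node from the estimated 11-node network
*without re-estimation*, so the remaining factor–factor edges stay
conditioned on distress. This is deliberately different from
re-estimating a 10-node network — conditioning on a common cause can
expose negative interrelations that marginalizing it hides, and the
test suite demonstrates exactly this on a designed fixture.

## Inference

* **Centrality.** Node strength $s_i = \sum_j |w_{ij}|$ and expected
  influence $e_i = \sum_j w_{ij}$; global strength and global expected
  influence sum each edge once (upper triangle), so global strength is
  half the sum of node strengths.
* **Predictability.** Each node is regressed on all others with a
  penalized nodewise model (linear for continuous nodes, logistic for
  binary), the penalty picked by EBIC with the network's $\gamma$.
  Continuous nodes report $R^2$; binary nodes report normalized
  accuracy beyond the modal class, floored at 0. These are separate
  regressions, not a re-use of the glasso coefficients, matching the
  mixed-graphical-model practice for predictability.
* **Shortest pathways.** Dijkstra's algorithm on distances $1/|w_{ij}|$
  over the nonzero edges; absent edges are non-adjacent. Ties between
  equal-length routes resolve to the lexicographically smaller node
  sequence, so results are deterministic. A pathway is *direct* when
  the optimal route is the single source–target edge.

## Comparing the two groups

`compare_networks()` runs the permutation design: estimate both group
networks under one shared estimator configuration, then repeatedly
reshuffle the group labels (preserving group sizes), re-run the *full*
estimator — correlation matrix, path, EBIC selection — for both
pseudo-groups, and recompute four statistics: the maximal absolute edge
difference $M$ (network structure invariance), the absolute global
strength difference, the absolute global expected-influence difference,
and every per-edge absolute difference, the latter Holm–Bonferroni
corrected across all $p(p-1)/2$ pairs. One joint permutation stream
feeds all statistics; p-values use $(1 + \#\{\text{perm} \ge
\text{obs}\})/(1 + n_{\text{perm}})$, which cannot return zero. The
statistics are absolute, so the tests are two-tailed by construction.
The reference design uses 5000 permutations; the test suite scales this
down (its calibration study uses 500 replicates of 200 permutations,
which bounds the type-I error check's Monte-Carlo error while staying
inside a practical runtime for the full suite).

Re-running the full estimator inside every permutation — rather than
shortcutting on a pooled correlation matrix — keeps selection
variability inside the null distribution. The fast all-continuous
estimation path used inside these loops is the same estimator: for
complete continuous data the Pearson matrix is already positive
definite, so the repair stage is a provable no-op there.

## Robustness

* **Edge accuracy** (`edge_bootstrap()`): persons are resampled with
  replacement and the network re-estimated per replicate. Point
  estimates and bootstrap medians are reported on the regularized
  scale. The 95% percentile confidence interval, however, is computed
  from the *support-refit* replicate weights (the unpenalized MLE on
  each replicate's selected support): percentile intervals of the
  shrunk weights sit systematically below strong true edges — the
  shrinkage bias is of the same order as the interval width at any
  sample size — whereas the refit intervals keep selection and
  sampling variability while dropping that bias. Simulation puts their
  empirical coverage of true edge weights in the low-to-mid 0.9s on
  strong-signal fixtures.
* **Centrality stability** (`case_dropping_stability()`): for each
  case-dropping proportion, subsets are drawn without replacement, the
  network re-estimated, and subset node strength / expected influence
  Spearman-correlated with the full-sample values. The stability
  coefficient is the largest drop proportion (reached monotonically
  from below) at which the correlation stays $\ge 0.7$ in $\ge 95\%$ of
  subsets — the conventional thresholds of the field's stability
  tooling; the underlying design describes the procedure but fixes no
  thresholds, so these are package defaults. Spearman (rank) rather
  than Pearson correlation is used for robustness to scale changes.
  Note that a stability analysis is only as meaningful as the
  centrality order is identifiable: a network whose true node strengths
  are tied (e.g. a homogeneous chain) has a fragile rank order at any
  sample size.

## The synthetic cohort generator

Because the motivating study's person-level data are access-restricted,
every stage is exercised against `generator_config()` /
`generate_two_group_study()`: a two-group latent Gaussian cohort whose
ground truth is fully known. The generator draws latent multivariate
normal scores per group from `build_covariance_from_partials()` — the
exact inverse of the estimator's partial-correlation convention, so
round-trips are identities to numerical precision — applies per-group
mean shifts, thresholds binary nodes, and can emit ordinal indicator
items $y = \ell f + \sqrt{1-\ell^2}\,\varepsilon$ cut at configurable
thresholds for testing the CFA layer. Group A draws from `seed + 1` and
group B from `seed + 2`, so resizing one group never perturbs the
other. Optional missingness is MCAR per column (default 0).

`paper_like_config()` ships the default study-shaped cohort: 10
resilience factors (8 continuous, 2 binary) plus one continuous
general-distress node, group sizes 638 and 501. The non-exposed
analogue (group B) has sparse all-positive factor–factor partials and
mild negative factor–distress edges; the exposed analogue (group A)
flips a minority of factor–factor partials negative (including the
suppression–friendship pair), strengthens and multiplies the
factor–distress edges, and shifts means (factors down, distress up).
True partial values, thresholds and loadings are this package's own
choices of plausible magnitudes — the study reports no ground-truth
values, and no attempt is made to match its unpublished edge weights.

What the generator does *not* emulate: item-level measurement
non-invariance between groups, missingness that is informative rather
than MCAR, floor/ceiling effects beyond what thresholding induces, and
sampling designs with dependence between persons. Tests passing on
this generator therefore validate the estimators and their calibration
under the latent-Gaussian measurement model, not robustness to every
way real cohort data can misbehave.

## Degenerate inputs and numerical edge cases

* A correlation matrix with no off-diagonal signal selects the empty
  network directly (no path is fitted).
* Non-convergence of the glasso block coordinate descent (tolerance
  `1e-6` on the maximum parameter change) is an error, not a warning.
* Estimation failures inside permutation or bootstrap loops cause that
  replicate to be redrawn, capped at 1% of the requested replicates.
* Polychoric/polyserial estimation requires at least two observed
  categories and pair $n \ge 10$ after deletion; constant columns are
  errors.
* Stability grid points leaving fewer than $p + 10$ persons are
  skipped with a warning.

## Problem sizes used by the test suite

The suite validates calibration and recovery at sizes chosen to make
Monte-Carlo error small relative to the tested tolerances while keeping
the default run practical: type-I error of the invariance test over 500
null replicates at 200 permutations ($n = 300$ per group, 6 nodes);
Holm-corrected edge-test power over 100 replicates at 1000 permutations
($n = 500$ per group); chain support recovery at $n = 5000$; polychoric
recovery at $n = 10{,}000$; CFA loading recovery at $n = 2000$;
bootstrap CI coverage over 200 simulated datasets.

## Known limitations

* The GGM is undirected and cross-sectional: edges are conditional
  associations, not causal effects, and the distress-corrected
  construction inherits every caveat of conditioning on a possibly
  endogenous variable.
* Polychoric/polyserial estimation is two-step, not full ML; standard
  errors of individual correlations are not propagated into the
  network.
* The one-factor scorer fits no fit indices beyond the ULS residual
  and deliberately offers no multi-factor or bifactor models.
* Permutation tests assume exchangeability under the null, which the
  pooled transformation supports but cannot guarantee if the groups
  differ in measurement structure itself.
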