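---
title: "PALM: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PALM: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-wide association studies test millions of SNPs and summarize each by
a p-value. Many truly associated variants have effects too weak to clear a
genome-wide threshold, but they are not exchangeable a priori: variants in
functionally active regions (cell-type-specific chromatin, regulatory
elements) are enriched for true associations. PALM prioritizes risk
variants by combining the *direct* evidence (the p-value) with this
*indirect* evidence (a vector of functional annotations per SNP), without
assuming the relationship between annotations and association status is
linear.

## The model

Each SNP $j = 1, \dots, M$ carries a latent association status
$Z_j \in \{0, 1\}$ and a two-groups model for its p-value:

$$p_j \mid Z_j = 0 \sim \mathrm{U}(0,1), \qquad
  p_j \mid Z_j = 1 \sim \mathrm{Beta}(\alpha, 1), \quad 0 < \alpha < 1,$$

so the non-null density is $\phi(p;\alpha) = \alpha p^{\alpha-1}$,
decreasing in $p$. The prior of association is modulated by the SNP's
annotation row $A_j \in \mathbb{R}^L$ through a logit link,

$$\log \frac{\Pr(Z_j = 1 \mid A_j)}{\Pr(Z_j = 0 \mid A_j)} = F(A_j),
  \qquad F(A_j) = f_0 + \sum_{t=1}^{T} f_t(A_j),$$

where each $f_t$ is a regression tree of depth $D$. Depth 1 gives an
additive model in the annotations (PALM-D1); depth 2 admits pairwise
interactions (PALM-D2). With $T = 0$ the model collapses to the classical
two-groups model (TGM) with a common prior.

## Fitting: a functional-gradient EM

The marginal log-likelihood is
$\ell(F, \alpha) = \sum_j \log[\pi_{j0} + \pi_{j1}\phi(p_j;\alpha)]$ with
$\pi_{j1} = \sigma(F(A_j))$. Because $Z$ is latent, standard supervised
boosting does not apply; PALM interleaves EM with boosting:

1. **E-step.** Posterior responsibilities
   $q_{j1} = \pi_{j1}\phi / (\pi_{j0} + \pi_{j1}\phi)$.
2. **M-step for $\alpha$** (closed form):
   $\alpha \leftarrow -\sum_j q_{j1} / \sum_j q_{j1} \log p_j$, clamped to
   $(10^{-6}, 1 - 10^{-6})$.
3. **M-step for $F$** (one boosting round): expand the expected
   complete-data log-likelihood to second order around the current $F$,
   giving per-SNP gradient $g_j = q_{j1} - \sigma(F_j)$ and hessian
   $h_j = -\sigma(F_j)(1 - \sigma(F_j))$, fit one tree to these by
   weighted least squares, and update $F \leftarrow F + \nu f_{t+1}$ with
   shrinkage $\nu$.

Each step cannot decrease the marginal log-likelihood (up to the
second-order approximation, which each leaf optimizes exactly via its
Newton step), and the fit trace is checked to be non-decreasing in the
tests with slack $10^{-8}$.

The quadratic tree objective is implemented with per-node aggregates
$(\sum g, \sum(-h))$ rather than the per-sample pseudo-targets $-g_j/h_j$,
which is algebraically identical and avoids division by vanishing
hessians. Leaf values are $\sum g / (\sum(-h) + \lambda)$.

### Initialisation

$(\pi_1, \alpha)$ are first fitted by the intercept-only TGM (EM from the
neutral start $\pi_1 = 0.1$, $\alpha = 0.5$, relative tolerance $10^{-8}$,
at most 1000 iterations), and the ensemble intercept is
$f_0 = \mathrm{logit}(\hat\pi_1)$. Zero trees therefore reproduce the TGM
exactly.

### Missing annotations

Every split learns a *default direction* for missing values: both routings
of the node's missing rows are scored during the exact greedy split search
and the gain-maximizing one is stored (sparsity-aware split finding). At
prediction time a missing feature follows the stored direction. SNPs with
entirely missing annotation rows are handled by the same mechanism.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `depth` | 1 | tree depth; 1 = additive, 2 = pairwise interactions |
| `nu` | 0.1 | shrinkage per tree; smaller is more stable, needs more trees |
| `cv_folds` | 5 | K for cross-validation (2 is used in the benchmark suites) |
| `max_trees` | 500 | search horizon for T |
| `tau` | 0.1 | nominal global FDR level |
| `min_child_weight` | 1 | minimum hessian mass per child |
| `lambda` | 1 | L2 penalty on leaf values |
| `early_stop` | 50 | stop CV after this many non-improving trees |

`min_child_weight` and `lambda` are the de-facto defaults of mainstream
gradient-boosting implementations; they prevent unbounded leaf values when
a candidate child's curvature mass vanishes and are declared here rather
than inferred from any reference.

### Choosing the number of trees

All K folds are boosted in lockstep; after each round the held-out
marginal log-likelihood is evaluated with the fold's current $\alpha$ and
its ensemble truncated at that round. The search stops once the mean
held-out curve has not improved for `early_stop` consecutive trees.

T is then selected by a **one-standard-error rule**: the smallest T whose
summed held-out improvement is within one SE of the best. The SE is
computed from per-SNP paired differences of held-out log-likelihood
between the best and the tree-free model, not from the K fold means: with
K = 2 a fold-based SE has a single degree of freedom and occasionally
collapses, which would let correlated noise drift retain spurious trees on
data whose annotations carry no signal. The plain argmax is available as
`cv_rule = "max"`. On negative-control data the 1-SE rule keeps zero trees
in almost all replicates, which is what makes the annotation-importance
output "null" there; on enriched data it trims only the flat tail of the
curve and leaves power essentially unchanged. The final model is refitted
on all data with exactly T trees, re-estimating $\alpha$ from scratch.

## Inference

The local false discovery rate of SNP j is
$\widehat{\mathrm{fdr}}_j = 1 - q_{j1}$ evaluated at the fitted model.
Global FDR is controlled by the direct posterior probability approach:
sort local fdr ascending and reject the largest prefix whose mean is at
most $\tau$. Ties at the prefix boundary are resolved conservatively: the
whole tie group enters only if the prefix mean stays below $\tau$. The
per-rank prefix means are reported so results can be re-thresholded
without refitting. The mean local fdr over the rejected set is $\le \tau$
by construction; the calibration of the *realized* false discovery
proportion is checked by simulation.

## Annotation importance and interactions

Tree t records, for every feature, the total split-objective reduction
achieved by splitting on it. The importance of annotation l is the average
over trees, $I_l = T^{-1}\sum_t I_{t,l}$, with a max-1 normalized column
for display. Two caveats are deliberate:

* $I_l = 0$ exactly for features never split on, and all importances are 0
  when T = 0.
* The $1/T$ factor is a per-model constant. It is immaterial for ranking
  annotations within one fit but makes raw importances incomparable across
  fits with very different T; cross-model comparisons (as in the
  negative-control check of the test suite) use the total accumulated gain
  instead.

Pairwise interactions are quantified by the Friedman–Popescu H-statistic:
the variance of the centered joint partial dependence on a feature pair
not explained by the two centered one-dimensional partial dependences,
divided by the variance of the centered joint partial dependence (the
squared H, in [0, 1]). Partial dependences are averaged over the empirical
distribution of the other annotations using `n_grid` subsampled rows
(default 2000), which double as evaluation points; rows missing either
feature of the pair are dropped. Trees splitting on neither feature cancel
exactly after centering and are skipped; trees splitting on exactly one
cancel between the joint and marginal terms, and the interaction residual
is accumulated only over trees that split on both — so depth-1 ensembles
return H = 0 exactly, not approximately.

## The simulation benchmark

The generator emulates a GWAS post-processing setting:

* annotations i.i.d. $\mathrm{U}(-1, 1)$ (plus one Bernoulli(0.5) binary
  column for scenario E);
* five annotation-to-prior scenarios on the logit scale (constant $-3$;
  linear; quadratic with interaction; sinusoidal + quadratic over five
  features; piecewise in a binary feature) — the constant scenario is the
  negative control with marginal non-null fraction
  $\sigma(-3) \approx 4.7\%$;
* latent status $Z_j \sim \mathrm{Bernoulli}(\sigma(F(A_j)))$;
* null p-values uniform; non-null p-values via a bimodal latent mean
  $\mu \sim 0.48\,N(-2,1) + 0.04\,N(0,16) + 0.48\,N(2,1)$,
  $z \sim N(\mu, 1)$, $p = 2(1 - \Phi(|z|))$ — deliberately *not* the
  model's Beta non-null, so every benchmark run probes robustness to
  misspecification (alternative normal mixtures can be supplied);
* independent entry-wise missingness at a configurable rate.

Everything is a pure function of one seed through named sub-streams
("annotations", "status", "pvalues", "missing", "cv").

What the generator does **not** emulate: linkage disequilibrium between
SNPs (p-values are independent given Z; real GWAS statistics are locally
correlated), realistic annotation correlation structure, genomic inflation
or confounding, and effect sizes tied to allele frequency. A green
benchmark therefore establishes calibration and power under independent,
well-randomized inputs — not performance under LD-induced dependence.

## Numerical choices and degenerate inputs

* p-values are clipped to $[10^{-300}, 1]$ on ingest (the Beta density
  diverges at 0); clip counts are reported.
* $\alpha$ is clamped to $(10^{-6}, 1-10^{-6})$; a zero posterior mass
  keeps the previous $\alpha$ with a warning.
* Under a pure null the TGM likelihood is flat along the ridge
  $\alpha \to 1$, where the non-null component degenerates to uniform; the
  EM then converges to an arbitrary ridge point with $\hat\pi_1$ not
  necessarily near 0. The identifiable functionals — the excess mass
  $\pi_1(1-\alpha)$ and the rejection set — behave correctly, and the
  tests assert those.
* Split ties are broken deterministically (lowest feature index, smallest
  threshold, then missing-direction left), so fits are exactly
  reproducible and permutation-equivariant.
* A split is accepted only if it improves the objective by more than
  $10^{-12}$ and both children carry at least `min_child_weight` of
  hessian mass; otherwise the node stays a leaf.

## Known limitations

* No LD modeling: dependent p-values can inflate the realized FDR relative
  to the nominal level; the guarantee is on posterior averages under the
  fitted model.
* The CV curve is evaluated per-tree on a single K-fold run (no refit per
  candidate T), trading a small optimism for tractability.
* Depth is a global constant per fit; depths above 4 are deliberately not
  defaults.
* The H-statistic is a ratio of variances of estimated partial
  dependences; on near-additive fits its denominator is small and the
  estimate is noisy — exact zeros are only guaranteed for depth-1 models.
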