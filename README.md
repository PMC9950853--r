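# palm

Prioritization of GWAS risk variants by integrating summary-statistic
p-values with functional annotations under a tree-ensemble two-groups
model (PALM).

## Who this is for

Statistical geneticists who have genome-wide p-values for one trait and a
matrix of per-SNP functional annotations (binary or continuous, possibly
with missing entries) and want to (i) identify more risk variants at a
controlled false discovery rate and (ii) learn which annotations drive the
enrichment, without assuming the annotation effects are linear.

## The model

Each SNP j has a latent association status `Z_j`. Its p-value follows a
two-groups mixture

```
p_j | Z_j = 0  ~  U(0, 1)
p_j | Z_j = 1  ~  Beta(alpha, 1),   0 < alpha < 1
```

and the prior of association is modulated by the annotation row `A_j`
through a logit link with a boosted tree ensemble:

```
logit Pr(Z_j = 1 | A_j) = F(A_j) = f0 + sum_t f_t(A_j)
```

where each `f_t` is a depth-D regression tree (D = 1: additive "PALM-D1";
D = 2: pairwise interactions "PALM-D2"). The ensemble and `alpha` are
fitted by a functional-gradient EM algorithm: the E-step computes posterior
responsibilities, the M-step updates `alpha` in closed form and adds one
tree fitted to the first/second derivatives of the expected complete-data
log-likelihood, shrunk by a learning rate `nu`. The number of trees is
chosen by K-fold cross-validation on held-out marginal log-likelihood
(one-standard-error rule). Missing annotation values are routed through
per-split default directions learned by sparsity-aware split finding.

Inference reports the local false discovery rate `fdr_j = Pr(Z_j = 0 |
p_j, A_j)` and controls the global FDR at level `tau` by the direct
posterior probability approach (reject the largest ascending-local-fdr
prefix whose mean is at most `tau`). Annotations are ranked by gain
importance; pairwise interactions are quantified by Friedman's
H-statistic. See `vignettes/palm-methods.Rmd` for the full account.

## Worked example

```r
library(palm)
set.seed(1)

# Simulated benchmark data: scenario C couples two annotations to the
# prior through a quadratic with an interaction; 20 annotations total.
sim <- simulate_dataset(M = 10000, L = 20, case = "C", seed = 7)
mean(sim$Z)                     # 0.0819  -- true non-null fraction

cfg   <- palm_config(depth = 2, cv_folds = 2, tau = 0.1, seed = 7)
model <- palm_fit(sim$p, sim$A, cfg)
model
#> PALM tree-ensemble model: 43 trees (depth 2), nu = 0.1, alpha = 0.2358, f0 = -2.3313
#>   20 annotations

res <- posterior_inference(model, sim$p, sim$A, tau = 0.1)
res
#> PALM inference: 299 of 10000 SNPs rejected at global FDR 0.1

# Against the truth of this replicate:
evaluate_replicate(sim$Z, res$rejected, "PALM-D2")
#>    method       fdp     power n_rejected
#> 1 PALM-D2 0.1237458 0.3199023        299
evaluate_replicate(sim$Z, bh_procedure(sim$p, 0.1), "BH")
#>   method       fdp     power n_rejected
#> 1     BH 0.1383929 0.2356532        224

imp <- variable_importance(model)
head(imp[order(-imp$importance), ], 3)
#>    annotation importance normalized
#> 2          A2  9.7218862  1.0000000
#> 1          A1  6.4572463  0.6641969
#> 10        A10  0.2292182  0.0235775

h_statistic(model, sim$A, 1, 2, n_grid = 500)   # 0.381 -- real interaction
h_statistic(model, sim$A, 3, 4, n_grid = 500)   # 0     -- irrelevant pair
```

Reading: PALM rejects 299 SNPs at nominal FDR 0.1 versus 224 for BH
(realized false-discovery proportions 0.124 and 0.138 on this single
replicate; both concentrate near 0.1 on average over replicates), a
~36% power gain from the annotations. The importance ranking recovers the
two truly coupled annotations and the H-statistic isolates their
interaction.

The same pipeline is available from the shell via `exec/palm`:

```sh
exec/palm simulate --case B --M 20000 --L 50 --seed 1 --out-prefix sim
exec/palm fit --sumstats sim.sumstats.tsv --annot sim.annot.tsv \
              --depth 2 --cv-folds 5 --fdr 0.1 --seed 1 --out-prefix fit
exec/palm importance --model fit.model.json --annot sim.annot.tsv \
              --pairs --out-prefix imp
```

`fit` writes a per-SNP results table (snp, p, prior, posterior, local_fdr,
global_Fdr_rank, rejected), the serialized model (JSON) and a run
manifest with option values and input checksums.

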