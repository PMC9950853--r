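Package: palm
Title: Prioritizing GWAS Risk Variants with Functional Annotations via a
    Tree-Ensemble Two-Groups Model
Version: 0.1.0
Authors@R:
    person("PALM", "Maintainers", email = "palm@example.org", role = c("aut", "cre"))
Description: Implements PALM, a covariate-modulated two-groups model for
    genome-wide association study (GWAS) summary statistics. P-values arise
    from a uniform null component or a Beta(alpha, 1) non-null component,
    and the per-SNP prior probability of association is modulated by
    functional annotations through a gradient-boosted ensemble of shallow
    regression trees on the logit scale. The ensemble is fitted by a
    functional-gradient EM algorithm whose M-step adds one tree fitted to
    the first and second derivatives of the expected complete-data
    log-likelihood; the number of trees is chosen by K-fold
    cross-validation. Missing annotation values are handled by learned
    per-split default directions (sparsity-aware split finding). The
    package provides local and global false discovery rate control by the
    direct posterior probability approach, gain-based annotation
    importance, Friedman's H-statistic for pairwise annotation
    interactions, a seedable simulation benchmark, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
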