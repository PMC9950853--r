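# Seedable simulation benchmark: annotations uniform on (-1, 1), prior
# probabilities from five reference scenarios for the annotation-to-prior
# function F, latent Bernoulli association status, uniform null p-values,
# non-null p-values from a bimodal z-score mixture, configurable missing
# rates, and empirical FDR/power evaluation.

.CASE_MIN_L <- c(A = 0L, B = 2L, C = 2L, D = 5L, E = 2L)

#' True annotation-to-prior functions of the simulation scenarios
#'
#' Five reference scenarios on the logit scale:
#' \itemize{
#'   \item A: constant -3 (all annotations irrelevant; negative control)
#'   \item B: linear, -3 + 1.5 A1 + 1.5 A2
#'   \item C: quadratic with interaction, -4.25 + 2 A1^2 + 2 A2^2 - 2 A1 A2
#'   \item D: -4 + 4 sin(pi A1 A2) + 2 (A3 - A4)^2 + A4 + 0.5 A5
#'   \item E: piecewise in a binary A2: 1 - 6 A1^2 when A2 = 0,
#'         -1 + 2 A1 - 6 A1^2 when A2 = 1
#' }
#' The non-null prior is pi_j1 = sigmoid(F(A_j)).
#'
#' @param case one of "A".."E"
#' @param A annotation matrix (or single row)
#' @return numeric vector of F values, one per row
#' @export
true_F <- function(case, A) {
  case <- match.arg(case, c("A", "B", "C", "D", "E"))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (ncol(A) < .CASE_MIN_L[[case]])
    stop(sprintf("case %s needs at least %d annotation columns", case,
                 .CASE_MIN_L[[case]]))
  switch(case,
    A = rep(-3, nrow(A)),
    B = -3 + 1.5 * A[, 1] + 1.5 * A[, 2],
    C = -4.25 + 2 * A[, 1]^2 + 2 * A[, 2]^2 - 2 * A[, 1] * A[, 2],
    D = -4 + 4 * sin(pi * A[, 1] * A[, 2]) + 2 * (A[, 3] - A[, 4])^2 +
        A[, 4] + 0.5 * A[, 5],
    E = ifelse(A[, 2] == 0, 1 - 6 * A[, 1]^2,
               -1 + 2 * A[, 1] - 6 * A[, 1]^2))
}

#' Generate an annotation matrix
#'
#' Entries i.i.d. uniform on (-1, 1); for scenario E column 2 is replaced by
#' a Bernoulli(0.5) indicator in {0, 1}.
#'
#' @param M number of SNPs
#' @param L number of annotations (must cover the scenario's features)
#' @param case scenario id "A".."E"
#' @param seed integer seed (generation is a pure function of it)
#' @return M x L matrix with columns A1..AL
#' @export
gen_annotations <- function(M, L, case = "A", seed = 1L) {
  case <- match.arg(case, c("A", "B", "C", "D", "E"))
  if (L < .CASE_MIN_L[[case]])
    stop(sprintf("case %s needs at least %d annotation columns", case,
                 .CASE_MIN_L[[case]]))
  set.seed(seed)
  A <- matrix(runif(M * L, -1, 1), nrow = M, ncol = L,
              dimnames = list(NULL, paste0("A", seq_len(L))))
  if (case == "E") A[, 2] <- rbinom(M, 1L, 0.5)
  A
}

#' Draw latent association status
#'
#' Z_j ~ Bernoulli(pi_j1), independently.
#'
#' @param pi1 prior non-null probabilities in [0, 1]
#' @param seed integer seed
#' @return logical vector
#' @export
gen_status <- function(pi1, seed = 1L) {
  set.seed(seed)
  rbinom(length(pi1), 1L, pi1) == 1L
}

#' Default non-null z-score mixture (bimodal)
#'
#' mu ~ 0.48 N(-2, 1) + 0.04 N(0, 16) + 0.48 N(2, 1); z ~ N(mu, 1);
#' p = 2 (1 - Phi(|z|)). Deliberately different from the model's Beta(alpha,
#' 1) non-null so simulations probe robustness to misspecification.
#'
#' @return list(weights, means, sds) accepted by [gen_pvalues()]
#' @export
bimodal_mixture <- function() {
  list(weights = c(0.48, 0.04, 0.48), means = c(-2, 0, 2), sds = c(1, 4, 1))
}

#' Generate p-values given association status
#'
#' Null entries are U(0, 1); non-null entries draw a mixture component for
#' mu, then z ~ N(mu, 1) and p = 2 (1 - Phi(|z|)). Alternative normal
#' mixtures may be supplied as \code{dist}.
#'
#' @param Z logical association status
#' @param dist list(weights, means, sds); weights must sum to 1
#' @param seed integer seed
#' @return list with \code{p} (clipped p-values) and \code{z} (z-scores for
#'   non-null entries, NA elsewhere)
#' @export
gen_pvalues <- function(Z, dist = bimodal_mixture(), seed = 1L) {
  if (abs(sum(dist$weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  set.seed(seed)
  M <- length(Z)
  p <- numeric(M)
  z <- rep(NA_real_, M)
  n0 <- sum(!Z)
  n1 <- sum(Z)
  p[!Z] <- runif(n0)
  if (n1 > 0) {
    comp <- sample.int(length(dist$weights), n1, replace = TRUE,
                       prob = dist$weights)
    mu <- rnorm(n1, dist$means[comp], dist$sds[comp])
    zz <- rnorm(n1, mu, 1)
    z[Z] <- zz
    p[Z] <- 2 * pnorm(-abs(zz))
  }
  list(p = clip_pvalues(p), z = z)
}

#' Inject missing values into an annotation matrix
#'
#' Each entry is independently set missing with probability \code{mrate}.
#'
#' @param A annotation matrix
#' @param mrate missing rate in [0, 1)
#' @param seed integer seed
#' @return matrix with NA entries
#' @export
inject_missing <- function(A, mrate, seed = 1L) {
  stopifnot(mrate >= 0, mrate < 1)
  if (mrate == 0) return(A)
  set.seed(seed)
  A[matrix(runif(length(A)) < mrate, nrow = nrow(A))] <- NA_real_
  A
}

#' Simulate a complete benchmark dataset
#'
#' Sub-seeds for annotations, status, p-values and the missing mask are
#' derived from the single \code{seed} through named streams, so each
#' component is independently reproducible.
#'
#' @param M number of SNPs
#' @param L number of annotations
#' @param case scenario id "A".."E"
#' @param mrate annotation missing rate in [0, 1)
#' @param seed top-level seed
#' @param dist non-null z-score mixture (default bimodal)
#' @return object of class \code{palm_sim}: list(A, Z, pi1_true, p, z,
#'   case, mrate, seed); A carries the missing mask, pi1_true the exact
#'   priors used for Z
#' @export
simulate_dataset <- function(M, L, case = "A", mrate = 0, seed = 1L,
                             dist = bimodal_mixture()) {
  A <- gen_annotations(M, L, case, derive_seed(seed, "annotations"))
  pi1 <- sigmoid(true_F(case, A))
  Z <- gen_status(pi1, derive_seed(seed, "status"))
  pv <- gen_pvalues(Z, dist, derive_seed(seed, "pvalues"))
  A_obs <- inject_missing(A, mrate, derive_seed(seed, "missing"))
  structure(list(A = A_obs, A_full = A, Z = Z, pi1_true = pi1, p = pv$p,
                 z = pv$z, case = case, mrate = mrate, seed = seed),
            class = "palm_sim")
}

#' Empirical FDR and power of one replicate
#'
#' fdp = falsely rejected / max(1, rejected) (0 when nothing is rejected);
#' power = correctly rejected / truly non-null (NA when there are no true
#' non-nulls).
#'
#' @param Z logical truth
#' @param rejected logical rejection vector
#' @param method optional method label
#' @return one-row data.frame: method, fdp, power, n_rejected
#' @export
evaluate_replicate <- function(Z, rejected, method = NA_character_) {
  stopifnot(length(Z) == length(rejected))
  nr <- sum(rejected)
  fdp <- if (nr == 0) 0 else sum(rejected & !Z) / nr
  pw <- if (sum(Z) == 0) NA_real_ else sum(rejected & Z) / sum(Z)
  data.frame(method = method, fdp = fdp, power = pw,
             n_rejected = as.integer(nr), stringsAsFactors = FALSE)
}

# Inference for the intercept-only baseline on one dataset.
.tgm_reject <- function(p, tau) {
  tgm <- fit_tgm(p)
  lfdr <- 1 - posterior_responsibility(clip_pvalues(p), tgm$pi1, tgm$alpha)
  global_fdr_select(lfdr, tau)$rejected
}

#' Run the simulation study
#'
#' For each scenario and replicate, simulates a dataset and evaluates the
#' requested methods at nominal global FDR \code{config$tau}: "PALM-D1" and
#' "PALM-D2" (full cross-validated fits at depth 1/2), "TGM" (intercept-only
#' two-groups model with the same posterior FDR rule) and "BH". Per-replicate
#' seeds derive from \code{seed} and the case label.
#'
#' @param cases character vector of scenario ids
#' @param M,L problem size per replicate
#' @param methods subset of c("PALM-D1", "PALM-D2", "TGM", "BH")
#' @param n_reps replicates per scenario
#' @param seed top-level seed
#' @param config a [palm_config()]; depth is overridden per PALM method
#' @param mrate annotation missing rate
#' @param dist non-null z-score mixture
#' @param verbose print one line per replicate
#' @return long-format data.frame (case, M, L, mrate, method, replicate,
#'   fdp, power, n_rejected, T_opt, alpha_hat, max_importance,
#'   max_total_gain, min_ll_delta, runtime); PALM rows carry the fitted
#'   diagnostics
#' @export
run_study <- function(cases = c("A", "B", "C", "D", "E"), M = 20000L,
                      L = 50L,
                      methods = c("PALM-D1", "PALM-D2", "TGM", "BH"),
                      n_reps = 20L, seed = 1L, config = palm_config(),
                      mrate = 0, dist = bimodal_mixture(),
                      verbose = FALSE) {
  rows <- list()
  for (case in cases) {
    for (r in seq_len(n_reps)) {
      rep_seed <- derive_seed(seed, paste0("case", case, "rep", r))
      sim <- simulate_dataset(M, L, case, mrate, rep_seed, dist)
      for (method in methods) {
        t0 <- proc.time()[["elapsed"]]
        T_opt <- NA_integer_; alpha_hat <- NA_real_
        max_imp <- NA_real_; max_gain <- NA_real_; min_dll <- NA_real_
        if (method %in% c("PALM-D1", "PALM-D2")) {
          cfg <- config
          cfg$depth <- if (method == "PALM-D1") 1L else 2L
          cfg$seed <- rep_seed
          model <- palm_fit(sim$p, sim$A, cfg)
          rej <- posterior_inference(model, sim$p, sim$A,
                                     tau = config$tau)$rejected
          T_opt <- attr(model, "T_opt")
          alpha_hat <- model$alpha
          imp <- variable_importance(model)
          max_imp <- max(imp$importance)
          # total accumulated gain: T-free scale, comparable across fits
          max_gain <- if (length(model$trees)) max(colSums(model$gain)) else 0
          ll <- attr(model, "trace")$loglik
          min_dll <- if (length(ll) > 1) min(diff(ll)) else 0
        } else if (method == "TGM") {
          rej <- .tgm_reject(sim$p, config$tau)
        } else if (method == "BH") {
          rej <- bh_procedure(sim$p, config$tau)
        } else stop("unknown method: ", method)
        met <- evaluate_replicate(sim$Z, rej, method)
        met$case <- case; met$M <- M; met$L <- L; met$mrate <- mrate
        met$replicate <- r; met$T_opt <- T_opt; met$alpha_hat <- alpha_hat
        met$max_importance <- max_imp; met$max_total_gain <- max_gain
        met$min_ll_delta <- min_dll
        met$runtime <- proc.time()[["elapsed"]] - t0
        rows[[length(rows) + 1L]] <- met
        if (verbose)
          message(sprintf(
            "case %s rep %d %-8s fdp=%.3f power=%.3f k=%d (%.1fs)",
            case, r, method, met$fdp, met$power, met$n_rejected,
            met$runtime))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("case", "M", "L", "mrate", "method", "replicate", "fdp", "power",
          "n_rejected", "T_opt", "alpha_hat", "max_importance",
          "max_total_gain", "min_ll_delta", "runtime")]
}
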