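# Two-groups model primitives: the beta/uniform mixture for p-values, its
# posteriors, the closed-form alpha update, and the intercept-only baseline.

.ALPHA_EPS <- 1e-6

#' Beta(alpha, 1) density
#'
#' Density of the non-null p-value component, phi(p; alpha) = alpha *
#' p^(alpha - 1). For alpha < 1 this is strictly decreasing in p, encoding
#' that associated SNPs have p-values concentrated near 0.
#'
#' @param p p-values in (0, 1]; values <= 0 are rejected (they signal
#'   un-clipped input, see [clip_pvalues()])
#' @param alpha shape parameter in (0, 1]
#' @return nonnegative density values
#' @export
beta_density <- function(p, alpha) {
  if (any(p <= 0)) stop("p-values must be > 0; clip input first")
  if (any(p > 1)) stop("p-values must be <= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  alpha * as.vector(p)^(alpha - 1)
}

#' Posterior probability of association (E-step responsibility)
#'
#' q_j1 = pi_j1 phi(p_j; alpha) / (pi_j0 + pi_j1 phi(p_j; alpha)), the
#' posterior probability that SNP j is non-null given its p-value and prior.
#'
#' @param p p-values in (0, 1]
#' @param pi1 prior non-null probabilities, length 1 or length(p), in [0, 1]
#' @param alpha non-null beta shape in (0, 1]
#' @return vector of posterior probabilities q1 in [0, 1]
#' @export
posterior_responsibility <- function(p, pi1, alpha) {
  phi <- beta_density(p, alpha)
  num <- pi1 * phi
  num / ((1 - pi1) + num)
}

#' Closed-form M-step update of alpha
#'
#' Maximizes the expected complete-data log-likelihood in alpha:
#' alpha = -sum(q1) / sum(q1 * log p), clamped into (1e-6, 1 - 1e-6).
#' If the non-null mass sum(q1) is zero the previous alpha is returned
#' unchanged with a warning.
#'
#' @param q1 posterior responsibilities in [0, 1]
#' @param p p-values in (0, 1]
#' @param alpha_prev fallback value when sum(q1) == 0
#' @return updated alpha in (1e-6, 1 - 1e-6)
#' @export
update_alpha <- function(q1, p, alpha_prev = 0.5) {
  s <- sum(q1)
  if (s <= 0) {
    warning("no non-null mass (sum(q1) == 0); keeping previous alpha")
    return(alpha_prev)
  }
  a <- -s / sum(q1 * log(p))
  min(max(a, .ALPHA_EPS), 1 - .ALPHA_EPS)
}

#' Marginal log-likelihood of the two-groups mixture
#'
#' sum_j log(pi_j0 + pi_j1 phi(p_j; alpha)) — the EM objective.
#'
#' @inheritParams posterior_responsibility
#' @return a finite scalar; non-finite results signal p = 0 leakage
#' @export
marginal_loglik <- function(p, pi1, alpha) {
  ll <- sum(log((1 - pi1) + pi1 * beta_density(p, alpha)))
  if (!is.finite(ll)) stop("non-finite marginal log-likelihood")
  ll
}

#' Intercept-only two-groups model (TGM baseline)
#'
#' EM fit of the beta/uniform mixture with a common prior pi1 for all SNPs:
#' E-step computes responsibilities, M-step sets pi1 to their mean and alpha
#' to its closed-form maximizer. Used both as the annotation-free baseline
#' (TGM-Pval) and to initialize the boosted model's intercept f0 =
#' logit(pi1).
#'
#' @param p p-values in (0, 1]; clipped on ingest
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations
#' @param pi1_init,alpha_init neutral mid-range starting values
#' @return a list of class \code{palm_tgm} with elements \code{pi1},
#'   \code{alpha}, \code{loglik} (trace), \code{converged}, \code{n_iter}
#' @export
fit_tgm <- function(p, tol = 1e-8, max_iter = 1000L,
                    pi1_init = 0.1, alpha_init = 0.5) {
  p <- clip_pvalues(p)
  if (length(p) < 2) stop("need at least 2 p-values")
  pi1 <- pi1_init
  alpha <- alpha_init
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  logp <- log(p)
  for (it in seq_len(max_iter)) {
    q1 <- posterior_responsibility(p, pi1, alpha)
    alpha <- update_alpha(q1, p, alpha)
    pi1 <- mean(q1)
    pi1 <- min(max(pi1, 1e-12), 1 - 1e-12)
    ll <- marginal_loglik(p, pi1, alpha)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(list(pi1 = pi1, alpha = alpha, loglik = trace,
                 converged = converged, n_iter = length(trace)),
            class = "palm_tgm")
}

#' @export
print.palm_tgm <- function(x, ...) {
  cat(sprintf(
    "Two-groups model (intercept only): pi1 = %.4f, alpha = %.4f (%s, %d iter)\n",
    x$pi1, x$alpha, if (x$converged) "converged" else "NOT converged",
    x$n_iter))
  invisible(x)
}
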