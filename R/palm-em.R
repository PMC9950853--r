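# Functional-gradient EM driver: alternate posterior E-steps with one-tree
# boosting M-steps; select the number of trees by K-fold cross-validation on
# the held-out marginal log-likelihood; refit on all data.

#' PALM configuration
#'
#' @param depth tree depth D (1 = additive "PALM-D1", 2 = pairwise
#'   interactions "PALM-D2")
#' @param nu shrinkage (learning rate) in (0, 1); default 0.1
#' @param cv_folds K for cross-validation; default 5
#' @param max_trees search horizon for the number of boosting rounds
#' @param tau nominal global FDR level in (0, 1)
#' @param seed top-level seed; all sub-streams derive from it
#' @param min_child_weight minimum hessian mass per child in tree fitting
#' @param lambda L2 leaf penalty
#' @param early_stop stop the CV search after this many consecutive trees
#'   without improvement of the mean held-out log-likelihood
#' @param cv_rule how to pick T from the held-out curve: \code{"1se"}
#'   (default) takes the smallest tree count whose held-out log-likelihood
#'   is within one standard error of the best, with the SE computed from
#'   per-SNP paired differences between the best and the tree-free model;
#'   this is robust to selection noise on flat curves, so negative controls
#'   keep zero trees. \code{"max"} takes the plain argmax
#' @param em_inner reserved policy flag (one tree per EM iteration; inner
#'   Newton iterations are not performed)
#' @return a list of class \code{palm_config}
#' @export
palm_config <- function(depth = 1L, nu = 0.1, cv_folds = 5L,
                        max_trees = 500L, tau = 0.1, seed = 1L,
                        min_child_weight = 1.0, lambda = 1.0,
                        early_stop = 50L, cv_rule = c("1se", "max"),
                        em_inner = FALSE) {
  stopifnot(depth >= 1, nu > 0, nu < 1, cv_folds >= 2, max_trees >= 0,
            tau > 0, tau < 1, early_stop >= 1)
  cv_rule <- match.arg(cv_rule)
  structure(list(depth = as.integer(depth), nu = nu,
                 cv_folds = as.integer(cv_folds),
                 max_trees = as.integer(max_trees), tau = tau,
                 seed = as.integer(seed),
                 min_child_weight = min_child_weight, lambda = lambda,
                 early_stop = as.integer(early_stop), cv_rule = cv_rule,
                 em_inner = em_inner),
            class = "palm_config")
}

# One EM-boosting state: holds everything needed to advance one iteration.
.boost_state_init <- function(p, A, config) {
  p <- clip_pvalues(p)
  tgm <- fit_tgm(p)
  list(p = p, A = A, presort = presort_annotations(A),
       F = rep(qlogis(tgm$pi1), length(p)), alpha = tgm$alpha,
       tgm = tgm, f0 = qlogis(tgm$pi1), trees = list(),
       config = config)
}

# Advance the state by one EM iteration: E-step, closed-form alpha update,
# gradient/hessian, fit one tree, append with shrinkage. Returns the state.
.boost_state_step <- function(st) {
  cfg <- st$config
  pi1 <- sigmoid(st$F)
  q1 <- posterior_responsibility(st$p, pi1, st$alpha)
  st$alpha <- update_alpha(q1, st$p, st$alpha)
  gh <- compute_grad_hess(q1, st$F)
  tree <- fit_tree(st$A, gh$g, gh$h, depth = cfg$depth,
                   min_child_weight = cfg$min_child_weight,
                   lambda = cfg$lambda, presort = st$presort)
  st$F <- st$F + cfg$nu * predict_tree(tree, st$A)
  st$trees[[length(st$trees) + 1L]] <- tree
  st
}

#' Fit the boosted two-groups model with a fixed number of trees
#'
#' Initializes (pi1, alpha) from the intercept-only fit and sets
#' f0 = logit(pi1_hat); then runs T EM iterations, each consisting of an
#' E-step, the closed-form alpha update, and one boosting M-step that adds a
#' regression tree fitted to the Q-function's first and second derivatives,
#' shrunk by nu. With T = 0 the model reduces exactly to the TGM baseline.
#'
#' @param p p-values (clipped on ingest)
#' @param A annotation matrix, rows aligned with \code{p}; NA = missing
#' @param config a [palm_config()]
#' @param T number of trees (EM iterations) to add
#' @return list with elements \code{model} (a \code{palm_model}) and
#'   \code{trace} (class \code{palm_trace}: per-iteration marginal
#'   log-likelihood and alpha, plus \code{selected_T})
#' @export
em_boost_fit <- function(p, A, config = palm_config(), T = 100L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (nrow(A) != length(p)) stop("rows of A must align with p")
  st <- .boost_state_init(p, A, config)
  ll <- numeric(T + 1L)
  al <- numeric(T + 1L)
  ll[1] <- marginal_loglik(st$p, sigmoid(st$F), st$alpha)
  al[1] <- st$alpha
  for (t in seq_len(T)) {
    st <- .boost_state_step(st)
    lli <- sum(log((1 - sigmoid(st$F)) +
                     sigmoid(st$F) * st$alpha * st$p^(st$alpha - 1)))
    if (!is.finite(lli))
      stop(sprintf("non-finite marginal log-likelihood at iteration %d", t))
    ll[t + 1L] <- lli
    al[t + 1L] <- st$alpha
  }
  model <- palm_model(st$f0, st$trees, config$nu, st$alpha,
                      columns = colnames(A), depth = config$depth)
  trace <- structure(list(loglik = ll, alpha = al, selected_T = T),
                     class = "palm_trace")
  list(model = model, trace = trace)
}

#' Select the number of trees by K-fold cross-validation
#'
#' SNP indices are shuffled with a seed derived from \code{config$seed}
#' (sub-stream "cv") and cut into K contiguous blocks. All folds are boosted
#' in lockstep; after each round t every fold's held-out marginal
#' log-likelihood is evaluated with that fold's current alpha estimate and
#' ensemble truncated at t trees. The search stops early once the mean
#' held-out curve has not improved for \code{config$early_stop} consecutive
#' trees. T is then chosen from the mean curve by \code{config$cv_rule}:
#' the one-standard-error rule (default) or the plain argmax (t = 0, the
#' annotation-free model, is a permitted optimum under both rules).
#'
#' @inheritParams em_boost_fit
#' @return integer T_opt with attributes \code{cv_curve} (mean held-out
#'   log-likelihood per tree count, starting at 0 trees) and
#'   \code{fold_curves}
#' @export
select_num_trees_cv <- function(p, A, config = palm_config()) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  M <- length(p)
  K <- config$cv_folds
  if (M < 2 * K) stop("need at least 2 observations per fold")
  set.seed(derive_seed(config$seed, "cv"))
  perm <- sample.int(M)
  # contiguous blocks of the shuffled index
  fold_id <- integer(M)
  bounds <- floor(seq(0, M, length.out = K + 1))
  for (k in seq_len(K)) fold_id[perm[(bounds[k] + 1):bounds[k + 1]]] <- k

  p <- clip_pvalues(p)
  states <- vector("list", K)
  tests <- vector("list", K)
  Ftest <- vector("list", K)
  curves <- matrix(NA_real_, nrow = config$max_trees + 1L, ncol = K)
  for (k in seq_len(K)) {
    tr <- which(fold_id != k)
    te <- which(fold_id == k)
    states[[k]] <- .boost_state_init(p[tr], A[tr, , drop = FALSE], config)
    tests[[k]] <- list(p = p[te], A = A[te, , drop = FALSE])
    Ftest[[k]] <- rep(states[[k]]$f0, length(te))
    curves[1L, k] <- marginal_loglik(tests[[k]]$p, sigmoid(Ftest[[k]]),
                                     states[[k]]$alpha)
  }
  best_mean <- mean(curves[1L, ])
  best_t <- 0L
  t_used <- 0L
  Fbest <- Ftest
  F0 <- Ftest
  alpha_best <- vapply(states, `[[`, numeric(1), "alpha")
  alpha0 <- alpha_best
  for (t in seq_len(config$max_trees)) {
    for (k in seq_len(K)) {
      states[[k]] <- .boost_state_step(states[[k]])
      newtree <- states[[k]]$trees[[t]]
      Ftest[[k]] <- Ftest[[k]] + config$nu * predict_tree(newtree,
                                                          tests[[k]]$A)
      curves[t + 1L, k] <- marginal_loglik(tests[[k]]$p, sigmoid(Ftest[[k]]),
                                           states[[k]]$alpha)
    }
    t_used <- t
    ok <- is.finite(curves[t + 1L, ])
    if (!all(ok)) warning("dropping degenerate fold(s) from the CV mean")
    m <- mean(curves[t + 1L, ok])
    if (m > best_mean) {
      best_mean <- m
      best_t <- t
      Fbest <- Ftest
      alpha_best <- vapply(states, `[[`, numeric(1), "alpha")
    }
    if (t - best_t >= config$early_stop) break
  }
  curves <- curves[seq_len(t_used + 1L), , drop = FALSE]
  means <- rowMeans(curves, na.rm = TRUE)
  T_opt <- if (config$cv_rule == "1se" && best_t > 0L) {
    # Paired per-SNP SE of the held-out log-likelihood difference between
    # the best model and the tree-free model: the candidate-wise variance
    # of sum_j [ll_j(best) - ll_j(0)]. A fold-based SE would have K - 1
    # degrees of freedom (a single df at K = 2) and occasionally collapses,
    # letting correlated noise drift keep spurious trees on null data.
    var_sum <- 0
    for (k in seq_len(K)) {
      pk <- tests[[k]]$p
      a0 <- alpha0[k]
      d <- log((1 - sigmoid(Fbest[[k]])) +
                 sigmoid(Fbest[[k]]) * alpha_best[k] * pk^(alpha_best[k] - 1)) -
           log((1 - sigmoid(F0[[k]])) +
                 sigmoid(F0[[k]]) * a0 * pk^(a0 - 1))
      var_sum <- var_sum + length(d) * stats::var(d)
    }
    se_pw <- sqrt(var_sum)
    # summed (= K * mean) improvement curve, threshold one SE below best
    S <- K * (means - means[1L])
    min(which(S >= S[best_t + 1L] - se_pw)) - 1L
  } else best_t
  structure(as.integer(T_opt), cv_curve = means, fold_curves = curves,
            T_max = best_t)
}

#' Fit PALM: cross-validated tree count, then refit on all data
#'
#' Runs [select_num_trees_cv()] to pick T_opt, then [em_boost_fit()] with
#' exactly T_opt trees on the full dataset (alpha re-estimated from
#' scratch).
#'
#' @inheritParams em_boost_fit
#' @return a \code{palm_model} with attributes \code{trace} (the refit
#'   trace), \code{T_opt} and \code{cv_curve}
#' @export
palm_fit <- function(p, A, config = palm_config()) {
  T_opt <- select_num_trees_cv(p, A, config)
  fit <- em_boost_fit(p, A, config, T = as.integer(T_opt))
  model <- fit$model
  attr(model, "trace") <- fit$trace
  attr(model, "T_opt") <- as.integer(T_opt)
  attr(model, "cv_curve") <- attr(T_opt, "cv_curve")
  model
}
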