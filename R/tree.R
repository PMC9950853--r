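# Depth-limited weighted regression trees fit to (gradient, hessian) data,
# the ensemble container, and predictors. The split objective is the
# second-order approximation of the EM Q-function: maximizing
# sum_j (1/2) h_j [-g_j/h_j - f(A_j)]^2 over trees f is equivalent to a
# weighted least-squares fit with positive weights -h_j and pseudo-targets
# -g_j/h_j; we work directly with per-node aggregates (sum g, sum -h) so
# division by vanishing hessians never occurs. Missing annotation values are
# handled by sparsity-aware split finding: both routings of the missing rows
# are scored and the better one becomes the split's default direction.

#' Gradient and hessian of the Q-function at the current ensemble
#'
#' g_j = q_j1 - sigmoid(F_j), h_j = -sigmoid(F_j) (1 - sigmoid(F_j)).
#' h_j lies in [-0.25, 0).
#'
#' @param q1 posterior responsibilities from the E-step
#' @param F current ensemble scores F(A_j)
#' @return list with numeric vectors \code{g} and \code{h}
#' @export
compute_grad_hess <- function(q1, F) {
  if (length(q1) != length(F)) stop("length mismatch")
  s <- sigmoid(F)
  list(g = q1 - s, h = -s * (1 - s))
}

#' Pre-sort annotation columns for repeated tree fitting
#'
#' Computes, once per matrix, the row order of each column (missing entries
#' set aside) so that every boosting round scans columns in sorted order in
#' O(M) instead of re-sorting.
#'
#' @param A numeric annotation matrix (NA = missing)
#' @return opaque presort object consumed by [fit_tree()]
#' @export
presort_annotations <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  ps <- cpp_presort(A)
  ps$dim <- dim(A)
  ps
}

#' Fit one regression tree to (gradient, hessian) data
#'
#' Exact greedy search over all midpoints of sorted unique feature values.
#' Leaf values are the Newton step sum(g) / (sum(-h) + lambda). A split is
#' kept only if it improves the objective and both children carry at least
#' \code{min_child_weight} of hessian mass. Ties among equal-gain splits are
#' broken by lowest feature index, then smallest threshold, then
#' missing-direction left, so fits are fully deterministic.
#'
#' @param A numeric matrix M x L, NA = missing
#' @param g gradient vector (length M)
#' @param h hessian vector, strictly negative (length M)
#' @param depth maximum tree depth (number of split levels); depth 1 = stump
#' @param min_child_weight minimum sum(-h) per child
#' @param lambda L2 penalty on leaf values
#' @param presort optional [presort_annotations()] result for \code{A}
#' @return an object of class \code{palm_tree}: node arrays
#'   (\code{feature} 0-based or -1 for leaf, \code{threshold},
#'   \code{default_left}, \code{left}, \code{right}, \code{value}) plus a
#'   \code{gain} vector of per-feature objective reductions
#' @export
fit_tree <- function(A, g, h, depth = 1L, min_child_weight = 1.0,
                     lambda = 1.0, presort = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (length(g) != nrow(A) || length(h) != nrow(A)) stop("length mismatch")
  if (any(h >= 0)) stop("hessian entries must be strictly negative")
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(presort)) presort <- presort_annotations(A)
  tr <- cpp_fit_tree(A, presort$ord, presort$miss, presort$vals,
                     as.numeric(g), -as.numeric(h), as.integer(depth),
                     min_child_weight, lambda)
  structure(tr, class = "palm_tree")
}

#' Predict a single tree
#'
#' Deterministic traversal; a missing feature value routes to the split's
#' learned default direction.
#'
#' @param tree a \code{palm_tree}
#' @param A numeric matrix (or single row) with the fitting L columns
#' @return numeric vector of leaf values, one per row
#' @export
predict_tree <- function(tree, A) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  cpp_predict_tree(unclass(tree), A)
}

#' Construct a tree-ensemble model
#'
#' F(A_j) = f0 + nu * sum_t tree_t(A_j); the fitted alpha completes the
#' two-groups model so that pi_j1 = sigmoid(F(A_j)).
#'
#' @param f0 intercept (logit of the intercept-only prior)
#' @param trees list of \code{palm_tree} objects
#' @param nu shrinkage (learning rate) in (0, 1)
#' @param alpha fitted beta shape
#' @param columns annotation column names (length L)
#' @param depth tree depth used in fitting
#' @return object of class \code{palm_model}; per-tree gains are exposed as
#'   a T x L matrix in \code{$gain}
#' @export
palm_model <- function(f0, trees = list(), nu = 0.1, alpha = 0.5,
                       columns = NULL, depth = 1L) {
  L <- length(columns)
  gain <- matrix(0, nrow = length(trees), ncol = L,
                 dimnames = list(NULL, columns))
  for (t in seq_along(trees)) gain[t, ] <- trees[[t]]$gain
  structure(list(f0 = f0, trees = trees, nu = nu, alpha = alpha,
                 columns = columns, depth = as.integer(depth), gain = gain),
            class = "palm_model")
}

#' Evaluate the ensemble score F
#'
#' @param model a \code{palm_model}
#' @param A annotation matrix with \code{length(model$columns)} columns
#' @param n_trees optional truncation: use only the first n trees
#'   (n_trees = 0 gives the intercept-only prediction)
#' @return numeric vector F(A_j) = f0 + nu * sum_(t<=n_trees) tree_t(A_j)
#' @export
predict_ensemble <- function(model, A, n_trees = NULL) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (ncol(A) != length(model$columns))
    stop("annotation matrix has wrong number of columns")
  if (is.null(n_trees)) n_trees <- length(model$trees)
  if (n_trees > length(model$trees)) stop("n_trees exceeds ensemble size")
  cpp_predict_ensemble(lapply(model$trees, unclass), A, model$f0, model$nu,
                       as.integer(n_trees))
}

#' @export
#' @method predict palm_model
predict.palm_model <- function(object, newdata, n_trees = NULL,
                               type = c("link", "prior"), ...) {
  type <- match.arg(type)
  F <- predict_ensemble(object, newdata, n_trees)
  if (type == "prior") sigmoid(F) else F
}

#' @export
print.palm_model <- function(x, ...) {
  cat(sprintf(
    "PALM tree-ensemble model: %d trees (depth %d), nu = %g, alpha = %.4f, f0 = %.4f\n",
    length(x$trees), x$depth, x$nu, x$alpha, x$f0))
  cat(sprintf("  %d annotations\n", length(x$columns)))
  invisible(x)
}
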