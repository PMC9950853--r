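# Annotation ranking: gain importance averaged over trees, and Friedman's
# H-statistic for pairwise interactions.

#' Gain-based annotation importance
#'
#' I_l = (1/T) sum_t I_(t,l), where I_(t,l) is the total split-objective
#' reduction tree t achieved by splitting on annotation l (recorded during
#' fitting). An annotation never split on has importance exactly 0; a model
#' with no trees has all-zero importance. The normalized column rescales to
#' max = 1 for display.
#'
#' @param model fitted \code{palm_model}
#' @return object of class \code{palm_importance}: a data.frame with
#'   columns annotation, importance, normalized
#' @export
variable_importance <- function(model) {
  L <- length(model$columns)
  T <- length(model$trees)
  I <- if (T == 0L) rep(0, L) else colMeans(model$gain)
  mx <- max(I)
  norm <- if (mx > 0) I / mx else rep(0, L)
  structure(data.frame(annotation = model$columns %||%
                         paste0("A", seq_len(L)),
                       importance = as.numeric(I),
                       normalized = as.numeric(norm),
                       stringsAsFactors = FALSE),
            class = c("palm_importance", "data.frame"))
}

#' Friedman-Popescu H-statistic for a pair of annotations
#'
#' Quantifies how much of the ensemble's joint partial dependence on
#' annotations (l1, l2) is not explained additively by the two one-variable
#' partial dependences: the variance of the centered difference divided by
#' the variance of the centered two-variable partial dependence (the
#' squared H of Friedman and Popescu, in [0, 1]). Partial dependences are
#' averaged over the empirical distribution of the remaining annotations
#' using \code{n_grid} subsampled rows, which also serve as evaluation
#' points. Rows missing either annotation are dropped for the pair. Depth-1
#' ensembles are additive, so H is exactly 0 for every pair.
#'
#' @param model fitted \code{palm_model}
#' @param A annotation matrix (typically the fitting data)
#' @param l1,l2 distinct column indices (1-based)
#' @param n_grid number of rows to subsample for the evaluation
#' @param seed seed for the subsample
#' @return H in [0, 1]; 0 with a warning when the joint partial dependence
#'   has zero variance
#' @export
h_statistic <- function(model, A, l1, l2, n_grid = 2000L, seed = 1L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (l1 == l2) stop("l1 and l2 must differ")
  keep <- which(!is.na(A[, l1]) & !is.na(A[, l2]))
  if (length(keep) == 0) {
    warning("no rows with both annotations observed; H undefined, returning 0")
    return(0)
  }
  if (length(keep) > n_grid) {
    set.seed(derive_seed(seed, "hstat"))
    keep <- sort(sample(keep, n_grid))
  }
  h <- cpp_h_statistic(lapply(model$trees, unclass),
                       A[keep, , drop = FALSE],
                       as.integer(l1 - 1L), as.integer(l2 - 1L))
  if (h < 0) {
    warning("joint partial dependence has zero variance; returning H = 0")
    return(0)
  }
  h
}

#' H-statistics for all pairs among a set of annotations
#'
#' @inheritParams h_statistic
#' @param which_cols column indices to pair up (default: the 5 highest
#'   gain-importance annotations)
#' @return data.frame with columns a1, a2, H
#' @export
h_pairs <- function(model, A, which_cols = NULL, n_grid = 2000L, seed = 1L) {
  if (is.null(which_cols)) {
    imp <- variable_importance(model)
    which_cols <- order(imp$importance, decreasing = TRUE)[
      seq_len(min(5L, nrow(imp)))]
  }
  cmb <- utils::combn(sort(which_cols), 2)
  out <- data.frame(
    a1 = model$columns[cmb[1, ]] %||% cmb[1, ],
    a2 = model$columns[cmb[2, ]] %||% cmb[2, ],
    H = apply(cmb, 2, function(pr)
      h_statistic(model, A, pr[1], pr[2], n_grid = n_grid, seed = seed)),
    stringsAsFactors = FALSE)
  out
}
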