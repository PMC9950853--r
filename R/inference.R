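# Local fdr, global FDR control by the direct posterior probability
# approach, and the Benjamini-Hochberg baseline.

#' Per-SNP local false discovery rate
#'
#' fdr_j = Pr(Z_j = 0 | p_j, A_j) = 1 - q_j1, with the prior taken from the
#' fitted ensemble, pi_j1 = sigmoid(F(A_j)).
#'
#' @param model fitted \code{palm_model}
#' @param p p-values (clipped on ingest)
#' @param A annotation matrix compatible with the model
#' @return numeric vector of local fdr values in [0, 1]
#' @export
local_fdr <- function(model, p, A) {
  p <- clip_pvalues(p)
  pi1 <- sigmoid(predict_ensemble(model, A))
  1 - posterior_responsibility(p, pi1, model$alpha)
}

#' Global FDR control by the direct posterior probability approach
#'
#' Sorts local fdr ascending and rejects the largest prefix whose mean local
#' fdr is at most tau. Ties are sorted stably by original index; when a tie
#' group straddles the prefix boundary the whole group is included iff doing
#' so keeps the prefix mean <= tau (deterministic and conservative).
#'
#' @param lfdr local fdr values in [0, 1]
#' @param tau nominal global FDR level in (0, 1)
#' @return list with \code{rejected} (logical vector), \code{k} (number of
#'   rejections), \code{order} (ascending-lfdr permutation) and
#'   \code{cum_Fdr} (prefix means in sorted order)
#' @export
global_fdr_select <- function(lfdr, tau) {
  stopifnot(tau > 0, tau < 1)
  M <- length(lfdr)
  ord <- order(lfdr, seq_len(M))
  sorted <- lfdr[ord]
  cum <- cumsum(sorted) / seq_len(M)
  ok <- which(cum <= tau)
  k <- if (length(ok)) max(ok) else 0L
  if (k > 0L && k < M && sorted[k] == sorted[k + 1L]) {
    v <- sorted[k]
    grp_last <- max(which(sorted == v))
    k <- if (cum[grp_last] <= tau) grp_last else min(which(sorted == v)) - 1L
  }
  rejected <- logical(M)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  list(rejected = rejected, k = as.integer(k), order = ord, cum_Fdr = cum)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard BH at level tau (inclusive at the boundary): rejects the k*
#' smallest p-values where k* = max(k : p_(k) <= k tau / M).
#'
#' @param p p-values
#' @param tau nominal FDR level in (0, 1)
#' @return logical rejection vector
#' @export
bh_procedure <- function(p, tau) {
  stopifnot(tau > 0, tau < 1)
  p.adjust(p, method = "BH") <= tau
}

#' Full posterior inference for a fitted model
#'
#' Combines the posterior, local fdr, and the global FDR selection into a
#' per-SNP results object; the per-rank prefix-mean global Fdr is reported
#' so users can re-threshold without refitting.
#'
#' @inheritParams local_fdr
#' @param tau nominal global FDR level
#' @param snp optional SNP identifiers
#' @return object of class \code{palm_result}; see
#'   \code{as.data.frame.palm_result} for the per-SNP table (columns snp, p,
#'   prior, posterior, local_fdr, global_Fdr_rank, rejected)
#' @export
posterior_inference <- function(model, p, A, tau = 0.1, snp = NULL) {
  p <- clip_pvalues(p)
  pi1 <- sigmoid(predict_ensemble(model, A))
  q1 <- posterior_responsibility(p, pi1, model$alpha)
  lfdr <- 1 - q1
  sel <- global_fdr_select(lfdr, tau)
  fdr_rank <- numeric(length(p))
  fdr_rank[sel$order] <- sel$cum_Fdr
  structure(list(snp = snp %||% paste0("snp", seq_along(p)),
                 p = as.numeric(p), prior = pi1, q1 = q1, local_fdr = lfdr,
                 order = sel$order, cum_Fdr = sel$cum_Fdr,
                 global_Fdr_rank = fdr_rank, rejected = sel$rejected,
                 k = sel$k, tau = tau),
            class = "palm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method as.data.frame palm_result
as.data.frame.palm_result <- function(x, ...) {
  data.frame(snp = x$snp, p = x$p, prior = x$prior, posterior = x$q1,
             local_fdr = x$local_fdr, global_Fdr_rank = x$global_Fdr_rank,
             rejected = as.integer(x$rejected), stringsAsFactors = FALSE)
}

#' @export
print.palm_result <- function(x, ...) {
  cat(sprintf("PALM inference: %d of %d SNPs rejected at global FDR %.3g\n",
              x$k, length(x$p), x$tau))
  invisible(x)
}
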