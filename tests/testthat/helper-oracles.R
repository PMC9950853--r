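# Independent brute-force oracles used to check the fast implementations.

# Exhaustive split search: every feature, every midpoint of sorted unique
# observed values, both missing directions. Mirrors the tie rules stated for
# the implementation: strictly-larger gain wins; at the same candidate point
# missing-left wins ties; candidates are visited feature-ascending then
# threshold-ascending.
oracle_split <- function(A, g, hn, rows, lambda, mcw) {
  G <- sum(g[rows]); H <- sum(hn[rows])
  parent <- G^2 / (H + lambda)
  best <- list(gain = 1e-12, feature = NA_integer_)
  for (l in seq_len(ncol(A))) {
    vals <- A[rows, l]
    obs <- rows[!is.na(vals)]
    mis <- rows[is.na(vals)]
    ov <- A[obs, l]
    uv <- sort(unique(ov))
    if (length(uv) < 2) next
    for (i in seq_len(length(uv) - 1)) {
      thr <- (uv[i] + uv[i + 1]) / 2
      lo <- obs[ov <= thr]
      ro <- obs[ov > thr]
      cand_gain <- function(lr, rr) {
        HL <- sum(hn[lr]); HR <- sum(hn[rr])
        if (HL < mcw || HR < mcw) return(-Inf)
        0.5 * (sum(g[lr])^2 / (HL + lambda) + sum(g[rr])^2 / (HR + lambda) -
                 parent)
      }
      g_right <- cand_gain(lo, c(ro, mis))
      g_left <- cand_gain(c(lo, mis), ro)
      dir_left <- g_left >= g_right
      gn <- max(g_left, g_right)
      if (gn > best$gain)
        best <- list(gain = gn, feature = l, threshold = thr,
                     miss_left = dir_left)
    }
  }
  if (is.na(best$feature)) NULL else best
}

# Recursive exhaustive tree fit; returns per-row predictions over the full
# matrix plus the per-feature gain vector.
oracle_fit_tree <- function(A, g, h, depth, lambda = 1, mcw = 1) {
  hn <- -h
  pred <- numeric(nrow(A))
  gain <- numeric(ncol(A))
  rec <- function(rows, d) {
    if (d == 0 || length(rows) == 0) {
      pred[rows] <<- sum(g[rows]) / (sum(hn[rows]) + lambda)
      return(invisible())
    }
    sp <- oracle_split(A, g, hn, rows, lambda, mcw)
    if (is.null(sp)) {
      pred[rows] <<- sum(g[rows]) / (sum(hn[rows]) + lambda)
      return(invisible())
    }
    gain[sp$feature] <<- gain[sp$feature] + sp$gain
    vals <- A[rows, sp$feature]
    left <- ifelse(is.na(vals), sp$miss_left, vals <= sp$threshold)
    rec(rows[left], d - 1)
    rec(rows[!left], d - 1)
  }
  rec(seq_len(nrow(A)), depth)
  list(pred = pred, gain = gain)
}

# Prefix-rule oracle for the direct posterior probability FDR control:
# enumerate every prefix of the (stably) sorted local fdr values, find the
# longest with mean <= tau, then apply the conservative tie-group rule.
oracle_global_fdr <- function(lfdr, tau) {
  M <- length(lfdr)
  ord <- order(lfdr, seq_len(M))
  s <- lfdr[ord]
  k <- 0L
  for (j in seq_len(M)) if (mean(s[seq_len(j)]) <= tau) k <- j
  if (k > 0L && k < M && s[k] == s[k + 1L]) {
    grp <- which(s == s[k])
    k <- if (mean(s[seq_len(max(grp))]) <= tau) max(grp) else min(grp) - 1L
  }
  rejected <- logical(M)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  list(k = k, rejected = rejected)
}

# Assign each row of A to a leaf of a fitted tree by direct traversal in R
# (independent of the C++ predictor).
r_tree_leaf <- function(tree, A) {
  vapply(seq_len(nrow(A)), function(j) {
    n <- 1L
    while (tree$feature[n] >= 0L) {
      v <- A[j, tree$feature[n] + 1L]
      left <- if (is.na(v)) tree$default_left[n] == 1L
              else v <= tree$threshold[n]
      n <- (if (left) tree$left[n] else tree$right[n]) + 1L
    }
    n
  }, integer(1))
}
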