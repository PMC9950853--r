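test_that("gradient and hessian follow the Q-function derivatives", {
  gh <- compute_grad_hess(1, 0)
  expect_equal(gh$g, 0.5, tolerance = 1e-10)
  expect_equal(gh$h, -0.25, tolerance = 1e-10)
  expect_equal(compute_grad_hess(0.5, 0)$g, 0, tolerance = 1e-10)
  gh <- compute_grad_hess(1, 20)
  expect_lt(abs(gh$g), 1e-8)
  expect_lt(abs(gh$h), 1e-8)
  set.seed(1)
  gh <- compute_grad_hess(runif(100), rnorm(100))
  expect_true(all(gh$h >= -0.25 & gh$h < 0))
})

test_that("zero gradient yields a single leaf with zero value and gains", {
  A <- matrix(runif(40), 20, 2)
  tr <- fit_tree(A, rep(0, 20), rep(-0.1, 20), depth = 2)
  expect_equal(sum(tr$feature >= 0), 0)
  expect_equal(predict_tree(tr, A), rep(0, 20))
  expect_equal(tr$gain, c(0, 0))
})

test_that("textbook stump: split between the two value groups", {
  # equal weights w = 0.5, targets y = g/w = c(-1,-1,1,1); no leaf penalty
  A <- matrix(c(-1, -1, 1, 1), ncol = 1)
  g <- c(-0.5, -0.5, 0.5, 0.5)
  h <- rep(-0.5, 4)
  tr <- fit_tree(A, g, h, depth = 1, min_child_weight = 0.5, lambda = 0)
  expect_equal(tr$feature[1], 0L)
  expect_equal(tr$threshold[1], 0)
  expect_equal(sort(predict_tree(tr, A)), c(-1, -1, 1, 1))
  # matches exhaustive enumeration
  orc <- oracle_fit_tree(A, g, h, depth = 1, lambda = 0, mcw = 0.5)
  expect_equal(predict_tree(tr, A), orc$pred, tolerance = 1e-12)
  expect_equal(as.numeric(tr$gain), orc$gain, tolerance = 1e-12)
})

test_that("missing value joins the side that maximizes gain", {
  A <- matrix(c(NA, -1, 1, 1), ncol = 1)
  g <- c(-0.5, -0.5, 0.5, 0.5)
  h <- rep(-0.5, 4)
  tr <- fit_tree(A, g, h, depth = 1, min_child_weight = 0.4, lambda = 0)
  expect_equal(tr$feature[1], 0L)
  expect_equal(tr$default_left[1], 1L)  # joins the negative-target leaf
  # two-way enumeration oracle agrees
  orc <- oracle_fit_tree(A, g, h, depth = 1, lambda = 0, mcw = 0.4)
  expect_equal(predict_tree(tr, A), orc$pred, tolerance = 1e-12)
})

test_that("fit_tree matches the exhaustive oracle on random instances", {
  set.seed(101)
  for (i in 1:12) {
    M <- sample(c(30, 80, 150), 1)
    L <- sample(1:3, 1)
    depth <- sample(1:2, 1)
    A <- matrix(runif(M * L, -1, 1), M, L)
    if (i %% 2 == 0) A[matrix(runif(M * L) < 0.2, M, L)] <- NA
    if (i %% 3 == 0) A[, 1] <- sample(c(-1, 0, 1), M, replace = TRUE)
    q <- runif(M)
    F <- rnorm(M)
    gh <- compute_grad_hess(q, F)
    tr <- fit_tree(A, gh$g, gh$h, depth = depth)
    orc <- oracle_fit_tree(A, gh$g, gh$h, depth = depth)
    expect_equal(predict_tree(tr, A), orc$pred, tolerance = 1e-9)
    expect_equal(as.numeric(tr$gain), orc$gain, tolerance = 1e-9)
  }
})

test_that("leaf values are the Newton step and gains are conserved", {
  set.seed(55)
  M <- 300
  A <- matrix(runif(M * 3, -1, 1), M, 3)
  A[matrix(runif(M * 3) < 0.1, M, 3)] <- NA
  gh <- compute_grad_hess(runif(M), rnorm(M))
  lambda <- 1
  tr <- fit_tree(A, gh$g, gh$h, depth = 2, lambda = lambda)
  leaf <- r_tree_leaf(tr, A)
  hn <- -gh$h
  score <- function(rows) sum(gh$g[rows])^2 / (sum(hn[rows]) + lambda)
  for (lf in unique(leaf)) {
    rows <- which(leaf == lf)
    expect_equal(tr$value[lf], sum(gh$g[rows]) / (sum(hn[rows]) + lambda),
                 tolerance = 1e-9)
  }
  # importance conservation: sum of recorded gains equals the total
  # objective reduction from root to leaves
  total <- 0.5 * (sum(vapply(unique(leaf),
                             function(lf) score(which(leaf == lf)),
                             numeric(1))) - score(seq_len(M)))
  expect_equal(sum(tr$gain), total, tolerance = 1e-9)
  expect_true(all(tr$gain >= 0))
  # a feature never split on has exactly zero gain
  used <- unique(tr$feature[tr$feature >= 0]) + 1
  expect_true(all(tr$gain[setdiff(1:3, used)] == 0))
})

test_that("adding the fitted tree never decreases the quadratic Q-model", {
  set.seed(77)
  for (i in 1:5) {
    M <- 200
    A <- matrix(runif(M * 2, -1, 1), M, 2)
    gh <- compute_grad_hess(runif(M), rnorm(M))
    tr <- fit_tree(A, gh$g, gh$h, depth = 2)
    f <- predict_tree(tr, A)
    for (nu in c(0.05, 0.1, 0.5, 1)) {
      dq <- sum(gh$g * nu * f) + 0.5 * sum(gh$h * (nu * f)^2)
      expect_gte(dq, -1e-12)
    }
  }
})

test_that("tree prediction routes by threshold and default direction", {
  A <- matrix(c(-1, -1, 1, 1), ncol = 1)
  g <- c(-0.5, -0.5, 0.5, 0.5)
  tr <- fit_tree(A, g, rep(-0.5, 4), depth = 1, min_child_weight = 0.4,
                 lambda = 0)
  expect_equal(predict_tree(tr, matrix(-0.5)), -1)
  expect_equal(predict_tree(tr, matrix(0.5)), 1)
  # missing routes to the default direction
  dflt <- if (tr$default_left[1] == 1L) -1 else 1
  expect_equal(predict_tree(tr, matrix(NA_real_)), dflt)
  # a single-leaf tree predicts its value everywhere
  leaf_only <- fit_tree(matrix(runif(10)), rep(0, 10), rep(-0.1, 10))
  expect_equal(predict_tree(leaf_only, matrix(99)), 0)
})

test_that("ensemble prediction is linear in trees and supports truncation", {
  A <- matrix(runif(20, -1, 1), 10, 2)
  m0 <- palm_model(f0 = -3, trees = list(), columns = c("A1", "A2"))
  expect_equal(predict_ensemble(m0, A), rep(-3, 10))
  expect_equal(sigmoid(predict_ensemble(m0, A))[1], 1 / (1 + exp(3)),
               tolerance = 1e-10)
  gh <- compute_grad_hess(runif(10), rnorm(10))
  t1 <- fit_tree(A, gh$g, gh$h, depth = 1)
  t2 <- fit_tree(A, -gh$g, gh$h, depth = 1)
  m <- palm_model(f0 = 0.5, trees = list(t1, t2), nu = 0.1,
                  columns = c("A1", "A2"))
  expect_equal(predict_ensemble(m, A),
               0.5 + 0.1 * (predict_tree(t1, A) + predict_tree(t2, A)),
               tolerance = 1e-12)
  expect_equal(predict_ensemble(m, A, n_trees = 0), rep(0.5, 10))
  expect_equal(predict_ensemble(m, A, n_trees = 1),
               0.5 + 0.1 * predict_tree(t1, A), tolerance = 1e-12)
})
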