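test_that("beta density matches closed form and rejects unclipped input", {
  expect_equal(beta_density(0.7, 1), 1.0, tolerance = 1e-10)
  expect_equal(beta_density(0.25, 0.5), 1.0, tolerance = 1e-10)
  expect_equal(beta_density(1.0, 0.5), 0.5, tolerance = 1e-10)
  expect_error(beta_density(0, 0.5), "clip")
  expect_error(beta_density(-0.1, 0.5), "clip")
  expect_error(beta_density(0.5, 1.5), "alpha")
  # strictly decreasing in p for alpha < 1
  p <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(beta_density(p, 0.3)) < 0))
})

test_that("posterior responsibility matches hand computations", {
  expect_equal(posterior_responsibility(0.3, 0.5, 1), 0.5, tolerance = 1e-10)
  expect_equal(posterior_responsibility(1 / 64, 0.2, 0.5), 0.5,
               tolerance = 1e-10)
  expect_equal(posterior_responsibility(0.3, 0, 0.5), 0, tolerance = 1e-10)
})

test_that("posterior responsibility is a probability, monotone in prior and p", {
  set.seed(42)
  for (i in 1:20) {
    p <- clip_pvalues(runif(50))
    pi1 <- runif(50)
    alpha <- runif(1, 0.05, 0.95)
    q1 <- posterior_responsibility(p, pi1, alpha)
    expect_true(all(q1 >= 0 & q1 <= 1))
    expect_equal(q1 + (1 - q1), rep(1, 50))  # q0 + q1 == 1 by construction
  }
  pgrid <- seq(0.01, 1, length.out = 30)
  expect_true(all(diff(posterior_responsibility(pgrid, 0.3, 0.4)) < 0))
  pigrid <- seq(0.01, 0.99, length.out = 30)
  expect_true(all(diff(posterior_responsibility(0.2, pigrid, 0.4)) > 0))
})

test_that("alpha update matches closed form, is clamped, guards zero mass", {
  expect_equal(update_alpha(c(1, 1), exp(c(-2, -2))), 0.5, tolerance = 1e-10)
  expect_equal(update_alpha(rep(1, 4), rep(exp(-4), 4)), 0.25,
               tolerance = 1e-10)
  expect_equal(update_alpha(1, exp(-1)), 1 - 1e-6)  # clamped below 1
  expect_warning(a <- update_alpha(c(0, 0), c(0.1, 0.2), alpha_prev = 0.37),
                 "non-null mass")
  expect_equal(a, 0.37)
})

test_that("alpha update maximizes the expected complete-data log-likelihood", {
  # Q(alpha) = sum_j q_j1 (log alpha + (alpha - 1) log p_j) at fixed soft
  # labels; grid search over (0, 1) must not beat the closed form.
  set.seed(7)
  for (i in 1:10) {
    p <- clip_pvalues(runif(40)^2)
    q1 <- runif(40)
    a_hat <- update_alpha(q1, p)
    Q <- function(a) sum(q1 * (log(a) + (a - 1) * log(p)))
    grid <- seq(1e-4, 1 - 1e-4, length.out = 2000)
    expect_true(Q(a_hat) >= max(vapply(grid, Q, numeric(1))) - 1e-8)
  }
})

test_that("marginal log-likelihood matches hand computations", {
  expect_equal(marginal_loglik(c(0.2, 0.8, 0.4), runif(3), 1), 0,
               tolerance = 1e-10)
  expect_equal(marginal_loglik(0.25, 0.5, 0.5), 0, tolerance = 1e-10)
  expect_equal(marginal_loglik(1.0, 0.5, 0.5), log(0.75), tolerance = 1e-10)
})

test_that("intercept-only TGM behaves on degenerate and null data", {
  set.seed(11)
  null_fit <- fit_tgm(runif(10000))
  # under a pure null the (pi1, alpha) pair is identified only through the
  # ridge alpha -> 1: the effective non-null excess mass pi1 * (1 - alpha)
  # must vanish and no SNP may be declared
  expect_lte(null_fit$pi1 * (1 - null_fit$alpha), 0.01)
  lfdr <- 1 - posterior_responsibility(clip_pvalues(runif(10000)),
                                       null_fit$pi1, null_fit$alpha)
  expect_equal(global_fdr_select(lfdr, 0.1)$k, 0L)
  ones <- fit_tgm(rep(1, 100))
  expect_lt(ones$pi1, 0.01)
  expect_error(fit_tgm(0.5), "at least 2")
})

test_that("TGM EM log-likelihood trace is non-decreasing", {
  set.seed(12)
  p <- c(rbeta(2000, 0.3, 1), runif(6000))
  fit <- fit_tgm(p)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  # and the final estimates are in the interior
  expect_gt(fit$alpha, 0)
  expect_lt(fit$alpha, 1)
})

test_that("p-value clipping contract", {
  p <- clip_pvalues(c(0, 1e-320, 0.5, 2))
  expect_equal(attr(p, "n_clipped"), 3)
  expect_true(all(p >= 1e-300 & p <= 1))
  expect_error(clip_pvalues(c(0.5, NA)), "non-finite")
})
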