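test_that("the five scenario functions evaluate exactly", {
  expect_equal(true_F("A", matrix(runif(10), 2, 5)), c(-3, -3))
  expect_equal(true_F("B", c(1, 1)), 0)
  expect_equal(true_F("C", c(1, 1)), -2.25)
  expect_equal(true_F("D", c(1, 1, 1, 1, 1)), -2.5, tolerance = 1e-10)
  expect_equal(true_F("E", c(0, 0)), 1)
  expect_equal(true_F("E", c(0, 1)), -1)
  expect_equal(true_F("E", c(0.5, 1)), -1 + 1 - 1.5)
  expect_error(true_F("D", c(1, 1)), "at least 5")
})

test_that("annotation generation is uniform, case-aware and deterministic", {
  A <- gen_annotations(1000, 50, "B", seed = 1)
  expect_true(all(A > -1 & A < 1))
  expect_lt(max(abs(colMeans(A))), 0.1)
  AE <- gen_annotations(500, 5, "E", seed = 2)
  expect_true(all(AE[, 2] %in% c(0, 1)))
  expect_identical(gen_annotations(200, 10, "C", seed = 7),
                   gen_annotations(200, 10, "C", seed = 7))
  expect_error(gen_annotations(100, 1, "B", seed = 1), "at least 2")
})

test_that("status draws are Bernoulli(pi1)", {
  expect_false(any(gen_status(rep(0, 100), seed = 1)))
  expect_true(all(gen_status(rep(1, 100), seed = 1)))
  pi1 <- sigmoid(-3)
  z <- gen_status(rep(pi1, 100000), seed = 3)
  se <- sqrt(pi1 * (1 - pi1) / 100000)
  expect_lt(abs(mean(z) - pi1), 3 * se)
})

test_that("p-value generation follows the two-groups design", {
  Z <- rep(c(TRUE, FALSE), c(4000, 6000))
  pv <- gen_pvalues(Z, seed = 4)
  # non-null p-values are the two-sided tails of their z-scores
  expect_equal(pv$p[Z], clip_pvalues(2 * pnorm(-abs(pv$z[Z]))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(is.na(pv$z[!Z])))
  # all-null stream is uniform (KS at alpha = 0.001)
  p0 <- gen_pvalues(rep(FALSE, 100000), seed = 5)$p
  ks <- suppressWarnings(stats::ks.test(p0, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_error(gen_pvalues(Z, dist = list(weights = c(0.5, 0.4),
                                          means = c(0, 1), sds = c(1, 1))),
               "sum to 1")
})

test_that("missing injection hits the target rate and is reproducible", {
  A <- gen_annotations(4000, 250, "A", seed = 6)
  expect_identical(inject_missing(A, 0, seed = 1), A)
  Am <- inject_missing(A, 0.2, seed = 7)
  expect_lt(abs(mean(is.na(Am)) - 0.2), 0.002)
  expect_identical(inject_missing(A, 0.2, seed = 7), Am)
})

test_that("replicate metrics count false and true discoveries", {
  expect_equal(evaluate_replicate(c(TRUE, FALSE), c(FALSE, FALSE))[
    , c("fdp", "power")], data.frame(fdp = 0, power = 0))
  ev <- evaluate_replicate(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(ev$fdp, 0); expect_equal(ev$power, 1)
  ev2 <- evaluate_replicate(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ev2$fdp, 0.5); expect_equal(ev2$power, 0.5)
  expect_true(is.na(evaluate_replicate(c(FALSE, FALSE),
                                       c(TRUE, FALSE))$power))
})

test_that("simulate_dataset wires sub-streams deterministically", {
  s1 <- simulate_dataset(500, 5, "B", mrate = 0.1, seed = 42)
  s2 <- simulate_dataset(500, 5, "B", mrate = 0.1, seed = 42)
  expect_identical(s1$A, s2$A)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$Z, s2$Z)
  expect_equal(s1$pi1_true, sigmoid(true_F("B", s1$A_full)),
               tolerance = 1e-12)
  s3 <- simulate_dataset(500, 5, "B", mrate = 0.1, seed = 43)
  expect_false(identical(s1$p, s3$p))
})

test_that("run_study produces the long-format metrics table", {
  st <- run_study(cases = "B", M = 1500, L = 5,
                  methods = c("TGM", "BH"), n_reps = 2, seed = 2,
                  config = palm_config(cv_folds = 2, max_trees = 40))
  expect_equal(nrow(st), 4)
  expect_true(all(c("case", "method", "replicate", "fdp", "power",
                    "T_opt", "runtime") %in% names(st)))
  expect_true(all(st$fdp >= 0 & st$fdp <= 1))
  expect_true(all(st$power >= 0 & st$power <= 1))
})
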