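toy_design <- function(n, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 2]))
  list(X = X, y = y)
}

test_that("folds are stratified with near-equal sizes", {
  y <- rep(0:1, each = 50)
  f <- make_folds(100, 10, y, seed = 3)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  expect_true(all(table(f[y == 1]) == 5))
  expect_identical(f, make_folds(100, 10, y, seed = 3))
  # pigeonhole with a rare stratum
  y2 <- rep(c(1, 0), c(7, 93))
  f2 <- make_folds(100, 5, y2, seed = 1)
  expect_true(all(table(f2[y2 == 1]) %in% 1:2))
  expect_error(make_folds(100, 8, y2, seed = 1), "fewer members")
})

test_that("cross-validated predictions are honest out-of-fold values", {
  d <- toy_design(60)
  folds <- make_folds(60, 5, d$y, seed = 2)
  Z <- cv_predictions(d$X, d$y, folds, sl_library(c("mean", "logistic")))
  # the constant learner predicts the training-fold prevalence
  for (v in 1:5)
    expect_equal(unique(Z[folds == v, "mean"]), mean(d$y[folds != v]))
  # a failing learner is dropped with a warning
  bad <- list(boom = list(fit = function(X, y) stop("nope"),
                          predict = function(f, X) rep(0.5, nrow(X))),
              mean = sl_library("mean")$mean)
  expect_warning(Z2 <- cv_predictions(d$X, d$y, folds, bad), "boom")
  expect_equal(colnames(Z2), "mean")
})

test_that("a separable covariate orders exposed above unexposed", {
  X <- cbind(z = c(seq(-2, -0.2, length.out = 10),
                   seq(0.2, 2, length.out = 10)))
  y <- rep(c(0L, 1L), each = 10)
  folds <- make_folds(20, 4, y, seed = 5)
  Z <- cv_predictions(X, y, folds, sl_library(c("mean", "ridge")))
  expect_gt(mean(Z[y == 1, "ridge"]), mean(Z[y == 0, "ridge"]))
})

test_that("ensemble weights match the 1-simplex grid-search oracle", {
  set.seed(11)
  n <- 800
  p_true <- plogis(rnorm(n, 0, 1.2))
  y <- rbinom(n, 1, p_true)
  # one learner knows the truth, the other is uninformative
  Z <- cbind(truth = p_true, flat = rep(0.5, n))
  w <- solve_weights(Z, y)
  expect_gt(w[["truth"]], 0.95)
  oracle <- grid_weights_2(Z, y)
  expect_lt(max(abs(w - oracle)), 0.01)
  # random two-learner problems
  for (k in 1:5) {
    Zk <- cbind(a = plogis(qlogis(p_true) + rnorm(n, 0, 0.7)),
                b = plogis(qlogis(p_true) + rnorm(n, 0, 1.5)))
    wk <- solve_weights(Zk, y)
    expect_lt(max(abs(wk - grid_weights_2(Zk, y))), 0.01)
    expect_equal(sum(wk), 1)
    expect_true(all(wk >= 0))
  }
})

test_that("identical learners fall back to uniform weights", {
  set.seed(2)
  p <- runif(200, 0.2, 0.8)
  y <- rbinom(200, 1, p)
  Z <- cbind(a = p, b = p, c = p)
  expect_equal(unname(solve_weights(Z, y)), rep(1 / 3, 3))
})

test_that("the super-learner fit satisfies its guarantee and invariants", {
  d <- toy_design(400, seed = 7)
  df <- as.data.frame(d$X)
  pf <- fit_propensity(df, d$y, v = 5, library = c("mean", "logistic", "spline"),
                       seed = 4)
  expect_lte(pf$ensemble_risk, min(pf$learner_risks) + 1e-6)
  expect_equal(sum(pf$weights), 1)
  expect_true(all(pf$weights >= 0))
  expect_true(all(pf$scores >= 1e-4 & pf$scores <= 1 - 1e-4))
  expect_true(all(sort(unique(pf$folds)) == 1:5))
  # bitwise reproducibility under the same seed
  pf2 <- fit_propensity(df, d$y, v = 5,
                        library = c("mean", "logistic", "spline"), seed = 4)
  expect_identical(pf$weights, pf2$weights)
  expect_identical(pf$scores, pf2$scores)
  # a single-learner library reduces to that learner
  pf1 <- fit_propensity(df, d$y, v = 5, library = "logistic", seed = 4)
  expect_equal(unname(pf1$weights), 1)
})

test_that("null exposure yields scores concentrated at the prevalence", {
  set.seed(21)
  n <- 1500
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- rbinom(n, 1, 0.4)
  pf <- fit_propensity(df, y, v = 5, library = c("mean", "logistic"), seed = 2)
  expect_lt(abs(mean(pf$scores) - mean(y)), 0.02)
  expect_lt(sd(pf$scores), 0.06)
})

test_that("ensemble scores are calibrated against a known logistic model", {
  set.seed(31)
  n <- 5000
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 0.9 * df$x1 - 0.5 * df$x2))
  pf <- fit_propensity(df, y, v = 5, library = c("mean", "logistic", "spline"),
                       seed = 9)
  slope <- coef(glm(y ~ qlogis(pf$scores), family = binomial()))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("the planted no-overlap stratum lands in the extreme lower tail", {
  cfg <- city_study_config(17, n_city = 1500,
                           structural_overlap_violation = TRUE)
  fr <- greenbirth:::build_analysis_frame(cfg)
  ana <- fr$analysis
  covs <- c(default_adjustment_covariates(), "public_housing")
  pf <- fit_propensity(ana[, covs], ana$exposed, v = 5,
                       library = c("mean", "logistic"), seed = 5)
  stratum <- ana$public_housing
  expect_gt(sum(stratum), 10)
  lower <- quantile(pf$scores[ana$exposed], 0.01, type = 7)
  expect_true(all(pf$scores[stratum] < lower))
})
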