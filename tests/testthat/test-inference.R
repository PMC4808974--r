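test_that("the unadjusted 2x2 logistic fit reproduces printed odds ratios", {
  city <- or_from_counts(195, 1636, 127, 927)
  expect_equal(round(city$or, 2), 0.85)
  township <- or_from_counts(465, 4212, 248, 2249)
  expect_equal(round(township$or, 2), 1.00)
  # closed-form cross-product identity
  expect_equal(city$or, (195 / (1636 - 195)) / (127 / (927 - 127)),
               tolerance = 1e-6)
  expect_true(city$ci[1] < city$or && city$or < city$ci[2])
  expect_gt(city$or, 0)
})

test_that("one cluster per row reduces to the heteroskedasticity-robust sandwich", {
  set.seed(2)
  n <- 300
  df <- data.frame(y = rbinom(n, 1, 0.3), exposed = runif(n) < 0.5,
                   community_id = seq_len(n))
  est <- fit_outcome_model(df, model_spec("y", "logistic"))
  fit <- glm(y ~ exposed, family = binomial(), data = df)
  hc <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[["exposedTRUE"]]
  expect_equal(est$se_cluster, hc * sqrt(n / (n - 1)), tolerance = 1e-6)
})

test_that("model guards catch separation, singularity and degenerate exposure", {
  df <- data.frame(y = rep(c(0L, 1L), each = 30),
                   exposed = rep(c(FALSE, TRUE), each = 30),
                   community_id = rep(1:6, 10))
  expect_error(fit_outcome_model(df, model_spec("y", "logistic")),
               "separation")
  df2 <- data.frame(y = rbinom(60, 1, 0.5), exposed = rep(c(TRUE, FALSE), 30),
                    community_id = rep(1:6, 10))
  df2$dup <- as.numeric(df2$exposed)
  expect_error(fit_outcome_model(df2, model_spec("y", "logistic",
                                                 covariates = "dup")),
               "singular")
  df3 <- df2; df3$exposed <- TRUE
  expect_error(fit_outcome_model(df3, model_spec("y", "logistic")),
               "both exposure levels")
  expect_error(model_spec("term_weight_g", "linear"),
               "gestational age")
})

test_that("interaction selection retains real interactions and skips duplicates", {
  set.seed(14)
  n <- 5000
  df <- data.frame(age = rnorm(n), smoke = rbinom(n, 1, 0.3),
                   exposed = rbinom(n, 1, 0.5) == 1,
                   community_id = rep(1:20, length.out = n))
  lp <- -1.5 + 0.3 * df$age + 0.2 * df$smoke + 0.6 * df$age * df$smoke
  df$y <- rbinom(n, 1, plogis(lp))
  base <- model_spec("y", "logistic", covariates = c("age", "smoke"))
  sel <- lrt_select_interactions(df, base, c("age:smoke"))
  expect_true("age:smoke" %in% sel$interactions)
  # no candidates: spec unchanged
  expect_identical(lrt_select_interactions(df, base, character(0))$interactions,
                   character(0))
  # a candidate duplicating an existing column adds nothing
  df$agecopy <- df$age
  sel2 <- lrt_select_interactions(df, model_spec("y", "logistic",
                                                 covariates = "age"),
                                  "agecopy")
  log <- attr(sel2, "selection_log")
  expect_false(any(log$retained))
  expect_lt(log$lrt_stat[1], 1e-6)
})

test_that("effect modification detects planted interactions and rejects constants", {
  set.seed(6)
  n <- 4000
  df <- data.frame(ma = rbinom(n, 1, 0.4), exposed = rbinom(n, 1, 0.5) == 1,
                   community_id = rep(1:16, length.out = n))
  df$y <- rbinom(n, 1, plogis(-1.6 + 0.2 * df$ma +
                                (0.1 + 0.6 * df$ma) * df$exposed))
  sp <- model_spec("y", "logistic", covariates = character())
  em <- effect_modification(df, sp, "ma")
  expect_lt(em$wald_p, 0.05)
  expect_lt(em$lrt_p, 0.05)
  df$const <- 1
  expect_error(effect_modification(df, sp, "const"), "does not vary")
  # under the null the interaction p-values are roughly uniform
  set.seed(8)
  pvals <- replicate(40, {
    d <- data.frame(ma = rbinom(600, 1, 0.4),
                    exposed = rbinom(600, 1, 0.5) == 1,
                    community_id = seq_len(600))
    d$y <- rbinom(600, 1, plogis(-1.2 + 0.3 * d$ma - 0.2 * d$exposed))
    effect_modification(d, sp, "ma")$lrt_p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("continuous NDVI models recover slopes per 0.1 unit and flag curvature", {
  cfg <- city_study_config(23, n_city = 4000,
                           true_effects = list(
                             preterm = c(city = 0, borough = 0, township = 0),
                             sga = c(city = 0, borough = 0, township = 0),
                             low_apgar = c(city = 0, borough = 0, township = 0),
                             weight_g_per_ndvi = c(city = 210, borough = 0,
                                                   township = 0)))
  fr <- greenbirth:::build_analysis_frame(cfg)
  ana <- fr$analysis
  sp <- model_spec("term_weight_g", "linear",
                   covariates = c("sex", "gestational_age", "maternal_age"))
  est <- continuous_ndvi_model(ana, sp)
  expect_lt(abs(est$beta - 21), 3 * est$se_cluster + 3)
  expect_true(est$ci[1] < 21 + 12 && est$ci[2] > 21 - 12)
  # a null effect gives an estimate near zero
  cfg0 <- city_study_config(24, n_city = 2500,
                            true_effects = list(
                              preterm = c(city = 0, borough = 0, township = 0),
                              sga = c(city = 0, borough = 0, township = 0),
                              low_apgar = c(city = 0, borough = 0, township = 0),
                              weight_g_per_ndvi = c(city = 0, borough = 0,
                                                    township = 0)))
  fr0 <- greenbirth:::build_analysis_frame(cfg0)
  est0 <- continuous_ndvi_model(fr0$analysis, sp)
  expect_true(est0$ci[1] <= 0 && est0$ci[2] >= 0)
  # quadratic truth flags a departure from linearity
  set.seed(3)
  n <- 5000
  d <- data.frame(ndvi = runif(n, 0.2, 0.8),
                  community_id = rep(1:10, length.out = n))
  d$y <- rbinom(n, 1, plogis(-2 + 6 * (d$ndvi - 0.5)^2))
  spq <- model_spec("y", "logistic", exposure = "ndvi",
                    covariates = character())
  estq <- continuous_ndvi_model(d, spq)
  expect_lt(estq$nonlinearity_p[["quadratic"]], 0.05)
})

test_that("semivariograms are flat for iid residuals and rising for smooth fields", {
  set.seed(19)
  n <- 160
  x <- runif(n, 0, 10000); y <- runif(n, 0, 10000)
  r_iid <- rnorm(n)
  breaks <- seq(0, 14000, length.out = 6)
  sv <- residual_semivariogram(r_iid, x, y, breaks)
  expect_gt(sum(sv$n_pairs), 10000)
  filled <- sv$gamma[!sv$empty]
  expect_lt(max(abs(filled - mean(filled)) / mean(filled)), 0.15)
  # smooth spatial signal: short-range gamma well below long-range
  r_smooth <- sin(x / 2000) + cos(y / 2500)
  sv2 <- residual_semivariogram(r_smooth, x, y, breaks)
  expect_lt(sv2$gamma[1], sv2$gamma[4])
  # duplicated points only: the zero-distance bin has gamma 0
  sv3 <- residual_semivariogram(c(1, 1, 2, 2), c(0, 0, 5, 5), c(0, 0, 0, 0),
                                c(0, 1, 10))
  expect_equal(sv3$gamma[1], 0)
  expect_error(residual_semivariogram(r_iid, x, y, c(0, 100)), "breaks")
})

test_that("the sensitivity suite reports all variants and their correlations", {
  cfg <- tiny_config(seed = 27)
  raster <- simulate_raster(cfg)
  fr <- greenbirth:::build_analysis_frame(cfg, raster = raster)
  out <- sensitivity_suite(fr$analysis, raster, v = 4,
                           covariates = c("sex", "maternal_age", "smoking"),
                           propensity_covariates = c("maternal_age", "smoking",
                                                     "medical_assistance"),
                           library = c("mean", "logistic"), seed = 2)
  expect_true(all(c("tertile23_mean_250m", "tertile23_max_1250m") %in%
                    sub("^(tertile23_[a-z]+_[0-9]+m).*", "\\1",
                        out$table$variant)))
  expect_equal(dim(out$spearman), c(4, 4))
  expect_true(any(grepl("continuous_ndvi_restricted", out$table$variant)))
  expect_true(any(grepl("tertile23_original", out$table$variant)))
})

test_that("all exposure variants coincide on a constant raster", {
  cfg <- flat_config(seed = 31, base = 0.45)
  raster <- simulate_raster(cfg)
  sim <- simulate_cohort(cfg, raster)
  co <- sim$cohort[1:30, ]
  a1 <- assign_exposure(co, raster, 250, "mean")
  a2 <- assign_exposure(co, raster, 1250, "mean")
  a3 <- assign_exposure(co, raster, 250, "max")
  expect_equal(a1$ndvi, a2$ndvi)
  expect_equal(a1$ndvi, a3$ndvi)
})
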