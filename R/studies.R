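#' Study-condition configuration for city-only replication studies
#'
#' The configuration used by the parameter-recovery and
#' structural-confounding replicate studies: one community type (cities,
#' twelve communities, about `n_city` births), protective true city effects
#' (preterm OR 0.78, SGA OR 0.73), confounding on.
#'
#' @param seed integer seed.
#' @param n_city expected number of city births.
#' @param structural_overlap_violation plant the no-overlap stratum.
#' @param ... further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
city_study_config <- function(seed, n_city = 2500,
                              structural_overlap_violation = FALSE, ...) {
  sim_config(seed = seed,
             n_births = c(city = n_city, borough = 0, township = 0),
             n_communities = c(city = 12, borough = 1, township = 1),
             grid_dim = c(64L, 64L),
             structural_overlap_violation = structural_overlap_violation,
             ...)
}

# simulate -> exclude -> covariates -> outcomes -> exposure, merged into one
# analysis frame; shared by the replicate studies and the pipeline examples
build_analysis_frame <- function(config, raster = simulate_raster(config),
                                 layers = simulate_point_layers(config)) {
  sim <- simulate_cohort(config, raster)
  excl <- apply_exclusions(sim$cohort)
  inc <- excl$included
  panel <- build_covariate_panel(inc, sim$communities, layers)
  ref <- build_growth_reference(inc)
  outc <- classify_outcomes(inc, ref)
  expo <- assign_exposure(inc, raster, 250, "mean")
  ana <- cbind(inc[, c("birth_id", "mother_id", "community_id",
                       "community_type", "x", "y", "birth_date",
                       "gestational_age")],
               panel[, setdiff(names(panel), "birth_id"), drop = FALSE],
               expo[, c("ndvi", "tertile", "exposed")],
               outc[, c("sga", "preterm", "low_apgar", "term_weight_g")])
  list(analysis = ana, truth = sim$truth, exclusions = excl$ledger,
       reference = ref, exposure = expo, raster = raster, layers = layers,
       communities = sim$communities)
}

#' Parameter-recovery replicate study
#'
#' Repeatedly simulates city cohorts with the configured true effects,
#' runs the full exposure/propensity/trim/adjusted-regression chain, and
#' records the estimated preterm and SGA odds ratios with their
#' cluster-robust confidence intervals.  A consistent pipeline should give a
#' median estimate close to the truth and near-nominal interval coverage.
#'
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param n_city births per replicate.
#' @param v,library propensity settings (a light library keeps the study
#'   fast; the ensemble guarantee is exercised separately).
#' @param covariates adjustment covariates.
#' @return Data.frame with one row per replicate: estimated ORs, CI bounds,
#'   true ORs, and CI coverage indicators.
#' @export
run_recovery_study <- function(n_reps = 200, seed = 1, n_city = 2500,
                               v = 5, library = c("mean", "logistic"),
                               covariates = default_adjustment_covariates()) {
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- city_study_config(derive_seed(seed, paste0("recovery", r)),
                             n_city = n_city)
    fr <- build_analysis_frame(cfg)
    ana <- fr$analysis
    pf <- fit_propensity(ana[, covariates, drop = FALSE], ana$exposed,
                         v = v, library = library,
                         seed = derive_seed(seed, paste0("pfold", r)))
    tr <- trim_common_support(pf$scores, ana$exposed)
    res_dat <- ana[tr$keep, , drop = FALSE]
    row <- data.frame(rep = r)
    for (oc in c("preterm", "sga")) {
      est <- fit_outcome_model(res_dat,
                               model_spec(oc, "logistic",
                                          covariates = covariates))
      truth <- exp(fr$truth$effects[[oc]][["city"]])
      row[[paste0(oc, "_or")]] <- est$or
      row[[paste0(oc, "_lo")]] <- est$ci[1]
      row[[paste0(oc, "_hi")]] <- est$ci[2]
      row[[paste0(oc, "_true")]] <- truth
      row[[paste0(oc, "_covered")]] <- est$ci[1] <= truth & truth <= est$ci[2]
    }
    res[[r]] <- row
  }
  do.call(rbind, res)
}

#' Structural-confounding bias-contrast study
#'
#' Plants a no-overlap covariate stratum (present only among unexposed
#' low-greenness city mothers, with elevated outcome risk that the outcome
#' model does not adjust for), and compares the bias of the
#' common-support-trimmed estimate against the untrimmed estimate in each
#' replicate.  Trimming excludes the stratum -- its propensity scores are in
#' the extreme lower tail -- so the trimmed estimate should be closer to
#' the truth in most replicates.
#'
#' @inheritParams run_recovery_study
#' @param outcome outcome on which the contrast is measured.
#' @return Data.frame with per-replicate trimmed/untrimmed estimates,
#'   absolute log-scale biases, and the improvement indicator.
#' @export
run_support_bias_study <- function(n_reps = 100, seed = 1, n_city = 5000,
                                   v = 5, library = c("mean", "logistic"),
                                   covariates = default_adjustment_covariates(),
                                   outcome = "preterm") {
  prop_covs <- unique(c(covariates, "public_housing"))
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- city_study_config(derive_seed(seed, paste0("structural", r)),
                             n_city = n_city,
                             structural_overlap_violation = TRUE)
    fr <- build_analysis_frame(cfg)
    ana <- fr$analysis
    truth <- fr$truth$effects[[outcome]][["city"]]
    pf <- fit_propensity(ana[, prop_covs, drop = FALSE], ana$exposed,
                         v = v, library = library,
                         seed = derive_seed(seed, paste0("sfold", r)))
    tr <- trim_common_support(pf$scores, ana$exposed)
    sp <- model_spec(outcome, "logistic", covariates = covariates)
    est_all <- fit_outcome_model(ana, sp)
    est_trim <- fit_outcome_model(ana[tr$keep, , drop = FALSE], sp)
    res[[r]] <- data.frame(
      rep = r, or_untrimmed = est_all$or, or_trimmed = est_trim$or,
      bias_untrimmed = abs(log(est_all$or) - truth),
      bias_trimmed = abs(log(est_trim$or) - truth),
      stratum_trimmed = all(!tr$keep[ana$public_housing]),
      improved = abs(log(est_trim$or) - truth) < abs(log(est_all$or) - truth))
  }
  do.call(rbind, res)
}

#' Super-learner guarantee study
#'
#' Simulates exposure data from known nonlinear logistic models, fits the
#' full-library super learner, and records the gap between the ensemble
#' cross-validated risk and the best base learner's risk (the stacking
#' guarantee says the gap is never materially positive).
#'
#' @param n_datasets number of simulated datasets.
#' @param n observations per dataset.
#' @param seed master seed.
#' @param v folds.
#' @param library learner names.
#' @return Data.frame with per-dataset ensemble risk, best learner risk,
#'   and their gap.
#' @export
run_superlearner_study <- function(n_datasets = 50, n = 400, seed = 1,
                                   v = 10,
                                   library = c("mean", "ridge", "spline", "xgb")) {
  res <- vector("list", n_datasets)
  for (r in seq_len(n_datasets)) {
    dat <- with_seed(derive_seed(seed, paste0("sl", r)), {
      X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = factor(sample(letters[1:3], n, replace = TRUE)))
      lp <- 0.8 * X$x1 - 0.6 * sin(2 * X$x2) + 0.5 * (X$x3 > 0.5) +
        0.4 * (X$x4 == "b") - 0.2
      X$y <- rbinom(n, 1, plogis(lp))
      X
    })
    pf <- fit_propensity(dat[, 1:4], dat$y, v = v, library = library,
                         seed = derive_seed(seed, paste0("slfold", r)))
    res[[r]] <- data.frame(dataset = r, ensemble_risk = pf$ensemble_risk,
                           best_learner_risk = min(pf$learner_risks),
                           gap = pf$ensemble_risk - min(pf$learner_risks))
  }
  do.call(rbind, res)
}

#' Grid-search oracle for two-learner ensemble weights
#'
#' Exhaustive search over the 1-simplex at a fixed step: the independent
#' check that [solve_weights()] finds the risk-minimizing convex
#' combination.
#'
#' @param Z two-column prediction matrix.
#' @param y 0/1 outcomes.
#' @param step grid step.
#' @return Weight vector `c(w1, w2)` minimizing the binomial risk on the grid.
#' @export
grid_weights_2 <- function(Z, y, step = 0.001) {
  stopifnot(ncol(Z) == 2)
  w1 <- seq(0, 1, by = step)
  risks <- vapply(w1, function(w)
    binomial_risk(as.vector(.clip(Z) %*% c(w, 1 - w)), y), numeric(1))
  w <- w1[which.min(risks)]
  setNames(c(w, 1 - w), colnames(Z))
}
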