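#' Sensitivity analyses over exposure-metric choices
#'
#' Re-runs the exposure -> propensity -> trim -> inference chain under the
#' alternative exposure definitions: mean and maximum NDVI in 250 m and
#' 1250 m buffers (tertile 2-3 vs 1 contrast for each), plus -- for the
#' primary 250 m mean metric -- the community-specific 20th-percentile
#' dichotomization, the continuous-NDVI model on both the restricted and the
#' original population, and the original-vs-restricted binary contrast.
#' Spearman correlations among the four NDVI metrics are reported.
#'
#' @param analysis analysis data.frame (included births with covariate
#'   panel and outcome columns merged; must carry `x`, `y`, `birth_date`,
#'   `community_type`, `community_id`, `birth_id`).
#' @param raster an [ndvi_stack()].
#' @param outcome outcome column for the comparison table.
#' @param family model family for that outcome.
#' @param covariates adjustment covariates.
#' @param propensity_covariates covariates for the propensity model.
#' @param v,library propensity cross-validation folds and learner names.
#' @param percentile alternative dichotomization percentile.
#' @param lower_pct,upper_pct trim percentiles.
#' @param seed integer seed.
#' @return List with `table` (one row per variant x community type),
#'   `spearman` (correlation matrix among NDVI metrics).
#' @export
sensitivity_suite <- function(analysis, raster, outcome = "preterm",
                              family = "logistic",
                              covariates = default_adjustment_covariates(),
                              propensity_covariates = covariates,
                              v = 5, library = c("mean", "logistic"),
                              percentile = 20, lower_pct = 1, upper_pct = 99,
                              seed = 1) {
  metrics <- expand.grid(radius_m = c(250, 1250),
                         statistic = c("mean", "max"),
                         stringsAsFactors = FALSE)
  assigns <- lapply(seq_len(nrow(metrics)), function(i)
    assign_exposure(analysis, raster, metrics$radius_m[i],
                    metrics$statistic[i]))
  names(assigns) <- paste0(metrics$statistic, "_", metrics$radius_m, "m")
  ndvi_mat <- vapply(assigns, function(a) a$ndvi, numeric(nrow(analysis)))
  spearman <- cor(ndvi_mat, method = "spearman")

  fit_variant <- function(dat, expo_col, label, variant) {
    out <- list()
    for (tp in unique(as.character(dat$community_type))) {
      sub <- dat[dat$community_type == tp, , drop = FALSE]
      est <- tryCatch({
        pf <- fit_propensity(sub[, propensity_covariates, drop = FALSE],
                             sub[[expo_col]], v = v, library = library,
                             seed = derive_seed(seed, paste0(label, tp)))
        tr <- trim_common_support(pf$scores, sub[[expo_col]],
                                  lower_pct, upper_pct)
        sp <- model_spec(outcome, family, exposure = expo_col,
                         covariates = covariates)
        fit_outcome_model(sub[tr$keep, , drop = FALSE], sp)
      }, error = function(e) e)
      out[[tp]] <- if (inherits(est, "error"))
        data.frame(variant = variant, community_type = tp,
                   estimate = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, n = NA_integer_,
                   note = conditionMessage(est))
      else
        data.frame(variant = variant, community_type = tp,
                   estimate = if (family == "logistic") est$or else est$beta,
                   ci_lower = est$ci[1], ci_upper = est$ci[2], n = est$n,
                   note = "")
    }
    do.call(rbind, out)
  }

  rows <- list()
  for (i in seq_len(nrow(metrics))) {
    lab <- names(assigns)[i]
    dat <- analysis
    dat$exposed_v <- assigns[[i]]$exposed
    dat$ndvi <- assigns[[i]]$ndvi
    rows[[lab]] <- fit_variant(dat, "exposed_v", lab,
                               paste0("tertile23_", lab))
  }
  # 20th-percentile dichotomization on the primary metric
  primary <- assigns[["mean_250m"]]
  dat <- analysis
  dat$ndvi <- primary$ndvi
  dat$exposed_v <- as.logical(dichotomize_at_percentile(primary, percentile))
  rows[["p20"]] <- fit_variant(dat, "exposed_v", "p20",
                               sprintf("above_p%g_mean_250m", percentile))
  # continuous NDVI, original vs restricted, primary metric
  dat$exposed_v <- primary$exposed
  cont <- list()
  for (tp in unique(as.character(dat$community_type))) {
    sub <- dat[dat$community_type == tp, , drop = FALSE]
    pf <- fit_propensity(sub[, propensity_covariates, drop = FALSE],
                         sub$exposed_v, v = v, library = library,
                         seed = derive_seed(seed, paste0("cont", tp)))
    tr <- trim_common_support(pf$scores, sub$exposed_v, lower_pct, upper_pct)
    sp <- model_spec(outcome, family, exposure = "exposed_v",
                     covariates = covariates)
    for (pop in c("original", "restricted")) {
      d <- if (pop == "restricted") sub[tr$keep, , drop = FALSE] else sub
      ce <- continuous_ndvi_model(d, sp)
      be <- fit_outcome_model(d, sp)
      cont[[paste(tp, pop)]] <- data.frame(
        variant = paste0(c("continuous_ndvi_", "tertile23_"), pop, "_mean_250m"),
        community_type = tp,
        estimate = c(if (family == "logistic") ce$or else ce$beta,
                     if (family == "logistic") be$or else be$beta),
        ci_lower = c(ce$ci[1], be$ci[1]), ci_upper = c(ce$ci[2], be$ci[2]),
        n = c(ce$n, be$n), note = "")
    }
  }
  tab <- do.call(rbind, c(rows, cont))
  rownames(tab) <- NULL
  list(table = tab, spearman = spearman)
}
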