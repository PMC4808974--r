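#' Outcome model specification
#'
#' @param outcome outcome column name (`preterm`, `sga`, `low_apgar`,
#'   `term_weight_g`, ...).
#' @param family `"logistic"` or `"linear"`.
#' @param exposure exposure column name (binary contrast or continuous
#'   NDVI term).
#' @param covariates adjustment covariate column names.  `maternal_age` is
#'   automatically entered as centered linear + quadratic terms.
#' @param interactions character vector of `a:b` interaction terms.
#' @param cluster cluster column for the sandwich standard errors
#'   (community by default; mother-level clustering is a config choice).
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome, family = c("logistic", "linear"),
                       exposure = "exposed", covariates = character(),
                       interactions = character(),
                       cluster = "community_id") {
  family <- match.arg(family)
  if (outcome == "term_weight_g" && family == "logistic")
    stop("term birth weight requires the linear family")
  if (outcome == "term_weight_g" && !("gestational_age" %in% covariates))
    stop("the birth weight model must adjust for gestational age")
  structure(list(outcome = outcome, family = family, exposure = exposure,
                 covariates = covariates, interactions = interactions,
                 cluster = cluster),
            class = "model_spec")
}

#' Default adjustment covariates for the outcome models
#'
#' Neonate sex, year band and season of birth; maternal age (centered
#' linear + quadratic), race/ethnicity, primary care status, smoking, BMI
#' class, parity, Medical Assistance, antibiotic orders, delivery hospital;
#' water source, road distance, swine AFO exposure, well count; community
#' walkability and deprivation quartile.
#'
#' @return Character vector of column names.
#' @export
default_adjustment_covariates <- function() {
  c("sex", "year_band", "season_of_birth", "maternal_age", "race",
    "primary_care", "smoking", "bmi_class", "parity", "medical_assistance",
    "antibiotic_orders", "hospital", "water_source", "road_distance_m",
    "afo", "wells_20km", "walkability", "csd_quartile")
}

spec_terms <- function(spec) {
  covs <- setdiff(spec$covariates, c("maternal_age", "maternal_age2"))
  terms <- c(spec$exposure, covs)
  if ("maternal_age" %in% spec$covariates)
    terms <- c(terms, "maternal_age_c", "I(maternal_age_c^2)")
  c(terms, spec$interactions)
}

spec_formula <- function(spec, terms = spec_terms(spec)) {
  as.formula(paste(spec$outcome, "~", paste(terms, collapse = " + ")))
}

spec_vars <- function(spec) {
  unique(c(spec$outcome, spec$exposure,
           setdiff(spec$covariates, "maternal_age2"),
           unlist(strsplit(spec$interactions, ":", fixed = TRUE)),
           spec$cluster))
}

model_rows <- function(data, spec) {
  vars <- spec_vars(spec)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  complete.cases(data[, vars, drop = FALSE])
}

center_age <- function(data) {
  if ("maternal_age" %in% names(data))
    data$maternal_age_c <- data$maternal_age - mean(data$maternal_age)
  data
}

#' Fit a community-stratified outcome model with cluster-robust errors
#'
#' Maximum-likelihood linear or logistic regression of one outcome on the
#' exposure contrast and the adjustment covariates, on complete cases, with
#' standard errors from a one-way clustered sandwich (community level by
#' default) carrying the small-sample factor G/(G-1).  Logistic estimates
#' are reported as odds ratios with Wald intervals on the log scale.
#'
#' @param data analysis data (typically one community type, restricted to
#'   common support), containing outcome, exposure, covariates and cluster
#'   columns.
#' @param spec a [model_spec()].
#' @param level confidence level.
#' @return An `effect_estimate`: point estimate (`or` or `beta`),
#'   confidence interval, cluster-robust SE, n used, dropped-row count, and
#'   the underlying fit.
#' @export
fit_outcome_model <- function(data, spec, level = 0.95) {
  rows <- model_rows(data, spec)
  df <- center_age(data[rows, , drop = FALSE])
  constant <- spec$covariates[vapply(spec$covariates, function(v)
    v %in% names(df) && length(unique(df[[v]])) < 2, logical(1))]
  if (length(constant)) {
    spec$covariates <- setdiff(spec$covariates, constant)
    spec$interactions <- spec$interactions[
      !vapply(strsplit(spec$interactions, ":", fixed = TRUE),
              function(p) any(p %in% constant), logical(1))]
  }
  expo <- df[[spec$exposure]]
  if (length(unique(expo[!is.na(expo)])) < 2)
    stop("both exposure levels must be present")
  fml <- spec_formula(spec)
  fit <- if (spec$family == "logistic")
    suppressWarnings(glm(fml, family = binomial(), data = df))
  else lm(fml, data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("singular design: ", paste(names(cf)[is.na(cf)], collapse = ", "))
  k <- length(cf)
  if (sum(rows) < 10 * k)
    stop("too few complete-case rows (", sum(rows), ") for ", k, " parameters")
  if (spec$family == "logistic") {
    # flag separation only when it breaks the exposure contrast or most of
    # the fit; an isolated zero-event covariate cell is quasi-separation and
    # leaves the exposure estimate intact
    mu <- fitted(fit)
    expo_term <- grep(paste0("^", spec$exposure), names(cf), value = TRUE)
    boundary <- mean(mu < 1e-8 | mu > 1 - 1e-8)
    if (any(abs(cf[expo_term]) > 10) || boundary > 0.2) {
      big <- abs(cf) > 10
      stop("separation detected for: ",
           paste(names(cf)[if (any(big)) big else which.max(abs(cf))],
                 collapse = ", "))
    }
  }
  V <- sandwich::vcovCL(fit, cluster = df[[spec$cluster]], type = "HC0",
                        cadjust = TRUE)
  term <- grep(paste0("^", spec$exposure), names(cf), value = TRUE)[1]
  b <- cf[[term]]
  se <- sqrt(V[term, term])
  G <- length(unique(df[[spec$cluster]]))
  # t critical value with G - 1 df: the usual small-sample correction for
  # few-cluster sandwich intervals (reduces to the normal as G grows)
  z <- stats::qt(1 - (1 - level) / 2, df = max(G - 1, 1))
  est <- list(term = term, coef = b, se_cluster = se,
              dropped_covariates = constant,
              n = sum(rows), n_dropped = sum(!rows),
              n_clusters = length(unique(df[[spec$cluster]])),
              family = spec$family, outcome = spec$outcome,
              interactions = spec$interactions, level = level,
              vcov = V, fit = fit, spec = spec)
  if (spec$family == "logistic") {
    est$or <- exp(b)
    est$ci <- exp(b + c(-1, 1) * z * se)
  } else {
    est$beta <- b
    est$ci <- b + c(-1, 1) * z * se
  }
  structure(est, class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  lab <- if (x$family == "logistic") "OR" else "beta"
  val <- if (x$family == "logistic") x$or else x$beta
  cat(sprintf("<effect_estimate> %s on %s: %s = %.*f (%.*f-%.*f), n = %d, clusters = %d\n",
              x$term, x$outcome, lab, digits, val, digits, x$ci[1],
              digits, x$ci[2], x$n, x$n_clusters))
  invisible(x)
}

#' Unadjusted odds ratio from a 2x2 table of counts
#'
#' Expands the printed counts to individual records and fits the unadjusted
#' logistic model, the same path used for cohort data; the estimate equals
#' the cross-product ratio.
#'
#' @param events_exposed,n_exposed events and total among the exposed.
#' @param events_unexposed,n_unexposed events and total among the unexposed.
#' @return An `effect_estimate`.
#' @export
or_from_counts <- function(events_exposed, n_exposed,
                           events_unexposed, n_unexposed) {
  df <- data.frame(
    y = c(rep(1, events_exposed), rep(0, n_exposed - events_exposed),
          rep(1, events_unexposed), rep(0, n_unexposed - events_unexposed)),
    exposed = rep(c(TRUE, FALSE), c(n_exposed, n_unexposed)))
  df$community_id <- seq_len(nrow(df))
  fit_outcome_model(df, model_spec("y", "logistic", exposure = "exposed",
                                   cluster = "community_id"))
}

#' Greedy likelihood-ratio selection of two-way interactions
#'
#' Walks the candidate interactions in the declared order, refits the model
#' with each candidate added, and retains it when the likelihood ratio test
#' improves fit at p < 0.05.  Candidate and base models are compared on
#' identical rows.
#'
#' @param data analysis data.
#' @param spec base [model_spec()].
#' @param candidates character vector of `a:b` terms.
#' @param alpha retention threshold.
#' @return The augmented `model_spec`, with a `selection_log` attribute.
#' @export
lrt_select_interactions <- function(data, spec, candidates, alpha = 0.05) {
  if (length(candidates) == 0) return(spec)
  probe <- spec
  probe$interactions <- c(spec$interactions, candidates)
  rows <- model_rows(data, probe)
  df <- center_age(data[rows, , drop = FALSE])
  current <- spec
  log <- data.frame(candidate = candidates, lrt_stat = NA_real_,
                    p = NA_real_, retained = FALSE)
  fit_with <- function(sp) {
    if (sp$family == "logistic")
      suppressWarnings(glm(spec_formula(sp), family = binomial(), data = df))
    else lm(spec_formula(sp), data = df)
  }
  base_fit <- fit_with(current)
  for (i in seq_along(candidates)) {
    trial <- current
    trial$interactions <- c(current$interactions, candidates[i])
    trial_fit <- fit_with(trial)
    stat <- as.numeric(2 * (logLik(trial_fit) - logLik(base_fit)))
    dfree <- attr(logLik(trial_fit), "df") - attr(logLik(base_fit), "df")
    p <- if (dfree > 0) pchisq(max(stat, 0), dfree, lower.tail = FALSE) else NA
    log$lrt_stat[i] <- max(stat, 0); log$p[i] <- p
    if (!is.na(p) && p < alpha) {
      current <- trial
      base_fit <- trial_fit
      log$retained[i] <- TRUE
    }
  }
  attr(current, "selection_log") <- log
  current
}

#' Effect modification by a covariate
#'
#' Adds exposure-by-modifier interaction terms and reports the interaction
#' coefficients with a cluster-robust Wald test and the model-based
#' likelihood ratio p-value.
#'
#' @param data analysis data.
#' @param spec base [model_spec()].
#' @param modifier modifier column (e.g. Medical Assistance or community
#'   deprivation quartile); must vary within both exposure groups.
#' @return List with the interaction coefficients, cluster-robust Wald
#'   chi-square and p, and LRT p.
#' @export
effect_modification <- function(data, spec, modifier) {
  rows <- model_rows(data, spec) & complete.cases(data[, modifier, drop = FALSE])
  df <- center_age(data[rows, , drop = FALSE])
  for (g in unique(df[[spec$exposure]]))
    if (length(unique(df[[modifier]][df[[spec$exposure]] == g])) < 2)
      stop("modifier '", modifier, "' does not vary within both exposure groups")
  base_terms <- unique(c(spec_terms(spec), modifier))
  int_term <- paste0(spec$exposure, ":", modifier)
  f0 <- spec_formula(spec, base_terms)
  f1 <- spec_formula(spec, c(base_terms, int_term))
  fam <- if (spec$family == "logistic") binomial() else gaussian()
  fit0 <- suppressWarnings(glm(f0, family = fam, data = df))
  fit1 <- suppressWarnings(glm(f1, family = fam, data = df))
  V <- sandwich::vcovCL(fit1, cluster = df[[spec$cluster]], type = "HC0",
                        cadjust = TRUE)
  cf <- coef(fit1)
  idx <- setdiff(names(cf), names(coef(fit0)))
  b <- cf[idx]
  W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
  lrt <- lmtest::lrtest(fit0, fit1)
  list(terms = idx, coefficients = b,
       wald_chisq = W, wald_df = length(idx),
       wald_p = pchisq(W, length(idx), lower.tail = FALSE),
       lrt_p = lrt$`Pr(>Chisq)`[2], n = nrow(df))
}

#' Continuous-NDVI outcome model (per 0.1 NDVI)
#'
#' Fits the adjusted model with continuous NDVI scaled so the reported
#' coefficient corresponds to a 0.1-unit NDVI increase, and reports
#' likelihood-ratio p-values for quadratic and cubic departures from
#' linearity.
#'
#' @param data analysis data containing an `ndvi` column.
#' @param spec a [model_spec()]; its `exposure` is replaced by the scaled
#'   NDVI term.
#' @param ndvi NDVI column name.
#' @return An `effect_estimate` with `nonlinearity_p` (quadratic, cubic).
#' @export
continuous_ndvi_model <- function(data, spec, ndvi = "ndvi") {
  data$ndvi_01 <- data[[ndvi]] * 10
  sp <- spec
  sp$exposure <- "ndvi_01"
  est <- fit_outcome_model(data, sp)
  rows <- model_rows(data, sp)
  df <- center_age(data[rows, , drop = FALSE])
  fam <- if (sp$family == "logistic") binomial() else gaussian()
  f1 <- spec_formula(sp)
  f2 <- update(f1, . ~ . + I(ndvi_01^2))
  f3 <- update(f2, . ~ . + I(ndvi_01^3))
  fits <- lapply(list(f1, f2, f3), function(f)
    suppressWarnings(glm(f, family = fam, data = df)))
  est$nonlinearity_p <- c(
    quadratic = lmtest::lrtest(fits[[1]], fits[[2]])$`Pr(>Chisq)`[2],
    cubic = lmtest::lrtest(fits[[2]], fits[[3]])$`Pr(>Chisq)`[2])
  est
}

#' Empirical residual semivariogram
#'
#' gamma(h) = (1 / (2 |N(h)|)) * sum over pairs in bin h of the squared
#' residual difference; a flat variogram indicates no residual spatial
#' autocorrelation.
#'
#' @param residuals model residuals.
#' @param x,y coordinates (metres).
#' @param breaks distance bin edges (>= 2 bins).
#' @return Data.frame with bin bounds, `gamma`, pair count `n_pairs`, and
#'   an `empty` flag (gamma is missing for empty bins).
#' @export
residual_semivariogram <- function(residuals, x, y, breaks) {
  stopifnot(length(breaks) >= 3)
  d <- as.vector(dist(cbind(x, y)))
  n <- length(residuals)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dr2 <- (residuals[ij[, 1]] - residuals[ij[, 2]])^2
  bin <- cut(d, breaks, include.lowest = TRUE)
  counts <- tapply(dr2, bin, length)
  gam <- tapply(dr2, bin, sum) / (2 * counts)
  out <- data.frame(lower = head(breaks, -1), upper = breaks[-1],
                    gamma = as.numeric(gam),
                    n_pairs = as.integer(ifelse(is.na(counts), 0, counts)))
  out$empty <- out$n_pairs == 0
  out$gamma[out$empty] <- NA_real_
  out
}
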