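#' Pipeline run configuration
#'
#' Bundles the simulation, exposure, propensity, trimming and modelling
#' settings of one reproducible end-to-end run.  Every stochastic stage
#' derives a named substream seed from the master seed.
#'
#' @param seed master integer seed.
#' @param sim list of overrides for [sim_config()] (or a ready `sim_config`).
#' @param exposure list with `radius_m` and `statistic`.
#' @param propensity list with `v`, `library`, and optional `covariates`.
#' @param trim list with `lower_pct`, `upper_pct`.
#' @param models list with `outcomes` (character) and optional `covariates`.
#' @return A validated `run_config`.
#' @export
run_config <- function(seed = 20160311, sim = list(),
                       exposure = list(radius_m = 250, statistic = "mean"),
                       propensity = list(v = 10,
                                         library = c("mean", "ridge",
                                                     "spline", "xgb")),
                       trim = list(lower_pct = 1, upper_pct = 99),
                       models = list(outcomes = c("term_weight_g", "sga",
                                                  "preterm", "low_apgar"))) {
  sim_cfg <- if (inherits(sim, "sim_config")) sim
             else do.call(sim_config, c(list(seed = seed), sim))
  exposure <- modifyList(list(radius_m = 250, statistic = "mean"), exposure)
  propensity <- modifyList(list(v = 10,
                                library = c("mean", "ridge", "spline", "xgb"),
                                covariates = NULL), propensity)
  trim <- modifyList(list(lower_pct = 1, upper_pct = 99), trim)
  models <- modifyList(list(outcomes = c("term_weight_g", "sga", "preterm",
                                         "low_apgar"), covariates = NULL),
                       models)
  stopifnot(exposure$radius_m > 0,
            exposure$statistic %in% c("mean", "max"),
            propensity$v >= 2,
            trim$lower_pct > 0, trim$upper_pct < 100,
            trim$lower_pct <= trim$upper_pct)
  structure(list(seed = as.integer(seed), sim = sim_cfg, exposure = exposure,
                 propensity = propensity, trim = trim, models = models),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; top-level keys `seed`, `sim`, `exposure`,
#'   `propensity`, `trim`, `models`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "sim", "exposure", "propensity", "trim", "models"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(args$sim)) {
    for (k in c("raster_start", "raster_end"))
      if (!is.null(args$sim[[k]])) args$sim[[k]] <- as.Date(args$sim[[k]])
    if (!is.null(args$sim$birth_window))
      args$sim$birth_window <- as.Date(unlist(args$sim$birth_window))
    for (k in c("n_births", "n_communities", "type_offset", "confound_weights",
                "exclusion_rates", "grid_dim"))
      if (!is.null(args$sim[[k]])) args$sim[[k]] <- unlist(args$sim[[k]])
  }
  do.call(run_config, args)
}

pipeline_stage <- function(name, outdir, produces, log, expr) {
  t0 <- Sys.time()
  log(sprintf("stage %s: start", name))
  result <- tryCatch(expr, error = function(e) {
    for (f in produces) unlink(file.path(outdir, f), recursive = TRUE)
    stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
  log(sprintf("stage %s: done (%.2f s)", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  attr(result, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  result
}

#' Run the full analysis pipeline
#'
#' simulate -> covariates -> outcomes -> exposure -> propensity -> trim ->
#' infer, writing the stage outputs (CSV/JSON) under `outdir` together with a
#' manifest of seeds, row counts, stage timings and output file hashes.
#' Re-running with the same configuration reproduces all numeric outputs.
#'
#' @param config a [run_config()] (or a YAML path).
#' @param outdir output directory.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), msg)
    if (!quiet) message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  timings <- list()

  sim <- pipeline_stage("simulate", outdir,
                        c("cohort.csv", "communities.csv", "raster"), log, {
    raster <- simulate_raster(config$sim)
    layers <- simulate_point_layers(config$sim)
    out <- simulate_cohort(config$sim, raster)
    write.csv(out$cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)
    write.csv(out$communities, file.path(outdir, "communities.csv"),
              row.names = FALSE)
    write_ndvi_stack(raster, file.path(outdir, "raster"))
    for (nm in names(layers))
      write.csv(layers[[nm]], file.path(outdir, paste0(nm, ".csv")),
                row.names = FALSE)
    c(out, list(raster = raster, layers = layers))
  })
  timings$simulate <- attr(sim, "elapsed_s")

  outc <- pipeline_stage("outcomes", outdir,
                         c("exclusion_ledger.json", "outcomes.csv",
                           "growth_reference.csv"), log, {
    excl <- apply_exclusions(sim$cohort)
    jsonlite::write_json(excl$ledger, file.path(outdir, "exclusion_ledger.json"),
                         auto_unbox = TRUE, digits = NA)
    ref <- build_growth_reference(excl$included)
    write.csv(ref, file.path(outdir, "growth_reference.csv"), row.names = FALSE)
    oc <- classify_outcomes(excl$included, ref)
    write.csv(oc, file.path(outdir, "outcomes.csv"), row.names = FALSE)
    list(included = excl$included, ledger = excl$ledger, reference = ref,
         outcomes = oc)
  })
  timings$outcomes <- attr(outc, "elapsed_s")

  cov <- pipeline_stage("covariates", outdir, "covariates.csv", log, {
    panel <- build_covariate_panel(outc$included, sim$communities, sim$layers)
    write.csv(panel, file.path(outdir, "covariates.csv"), row.names = FALSE)
    panel
  })
  timings$covariates <- attr(cov, "elapsed_s")

  expo <- pipeline_stage("exposure", outdir,
                         c("exposure.csv", "exposure_audit.json"), log, {
    a <- assign_exposure(outc$included, sim$raster,
                         config$exposure$radius_m, config$exposure$statistic)
    write.csv(a, file.path(outdir, "exposure.csv"), row.names = FALSE)
    write_exposure_audit(a, file.path(outdir, "exposure_audit.json"))
    a
  })
  timings$exposure <- attr(expo, "elapsed_s")

  ana <- cbind(outc$included[, c("birth_id", "mother_id", "community_id",
                                 "community_type", "x", "y", "birth_date",
                                 "gestational_age")],
               cov[, setdiff(names(cov), "birth_id"), drop = FALSE],
               expo[, c("ndvi", "tertile", "exposed")],
               outc$outcomes[, c("sga", "preterm", "low_apgar",
                                 "term_weight_g")])
  types <- intersect(c("city", "borough", "township"),
                     unique(ana$community_type))
  prop_covs <- config$propensity$covariates
  if (is.null(prop_covs))
    prop_covs <- intersect(c(default_adjustment_covariates(), "public_housing"),
                           names(ana))

  prop <- pipeline_stage("propensity", outdir,
                         c("propensity_scores.csv", "propensity.json"), log, {
    fits <- list()
    for (tp in types)
      fits[[tp]] <- fit_propensity(
        ana[ana$community_type == tp, prop_covs, drop = FALSE],
        ana$exposed[ana$community_type == tp],
        v = config$propensity$v, library = config$propensity$library,
        seed = derive_seed(config$seed, paste0("propensity_", tp)))
    scores <- do.call(rbind, lapply(types, function(tp)
      data.frame(birth_id = ana$birth_id[ana$community_type == tp],
                 community_type = tp, score = fits[[tp]]$scores)))
    write.csv(scores, file.path(outdir, "propensity_scores.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(fits, function(f) list(weights = as.list(f$weights),
                                    learner_risks = as.list(f$learner_risks),
                                    ensemble_risk = f$ensemble_risk,
                                    v = f$v, seed = f$seed)),
      file.path(outdir, "propensity.json"), auto_unbox = TRUE, digits = NA)
    fits
  })
  timings$propensity <- attr(prop, "elapsed_s")

  trimres <- pipeline_stage("trim", outdir,
                            c("trim_bounds.json", "restricted_cohort.csv"),
                            log, {
    res <- list()
    for (tp in types) {
      idx <- ana$community_type == tp
      tr <- trim_common_support(prop[[tp]]$scores, ana$exposed[idx],
                                config$trim$lower_pct, config$trim$upper_pct)
      res[[tp]] <- tr
    }
    keep <- logical(nrow(ana))
    for (tp in types) keep[ana$community_type == tp] <- res[[tp]]$keep
    write.csv(ana[keep, c("birth_id", "community_type")],
              file.path(outdir, "restricted_cohort.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(res, `[[`, "bounds"),
                         file.path(outdir, "trim_bounds.json"),
                         auto_unbox = TRUE, digits = NA)
    c(res, list(keep = keep))
  })
  timings$trim <- attr(trimres, "elapsed_s")

  infer <- pipeline_stage("infer", outdir,
                          c("effects.csv", "effects.json"), log, {
    adj_covs <- config$models$covariates
    if (is.null(adj_covs)) adj_covs <- default_adjustment_covariates()
    rows <- list()
    for (tp in types) {
      sub <- ana[trimres$keep & ana$community_type == tp, , drop = FALSE]
      for (oc in config$models$outcomes) {
        fam <- if (oc == "term_weight_g") "linear" else "logistic"
        covs <- if (oc == "term_weight_g") c(adj_covs, "gestational_age")
                else adj_covs
        for (kind in c("unadjusted", "adjusted")) {
          sp <- model_spec(oc, fam,
                           covariates = if (kind == "adjusted") covs
                                        else if (oc == "term_weight_g")
                                          "gestational_age" else character())
          est <- tryCatch(fit_outcome_model(sub, sp), error = function(e) e)
          rows[[length(rows) + 1L]] <- if (inherits(est, "error"))
            data.frame(community_type = tp, outcome = oc, model = kind,
                       estimate = NA, ci_lower = NA, ci_upper = NA,
                       n = NA, display = "", note = conditionMessage(est))
          else data.frame(
            community_type = tp, outcome = oc, model = kind,
            estimate = if (fam == "logistic") est$or else est$beta,
            ci_lower = est$ci[1], ci_upper = est$ci[2], n = est$n,
            display = sprintf(if (fam == "logistic") "%.2f (%.2f-%.2f)"
                              else "%.0f (%.0f-%.0f)",
                              if (fam == "logistic") est$or else est$beta,
                              est$ci[1], est$ci[2]),
            note = "")
        }
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(outdir, "effects.csv"), row.names = FALSE)
    jsonlite::write_json(tab, file.path(outdir, "effects.json"),
                         auto_unbox = TRUE, digits = NA)
    tab
  })
  timings$infer <- attr(infer, "elapsed_s")

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("pipeline.log", "manifest.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("greenbirth")),
    seed = config$seed,
    stage_seeds = list(
      raster = derive_seed(config$sim$seed, "raster"),
      cohort = derive_seed(config$sim$seed, "cohort"),
      layers = derive_seed(config$sim$seed, "layers")),
    n_raw = nrow(sim$cohort), n_included = nrow(outc$included),
    n_restricted = sum(trimres$keep),
    exposure = config$exposure, trim_percentiles = config$trim,
    timings_s = timings,
    hashes = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("pipeline complete")
  invisible(manifest)
}
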