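#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_raster()], [simulate_cohort()] and [simulate_point_layers()].
#' Defaults encode the study conditions the pipeline is designed for: three
#' community types with a city < borough < township greenness gradient,
#' NDVI on a 250 m grid every 16 days with a late-July seasonal peak (so
#' autumns are greener than springs, which reproduces the strong
#' season-of-birth/greenness-tertile association), covariate mixtures that
#' differ by community type and tilt with local greenness (confounding), and
#' protective true exposure effects on preterm and SGA birth in cities only.
#'
#' @param seed master integer seed; all layers draw named substreams from it.
#' @param n_births named integer vector, births per community type
#'   (`city`, `borough`, `township`).
#' @param n_communities named integer vector, communities per type.
#' @param grid_dim integer `c(nx, ny)` raster dimensions (pixels).
#' @param res_m grid resolution in metres per pixel.
#' @param raster_start,raster_end first/last date covered by the composite
#'   series (16-day cadence).
#' @param birth_window `c(first, last)` dates between which births occur;
#'   must leave at least three full seasons of composites before the first
#'   birth.
#' @param season_ndvi_amplitude amplitude (NDVI units) of the seasonal
#'   sinusoid.
#' @param season_peak_doy day-of-year at which NDVI peaks.  The default
#'   (215, early August) makes autumn greener than spring, the asymmetry
#'   that links birth season to the three-season exposure window.
#' @param base_ndvi landscape mean NDVI before community offsets.
#' @param type_offset named NDVI offsets applied inside community zones.
#' @param spatial_sd standard deviation of the smooth spatial field.
#' @param pixel_noise_sd per-composite white-noise standard deviation.
#' @param missing_rate fraction of raster cells set missing at random.
#' @param covariate_mixtures per-community-type covariate mixture
#'   parameters; see defaults for the expected structure.
#' @param confound_weights named per-covariate weights describing how the
#'   covariate's log-odds tilt with within-type greenness rank (positive =
#'   more prevalent at low greenness).
#' @param confounding_strength global multiplier on `confound_weights`;
#'   0 switches confounding off.
#' @param true_effects list with per-type log odds ratios of binary exposure
#'   (community tertile 2-3 vs 1) on `preterm`, `sga`, `low_apgar`, and a
#'   per-type `weight_g_per_ndvi` slope (grams per unit NDVI) on term
#'   weight.
#' @param outcome_base list of per-type baseline probabilities for
#'   `preterm`, `sga` (latent), and a single `low_apgar` rate.
#' @param structural_overlap_violation logical; plant a covariate stratum
#'   that exists only among low-greenness, unexposed city mothers.
#' @param stratum list defining the violating stratum: `max_rank` (upper
#'   within-type greenness rank bound), `rate` (membership probability among
#'   eligible births), and `outcome_shift` (extra log-odds on preterm/SGA).
#' @param multiple_birth_rate probability that a mother contributes two
#'   births, in `[0, 1]`.
#' @param exclusion_rates planted rates of records that the exclusion
#'   cascade must remove (`unlinked`, `non_singleton`, `stillbirth`,
#'   `birth_defect`).
#' @param n_afos,n_wells,n_roads point-layer sizes.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 20160311,
                       n_births = c(city = 2600, borough = 3800, township = 6500),
                       n_communities = c(city = 12, borough = 18, township = 24),
                       grid_dim = c(72L, 72L),
                       res_m = 250,
                       raster_start = as.Date("2006-01-01"),
                       raster_end = as.Date("2008-12-31"),
                       birth_window = as.Date(c("2007-01-01", "2008-12-15")),
                       season_ndvi_amplitude = 0.15,
                       season_peak_doy = 215,
                       base_ndvi = 0.52,
                       type_offset = c(city = -0.085, borough = -0.02, township = 0.05),
                       spatial_sd = 0.04,
                       pixel_noise_sd = 0.012,
                       missing_rate = 0,
                       covariate_mixtures = default_covariate_mixtures(),
                       confound_weights = c(black = 0.6, hispanic = 0.1,
                                            medical_assistance = 0.3,
                                            smoking = -0.3, antibiotics = 0.2,
                                            primary_care = -0.1,
                                            nulliparous = 0.05,
                                            overweight = 0.2),
                       confounding_strength = 1,
                       true_effects = list(
                         preterm = c(city = log(0.78), borough = 0, township = 0),
                         sga = c(city = log(0.73), borough = 0, township = 0),
                         low_apgar = c(city = 0, borough = 0, township = 0),
                         weight_g_per_ndvi = c(city = 0, borough = 0, township = 0)),
                       outcome_base = list(
                         preterm = c(city = 0.125, borough = 0.105, township = 0.11),
                         sga = c(city = 0.125, borough = 0.092, township = 0.089),
                         low_apgar = 0.02),
                       structural_overlap_violation = FALSE,
                       stratum = list(max_rank = 0.25, rate = 0.6,
                                      outcome_shift = c(preterm = 1.0, sga = 0.8)),
                       multiple_birth_rate = 0.18,
                       exclusion_rates = c(unlinked = 0.002, non_singleton = 0.012,
                                           stillbirth = 0.001, birth_defect = 0.004),
                       n_afos = 40, n_wells = 150, n_roads = 60) {
  cfg <- list(seed = as.integer(seed), n_births = n_births,
              n_communities = n_communities,
              grid_dim = as.integer(grid_dim), res_m = res_m,
              raster_start = as.Date(raster_start),
              raster_end = as.Date(raster_end),
              birth_window = as.Date(birth_window),
              season_ndvi_amplitude = season_ndvi_amplitude,
              season_peak_doy = season_peak_doy,
              base_ndvi = base_ndvi, type_offset = type_offset,
              spatial_sd = spatial_sd, pixel_noise_sd = pixel_noise_sd,
              missing_rate = missing_rate,
              covariate_mixtures = covariate_mixtures,
              confound_weights = confound_weights,
              confounding_strength = confounding_strength,
              true_effects = true_effects, outcome_base = outcome_base,
              structural_overlap_violation = isTRUE(structural_overlap_violation),
              stratum = stratum,
              multiple_birth_rate = multiple_birth_rate,
              exclusion_rates = exclusion_rates,
              n_afos = n_afos, n_wells = n_wells, n_roads = n_roads)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  types <- c("city", "borough", "township")
  if (!all(types %in% names(config$n_births)) ||
      !all(types %in% names(config$n_communities)))
    stop("n_births and n_communities must be named city/borough/township")
  if (any(config$n_births < 0) || all(config$n_births == 0))
    stop("invalid config: n_births must be nonnegative with at least one type > 0")
  active <- config$n_births > 0
  if (any(config$n_communities[types][active[types]] <= 0))
    stop("invalid config: n_communities must be > 0 for types with births")
  if (any(config$grid_dim <= 0)) stop("invalid config: non-positive grid dims")
  if (config$res_m <= 0) stop("invalid config: resolution must be > 0")
  if (config$multiple_birth_rate < 0 || config$multiple_birth_rate > 1)
    stop("invalid config: multiple_birth_rate must be in [0, 1]")
  for (mix in config$covariate_mixtures) {
    for (p in mix[c("race", "bmi_class")]) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("invalid config: mixture proportions must be in [0,1] and sum to 1")
    }
    for (nm in c("medical_assistance", "smoking", "nulliparous", "primary_care"))
      if (mix[[nm]] < 0 || mix[[nm]] > 1)
        stop("invalid config: proportion ", nm, " outside [0, 1]")
  }
  if (any(config$exclusion_rates < 0 | config$exclusion_rates > 1))
    stop("invalid config: exclusion rates must be in [0, 1]")
  config
}

#' Default per-community-type covariate mixtures
#'
#' Proportions chosen to resemble a mixed rural/urban health-system
#' population: cities have more Black and Hispanic mothers, more Medical
#' Assistance receipt, higher walkability and deprivation; townships the
#' reverse.
#'
#' @return Named list with one mixture list per community type.
#' @export
default_covariate_mixtures <- function() {
  list(
    city = list(
      race = c(white = 0.72, black = 0.15, hispanic = 0.11, other = 0.02),
      medical_assistance = 0.59, smoking = 0.19,
      bmi_class = c(under = 0.02, normal = 0.43, over = 0.25, obese = 0.30),
      nulliparous = 0.465, primary_care = 0.37,
      age_mean = 28.4, age_sd = 5.6, antibiotics_lambda = 0.34,
      walkability = c(mean = 2.0, sd = 0.8), csd = c(mean = 4.3, sd = 1.6)),
    borough = list(
      race = c(white = 0.92, black = 0.04, hispanic = 0.03, other = 0.01),
      medical_assistance = 0.48, smoking = 0.23,
      bmi_class = c(under = 0.022, normal = 0.432, over = 0.253, obese = 0.293),
      nulliparous = 0.455, primary_care = 0.49,
      age_mean = 26.9, age_sd = 5.7, antibiotics_lambda = 0.29,
      walkability = c(mean = 0.75, sd = 0.8), csd = c(mean = 0.6, sd = 1.5)),
    township = list(
      race = c(white = 0.952, black = 0.019, hispanic = 0.016, other = 0.013),
      medical_assistance = 0.34, smoking = 0.22,
      bmi_class = c(under = 0.024, normal = 0.403, over = 0.278, obese = 0.295),
      nulliparous = 0.49, primary_care = 0.53,
      age_mean = 25.4, age_sd = 5.8, antibiotics_lambda = 0.27,
      walkability = c(mean = -1.2, sd = 0.7), csd = c(mean = -1.5, sd = 1.2)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  births:", paste(names(x$n_births), x$n_births, sep = "=", collapse = ", "), "\n")
  cat("  grid:", x$grid_dim[1], "x", x$grid_dim[2], "@", x$res_m, "m\n")
  cat("  composites:", format(x$raster_start), "to", format(x$raster_end), "\n")
  cat("  confounding strength:", x$confounding_strength,
      "| structural violation:", x$structural_overlap_violation, "\n")
  invisible(x)
}
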