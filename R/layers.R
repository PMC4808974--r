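#' Simulate point and polygon layers for spatial covariates
#'
#' Animal feeding operations (AFOs) with positive animal-unit counts, mostly
#' sited in the township region; unconventional gas wells with drill dates;
#' road segments (all flagged major); and rectangular municipal
#' water-service polygons covering the city and borough zones plus a
#' minority of township zones.  Coordinates are metres in the raster's local
#' planar frame.
#'
#' @param config a [sim_config()].
#' @param zones optional precomputed [community_zones()].
#' @return List with data.frames `afos` (`x`, `y`, `animal_units`), `wells`
#'   (`x`, `y`, `drill_date`), `roads` (`x1`, `y1`, `x2`, `y2`, `major`),
#'   and `water_polygons` (`xmin`, `xmax`, `ymin`, `ymax`, `municipal`).
#' @export
simulate_point_layers <- function(config, zones = community_zones(config)) {
  validate_sim_config(config)
  ext <- config$grid_dim * config$res_m
  with_seed(derive_seed(config$seed, "layers"), {
    n_a <- config$n_afos
    afos <- data.frame(
      x = runif(n_a, 0.4 * ext[1], ext[1]),   # skew towards the rural side
      y = runif(n_a, 0, ext[2]),
      animal_units = exp(rnorm(n_a, 5.5, 0.8)))
    n_w <- config$n_wells
    wells <- data.frame(
      x = runif(n_w, 0, ext[1]), y = runif(n_w, 0, ext[2]),
      drill_date = config$raster_start +
        round(runif(n_w, 0, as.numeric(config$raster_end - config$raster_start))))
    n_r <- config$n_roads
    x1 <- runif(n_r, 0, ext[1]); y1 <- runif(n_r, 0, ext[2])
    ang <- runif(n_r, 0, pi); len <- runif(n_r, 2000, 10000)
    roads <- data.frame(x1 = x1, y1 = y1,
                        x2 = pmin(pmax(x1 + len * cos(ang), 0), ext[1]),
                        y2 = pmin(pmax(y1 + len * sin(ang), 0), ext[2]),
                        major = TRUE)
    wp <- zones[, c("xmin", "xmax", "ymin", "ymax")]
    wp$municipal <- zones$community_type != "township" |
      runif(nrow(zones)) < 0.3
    list(afos = afos[afos$animal_units > 0, ], wells = wells, roads = roads,
         water_polygons = wp)
  })
}
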