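#' Z-score sum composite index
#'
#' Standardizes each component to mean 0 and SD 1 over the supplied units
#' (population SD, denominator n) and sums across components.  Used for both
#' the walkability index (population density, land-use mix, street
#' connectivity) and community socioeconomic deprivation (six disadvantage
#' indicators, a Townsend-type index).
#'
#' @param components numeric matrix or data.frame, one row per unit, one
#'   column per component; at least two units and positive variance per
#'   component.
#' @return Numeric index per unit (mean 0 by construction).
#' @export
zsum_index <- function(components) {
  m <- as.matrix(components)
  if (nrow(m) < 2) stop("zsum_index needs at least 2 units")
  if (is.null(colnames(m)))
    colnames(m) <- paste0("component_", seq_len(ncol(m)))
  sds <- apply(m, 2, function(x) sqrt(mean((x - mean(x))^2)))
  bad <- sds == 0
  if (any(bad))
    stop("zero-variance component: ",
         paste(colnames(m)[bad], collapse = ", "))
  z <- sweep(sweep(m, 2, colMeans(m)), 2, sds, "/")
  rowSums(z)
}

#' Inverse-squared-distance animal feeding operation exposure
#'
#' Cumulative metric `sum_j AU_j / d_j^2` with distances in kilometres;
#' distances below `floor_km` are clipped to the floor (the inverse-square
#' form is unbounded at zero).
#'
#' @param x,y home coordinates (metres), vectorized.
#' @param afos data.frame with `x`, `y` (metres) and `animal_units` (> 0).
#' @param floor_km distance floor in km.
#' @return Nonnegative exposure per home (animal units per km^2).
#' @export
afo_exposure <- function(x, y, afos, floor_km = 0.1) {
  if (is.null(afos) || nrow(afos) == 0) return(rep(0, length(x)))
  stopifnot(all(afos$animal_units > 0))
  vapply(seq_along(x), function(i) {
    d_km <- pmax(sqrt((afos$x - x[i])^2 + (afos$y - y[i])^2) / 1000, floor_km)
    sum(afos$animal_units / d_km^2)
  }, numeric(1))
}

#' Unconventional wells drilled within a radius before birth
#'
#' @param x,y home coordinates (metres), vectorized.
#' @param wells data.frame with `x`, `y`, `drill_date`.
#' @param birth_date per-home birth date (recycled if scalar).
#' @param radius_km search radius (default 20 km).
#' @return Integer count per home.
#' @export
wells_within <- function(x, y, wells, birth_date, radius_km = 20) {
  stopifnot(radius_km > 0)
  birth_date <- rep(as.Date(birth_date), length.out = length(x))
  if (is.null(wells) || nrow(wells) == 0) return(integer(length(x)))
  vapply(seq_along(x), function(i) {
    d_km <- sqrt((wells$x - x[i])^2 + (wells$y - y[i])^2) / 1000
    sum(d_km <= radius_km & as.Date(wells$drill_date) <= birth_date[i])
  }, integer(1))
}

# Euclidean distance from a point to one segment
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  t <- ifelse(L2 == 0, 0, pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

#' Distance to the nearest major road
#'
#' Minimum point-to-segment Euclidean distance in metres over all segments
#' flagged major.
#'
#' @param x,y home coordinates (metres), vectorized.
#' @param roads data.frame with `x1`, `y1`, `x2`, `y2` and optional `major`.
#' @return Distance in metres per home.
#' @export
road_distance <- function(x, y, roads) {
  if (!is.null(roads$major)) roads <- roads[roads$major, ]
  if (is.null(roads) || nrow(roads) == 0) stop("no road segments supplied")
  vapply(seq_along(x), function(i)
    min(point_segment_distance(x[i], y[i], roads$x1, roads$y1,
                               roads$x2, roads$y2)), numeric(1))
}

#' Medical Assistance status from qualifying encounter counts
#'
#' "Ever" receipt requires a qualifying code at more than two encounters.
#'
#' @param qualifying_encounters integer vector of encounters with a
#'   qualifying code per mother.
#' @return Factor `never`/`ever`.
#' @export
medical_assistance <- function(qualifying_encounters) {
  factor(ifelse(qualifying_encounters > 2, "ever", "never"),
         levels = c("never", "ever"))
}

#' Smoking status during gestation
#'
#' A mother is an ever-smoker for a pregnancy iff any smoking record date
#' falls inside the gestation interval (inclusive bounds).
#'
#' @param record_dates `Date` vector (NA = no record), one per birth.
#' @param start,end gestation interval bounds per birth.
#' @return Factor `never`/`ever`.
#' @export
smoking_status <- function(record_dates, start, end) {
  record_dates <- as.Date(record_dates)
  hit <- !is.na(record_dates) & record_dates >= as.Date(start) &
    record_dates <= as.Date(end)
  factor(ifelse(hit, "ever", "never"), levels = c("never", "ever"))
}

point_in_rectangles <- function(x, y, rects) {
  out <- logical(length(x))
  for (r in seq_len(nrow(rects))) {
    inside <- x >= rects$xmin[r] & x <= rects$xmax[r] &
      y >= rects$ymin[r] & y <= rects$ymax[r]
    out <- out | inside
  }
  out
}

quartile_labels <- function(x) {
  q <- unname(quantile(x, c(1, 2, 3) / 4, type = 7))
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}

#' Build the full covariate panel for a cohort
#'
#' Joins community-level composite indices (walkability and deprivation
#' z-sums computed over the study communities), spatial covariates (AFO
#' exposure, well counts, road distance, water source), and bespoke
#' individual covariates (Medical Assistance from encounter counts, smoking
#' during gestation, season and year-band of birth, BMI class with 18.5/25/30
#' cutpoints, age and age squared).
#'
#' @param cohort cohort data.frame (see [simulate_cohort()]).
#' @param communities community table with walkability and deprivation
#'   component columns.
#' @param layers point layers from [simulate_point_layers()].
#' @return Data.frame keyed by `birth_id` with one column per derived
#'   covariate; z-score parameters are attached as attribute `"z_params"`.
#' @export
build_covariate_panel <- function(cohort, communities, layers) {
  walk_comp <- communities[, c("pop_density", "landuse_mix", "connectivity")]
  csd_comp <- communities[, c("low_education", "unemployed",
                              "not_in_labor_force", "poverty",
                              "public_assistance", "no_car")]
  communities$walkability <- zsum_index(walk_comp)
  communities$csd <- zsum_index(csd_comp)
  ci <- match(cohort$community_id, communities$community_id)
  municipal_rects <- layers$water_polygons[layers$water_polygons$municipal, ]
  water <- point_in_rectangles(cohort$x, cohort$y, municipal_rects)
  panel <- data.frame(
    birth_id = cohort$birth_id,
    walkability = communities$walkability[ci],
    csd = communities$csd[ci],
    csd_quartile = NA_integer_,
    afo = afo_exposure(cohort$x, cohort$y, layers$afos),
    wells_20km = wells_within(cohort$x, cohort$y, layers$wells,
                              cohort$birth_date),
    road_distance_m = road_distance(cohort$x, cohort$y, layers$roads),
    water_source = factor(ifelse(water, "municipal", "non-municipal"),
                          levels = c("municipal", "non-municipal")),
    medical_assistance = medical_assistance(cohort$ma_qualifying_encounters),
    smoking = smoking_status(cohort$smoking_record_date,
                             cohort$conception_date, cohort$birth_date),
    season_of_birth = season_of_date(cohort$birth_date)$season,
    year_band = cut(as.integer(format(as.Date(cohort$birth_date), "%Y")),
                    c(-Inf, 2007, 2010, Inf),
                    labels = c("2006-2007", "2008-2010", "2011-2013")),
    maternal_age = cohort$maternal_age,
    maternal_age2 = cohort$maternal_age^2,
    race = factor(cohort$race, levels = c("white", "black", "hispanic", "other")),
    bmi_class = stats::relevel(cut(cohort$bmi, c(-Inf, 18.5, 25, 30, Inf),
                                   right = FALSE,
                                   labels = c("under", "normal", "over",
                                              "obese")),
                               ref = "normal"),
    parity = factor(ifelse(cohort$nulliparous, "nulliparous", "multiparous"),
                    levels = c("nulliparous", "multiparous")),
    antibiotic_orders = cohort$antibiotic_orders,
    primary_care = cohort$primary_care,
    hospital = factor(cohort$hospital),
    sex = factor(cohort$sex, levels = c("female", "male")),
    stringsAsFactors = FALSE)
  panel$csd_quartile <- quartile_labels(panel$csd)
  if (!is.null(cohort$public_housing)) panel$public_housing <- cohort$public_housing
  attr(panel, "z_params") <- list(
    walkability = list(mean = colMeans(walk_comp),
                       sd = apply(walk_comp, 2, function(x) sqrt(mean((x - mean(x))^2)))),
    csd = list(mean = colMeans(csd_comp),
               sd = apply(csd_comp, 2, function(x) sqrt(mean((x - mean(x))^2)))))
  panel
}
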