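#' Meteorological season of a calendar date
#'
#' Winter is December--February, spring March--May, summer June--August,
#' fall September--November.  December is anchored to the winter instance
#' that spans into the following year, so the season *instance* year of
#' December 2007 is winter 2008.
#'
#' @param date a `Date` vector.
#' @return A data.frame with `season` (factor winter/spring/summer/fall) and
#'   `season_year` (instance year).
#' @export
season_of_date <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- c("winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "fall", "fall", "fall",
              "winter")[m]
  data.frame(season = factor(season,
                             levels = c("winter", "spring", "summer", "fall")),
             season_year = y + (m == 12L))
}

season_bounds <- function(season, year) {
  start <- switch(season,
                  winter = as.Date(sprintf("%d-12-01", year - 1)),
                  spring = as.Date(sprintf("%d-03-01", year)),
                  summer = as.Date(sprintf("%d-06-01", year)),
                  fall   = as.Date(sprintf("%d-09-01", year)))
  end <- switch(season,
                winter = as.Date(sprintf("%d-03-01", year)) - 1,
                spring = as.Date(sprintf("%d-06-01", year)) - 1,
                summer = as.Date(sprintf("%d-09-01", year)) - 1,
                fall   = as.Date(sprintf("%d-12-01", year)) - 1)
  c(start = start, end = end)
}

prev_season <- function(season, year) {
  ord <- c("winter", "spring", "summer", "fall")
  i <- match(season, ord)
  if (i == 1L) list(season = "fall", year = year - 1L)
  else list(season = ord[i - 1L], year = year)
}

#' Three-season exposure window preceding a birth
#'
#' The exposure window is the three seasons prior to the birth date, unless
#' the child was born more than halfway through its season of birth, in
#' which case the two prior seasons and the season of birth are used.
#' "More than halfway" is strictly more than half the season's actual
#' day count; a birth exactly at the midpoint uses the earlier window.
#'
#' @param birth_date a single `Date`.
#' @return A data.frame of three rows (oldest first) with `season`,
#'   `season_year`, `start`, `end`.
#' @export
season_window <- function(birth_date) {
  birth_date <- as.Date(birth_date)
  stopifnot(length(birth_date) == 1L, !is.na(birth_date))
  s <- season_of_date(birth_date)
  lab <- as.character(s$season); yr <- s$season_year
  b <- season_bounds(lab, yr)
  len <- as.numeric(b["end"] - b["start"]) + 1
  day <- as.numeric(birth_date - b["start"]) + 1
  last <- if (day > len / 2) list(season = lab, year = yr)
          else prev_season(lab, yr)
  mid <- prev_season(last$season, last$year)
  first <- prev_season(mid$season, mid$year)
  out <- do.call(rbind, lapply(list(first, mid, last), function(si) {
    bb <- season_bounds(si$season, si$year)
    data.frame(season = si$season, season_year = si$year,
               start = bb["start"], end = bb["end"], row.names = NULL)
  }))
  out
}

# pixel-centre index set within radius of (x, y); home pixel always included
buffer_pixels <- function(raster, x, y, radius_m) {
  d <- dim(raster$values)
  res <- raster$res_m
  px <- function(coord, o) floor((coord - o) / res) + 1L
  i0 <- px(x, raster$origin[1]); j0 <- px(y, raster$origin[2])
  if (i0 < 1L || i0 > d[1] || j0 < 1L || j0 > d[2])
    stop("location falls outside the raster extent")
  r_px <- ceiling(radius_m / res) + 1L
  ii <- max(1L, i0 - r_px):min(d[1], i0 + r_px)
  jj <- max(1L, j0 - r_px):min(d[2], j0 + r_px)
  cxs <- raster$origin[1] + (ii - 0.5) * res
  cys <- raster$origin[2] + (jj - 0.5) * res
  dist2 <- outer((cxs - x)^2, (cys - y)^2, "+")
  keep <- which(dist2 <= radius_m^2 + 1e-9, arr.ind = TRUE)
  sel <- cbind(i = ii[keep[, 1]], j = jj[keep[, 2]])
  home <- cbind(i = i0, j = j0)
  if (!any(sel[, 1] == i0 & sel[, 2] == j0)) sel <- rbind(sel, home)
  sel
}

#' Buffer-mean NDVI around a home location
#'
#' Arithmetic mean of NDVI over all (pixel, composite-date) pairs whose
#' pixel centre lies within `radius_m` of the home (the home pixel is always
#' included) and whose date is among `dates`.  Missing cells are excluded
#' from numerator and denominator.  On a 250 m grid, a 250 m radius centred
#' on a pixel yields the 5-pixel "plus" (centre plus four orthogonal
#' neighbours); a 1250 m radius yields the 5-pixel-radius disc.
#'
#' @param raster an [ndvi_stack()].
#' @param x,y home coordinates in metres (inside the raster).
#' @param radius_m positive buffer radius in metres.
#' @param dates composite dates to average over (default: all in the stack).
#' @return Mean NDVI (scalar).
#' @export
buffer_mean <- function(raster, x, y, radius_m, dates = raster$dates) {
  sel <- buffer_pixels(raster, x, y, radius_m)
  ti <- which(raster$dates %in% as.Date(dates))
  if (length(ti) == 0L) stop("no composite dates selected")
  v <- raster$values[cbind(rep(sel[, 1], length(ti)),
                           rep(sel[, 2], length(ti)),
                           rep(ti, each = nrow(sel)))]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no NDVI data in buffer (all cells missing)")
  mean(v)
}

# per-composite buffer means (used by the max-NDVI variant)
buffer_series <- function(raster, x, y, radius_m, dates = raster$dates) {
  sel <- buffer_pixels(raster, x, y, radius_m)
  ti <- which(raster$dates %in% as.Date(dates))
  if (length(ti) == 0L) stop("no composite dates selected")
  vapply(ti, function(t) {
    v <- raster$values[cbind(sel[, 1], sel[, 2], t)]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

#' Season-window NDVI summary for one birth
#'
#' Selects the composite dates falling inside the three-season window for
#' `birth_date` and summarizes the buffer NDVI with `mean` (pooled over all
#' pixel x date pairs) or `max` (maximum of per-composite buffer means).
#'
#' @inheritParams buffer_mean
#' @param birth_date the child's birth date.
#' @param statistic `"mean"` or `"max"`.
#' @return Scalar NDVI summary.
#' @export
window_ndvi <- function(raster, x, y, birth_date, radius_m = 250,
                        statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  win <- season_window(birth_date)
  dts <- raster$dates[raster$dates >= min(win$start) & raster$dates <= max(win$end)]
  if (length(dts) == 0L) stop("no composites available in the season window")
  if (statistic == "mean") buffer_mean(raster, x, y, radius_m, dts)
  else {
    s <- buffer_series(raster, x, y, radius_m, dts)
    if (all(is.na(s))) stop("no NDVI data in buffer (all cells missing)")
    max(s, na.rm = TRUE)
  }
}

# date range [start, end] of the three-season window per birth date,
# vectorized (same midpoint rule as season_window, without its per-date
# data-frame overhead)
window_date_ranges <- function(birth_dates) {
  lt <- as.POSIXlt(birth_dates)
  m <- lt$mon + 1L
  y <- lt$year + 1900L
  s <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[m]  # w/sp/su/f
  sy <- y + (m == 12L)
  labs <- c("winter", "spring", "summer", "fall")
  key <- paste(s, sy)
  uk <- unique(key)
  bounds <- lapply(uk, function(k) {
    p <- as.integer(strsplit(k, " ")[[1]])
    season_bounds(labs[p[1]], p[2])
  })
  names(bounds) <- uk
  starts <- as.Date(vapply(bounds[key], function(b) as.numeric(b["start"]),
                           numeric(1)), origin = "1970-01-01")
  ends <- as.Date(vapply(bounds[key], function(b) as.numeric(b["end"]),
                         numeric(1)), origin = "1970-01-01")
  len <- as.numeric(ends - starts) + 1
  day <- as.numeric(as.Date(birth_dates) - starts) + 1
  include_birth <- day > len / 2
  # window covers 3 consecutive season instances; seasons are month-aligned
  # except winter boundaries, so step back whole seasons from the last one
  last_end <- ends
  nback <- ifelse(include_birth, 2L, 3L)
  shift_season <- function(sv, syv, k) {
    idx <- sv - k
    list(s = ((idx - 1L) %% 4L) + 1L, sy = syv + floor((idx - 1L) / 4L))
  }
  prev <- shift_season(s, sy, nback)
  first_key <- paste(prev$s, prev$sy)
  ufk <- unique(first_key)
  fb <- lapply(ufk, function(k) {
    p <- as.integer(strsplit(k, " ")[[1]])
    season_bounds(labs[p[1]], p[2])
  })
  names(fb) <- ufk
  win_start <- as.Date(vapply(fb[first_key], function(b) as.numeric(b["start"]),
                              numeric(1)), origin = "1970-01-01")
  lastk <- shift_season(s, sy, ifelse(include_birth, 0L, 1L))
  last_key <- paste(lastk$s, lastk$sy)
  ulk <- unique(last_key)
  lb <- lapply(ulk, function(k) {
    p <- as.integer(strsplit(k, " ")[[1]])
    season_bounds(labs[p[1]], p[2])
  })
  names(lb) <- ulk
  win_end <- as.Date(vapply(lb[last_key], function(b) as.numeric(b["end"]),
                            numeric(1)), origin = "1970-01-01")
  data.frame(start = win_start, end = win_end)
}

# vectorized window_ndvi with caching of season windows by unique birth date;
# complete rasters use a cumulative-sum fast path for the mean statistic
window_ndvi_vec <- function(raster, x, y, birth_dates, radius_m = 250,
                            statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  birth_dates <- as.Date(birth_dates)
  key <- as.integer(birth_dates)
  ud <- unique(key)
  wr <- window_date_ranges(as.Date(ud, origin = "1970-01-01"))
  rd <- as.numeric(raster$dates)
  t1 <- findInterval(as.numeric(wr$start) - 0.5, rd) + 1L
  t2 <- findInterval(as.numeric(wr$end) + 0.5, rd)
  dmap <- lapply(seq_along(ud), function(i) c(t1[i], t2[i]))
  names(dmap) <- as.character(ud)
  n <- length(x)
  out <- numeric(n)
  d3 <- dim(raster$values)
  complete <- !anyNA(raster$values)
  if (statistic == "mean" && complete) {
    # per-pixel cumulative sums over time give each window-mean layer in
    # O(1); births are grouped by window and the buffer accumulated over
    # pixel offsets for all of a group's births at once
    flat <- matrix(raster$values, d3[1] * d3[2], d3[3])
    csum <- flat
    for (t in seq_len(d3[3])[-1]) csum[, t] <- csum[, t - 1] + flat[, t]
    res <- raster$res_m
    i0 <- floor((x - raster$origin[1]) / res) + 1L
    j0 <- floor((y - raster$origin[2]) / res) + 1L
    if (any(i0 < 1L | i0 > d3[1] | j0 < 1L | j0 > d3[2]))
      stop("location falls outside the raster extent")
    r_px <- ceiling(radius_m / res) + 1L
    offs <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
    wkey <- vapply(dmap, function(tr) paste(tr, collapse = "_"), character(1))
    for (wk in unique(wkey[as.character(key)])) {
      tr <- dmap[[which(wkey == wk)[1]]]
      if (tr[1] > tr[2]) stop("no composites available in the season window")
      W <- (csum[, tr[2]] - (if (tr[1] > 1) csum[, tr[1] - 1] else 0)) /
        (tr[2] - tr[1] + 1)
      g <- which(wkey[as.character(key)] == wk)
      acc <- numeric(length(g)); cnt <- numeric(length(g))
      for (o in seq_len(nrow(offs))) {
        di <- offs$di[o]; dj <- offs$dj[o]
        ii <- i0[g] + di; jj <- j0[g] + dj
        cxs <- raster$origin[1] + (ii - 0.5) * res
        cys <- raster$origin[2] + (jj - 0.5) * res
        ok <- ii >= 1L & ii <= d3[1] & jj >= 1L & jj <= d3[2] &
          ((cxs - x[g])^2 + (cys - y[g])^2 <= radius_m^2 + 1e-9 |
             (di == 0L & dj == 0L))
        if (!any(ok)) next
        idx <- ii[ok] + (jj[ok] - 1L) * d3[1]
        acc[ok] <- acc[ok] + W[idx]
        cnt[ok] <- cnt[ok] + 1
      }
      out[g] <- acc / cnt
    }
    return(out)
  }
  for (i in seq_len(n)) {
    tr <- dmap[[as.character(key[i])]]
    if (tr[1] > tr[2] || is.infinite(tr[1]))
      stop("no composites available in the season window")
    ti <- tr[1]:tr[2]
    sel <- buffer_pixels(raster, x[i], y[i], radius_m)
    if (statistic == "mean") {
      v <- raster$values[cbind(rep(sel[, 1], length(ti)),
                               rep(sel[, 2], length(ti)),
                               rep(ti, each = nrow(sel)))]
      v <- v[!is.na(v)]
      if (length(v) == 0L) stop("no NDVI data in buffer (all cells missing)")
      out[i] <- mean(v)
    } else {
      s <- vapply(ti, function(t) {
        v <- raster$values[cbind(sel[, 1], sel[, 2], t)]
        v <- v[!is.na(v)]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      if (all(is.na(s))) stop("no NDVI data in buffer (all cells missing)")
      out[i] <- max(s, na.rm = TRUE)
    }
  }
  out
}

#' Tertile labels with linear-interpolation cutpoints
#'
#' Cutpoints are the empirical 33.3rd and 66.7th percentiles
#' (linear-interpolation quantiles); boundary values go to the lower
#' tertile.
#'
#' @param x numeric vector.
#' @param cutpoints optional fixed cutpoints `c(q1, q2)`.
#' @return Integer labels in `{1, 2, 3}` with the cutpoints as an attribute.
#' @export
tertile_labels <- function(x, cutpoints = NULL) {
  if (is.null(cutpoints))
    cutpoints <- unname(quantile(x, c(1, 2) / 3, type = 7, na.rm = TRUE))
  lab <- 1L + (x > cutpoints[1]) + (x > cutpoints[2])
  attr(lab, "cutpoints") <- cutpoints
  lab
}

#' Assign greenness exposure to a cohort
#'
#' One row per birth: the season-window NDVI summary at the requested buffer
#' radius, tertile labels computed within community type on the supplied
#' (analysis) sample, pooled overall tertiles for descriptive use, and the
#' binary exposure contrast (community tertile 2--3 vs 1).
#'
#' @param cohort data.frame with `birth_id`, `x`, `y`, `birth_date`,
#'   `community_type`.
#' @param raster an [ndvi_stack()].
#' @param radius_m buffer radius in metres (250 or 1250 in the main and
#'   sensitivity analyses; any positive value accepted).
#' @param statistic `"mean"` or `"max"` NDVI summary over the window.
#' @return A data.frame with `birth_id`, `ndvi`, `tertile` (within community
#'   type), `tertile_overall`, `exposed` (tertile >= 2); per-type cutpoints
#'   are attached as attribute `"cutpoints"` (also overall as
#'   `"cutpoints_overall"`).
#' @export
assign_exposure <- function(cohort, raster, radius_m = 250,
                            statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("birth_id", "x", "y", "birth_date", "community_type")
                %in% names(cohort)))
  nd <- window_ndvi_vec(raster, cohort$x, cohort$y, cohort$birth_date,
                        radius_m, statistic)
  types <- unique(as.character(cohort$community_type))
  tert <- integer(nrow(cohort))
  cuts <- list()
  for (tp in types) {
    idx <- which(cohort$community_type == tp)
    lab <- tertile_labels(nd[idx])
    tert[idx] <- lab
    cuts[[tp]] <- attr(lab, "cutpoints")
  }
  overall <- tertile_labels(nd)
  out <- data.frame(birth_id = cohort$birth_id, ndvi = nd,
                    community_type = cohort$community_type,
                    tertile = tert,
                    tertile_overall = as.integer(overall),
                    exposed = tert >= 2L,
                    stringsAsFactors = FALSE)
  attr(out, "cutpoints") <- cuts
  attr(out, "cutpoints_overall") <- attr(overall, "cutpoints")
  attr(out, "radius_m") <- radius_m
  attr(out, "statistic") <- statistic
  out
}

#' Dichotomize greenness at a community-specific percentile
#'
#' Indicator that a birth's NDVI summary is at or above the community-type
#' p-th percentile (linear-interpolation quantile); used in sensitivity
#' analyses with `p = 20`.
#'
#' @param assignments output of [assign_exposure()].
#' @param p percentile in (0, 100).
#' @return Logical vector, with the per-type thresholds as attribute
#'   `"thresholds"`.
#' @export
dichotomize_at_percentile <- function(assignments, p) {
  stopifnot(p > 0, p < 100)
  out <- logical(nrow(assignments))
  thr <- list()
  for (tp in unique(as.character(assignments$community_type))) {
    idx <- which(assignments$community_type == tp)
    q <- unname(quantile(assignments$ndvi[idx], p / 100, type = 7))
    out[idx] <- assignments$ndvi[idx] >= q
    thr[[tp]] <- q
  }
  attr(out, "thresholds") <- thr
  out
}

#' Write the exposure audit file
#'
#' Records the tertile cutpoints per community type (and the pooled
#' cutpoints), buffer radius and summary statistic as JSON, the format used
#' for regression tests against observed cutpoints.
#'
#' @param assignments output of [assign_exposure()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_exposure_audit <- function(assignments, path) {
  audit <- list(radius_m = attr(assignments, "radius_m"),
                statistic = attr(assignments, "statistic"),
                cutpoints = lapply(attr(assignments, "cutpoints"),
                                   function(q) list(q1 = q[1], q2 = q[2])),
                cutpoints_overall = as.list(setNames(
                  attr(assignments, "cutpoints_overall"), c("q1", "q2"))),
                computed_on = "post-exclusion analysis sample")
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
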