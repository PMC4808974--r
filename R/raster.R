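#' NDVI composite raster stack
#'
#' A minimal array-backed container for a time series of NDVI composite
#' grids in a local planar frame: a `nx x ny x n_dates` array of NDVI
#' values, the origin of the grid's lower-left corner (metres), the pixel
#' resolution (metres), and the ordered composite dates.  Pixel centres sit
#' at `origin + (i - 0.5) * res_m`.
#'
#' @param values numeric array `c(nx, ny, n_dates)`; NDVI in `[-1, 1]` or
#'   `NA` for missing cells.
#' @param origin numeric `c(x0, y0)` in metres.
#' @param res_m resolution in metres per pixel, `> 0`.
#' @param dates strictly increasing `Date` vector of composite dates.
#' @return An object of class `ndvi_stack`.
#' @export
ndvi_stack <- function(values, origin = c(0, 0), res_m = 250, dates) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dates <- as.Date(dates)
  if (dim(values)[3] != length(dates))
    stop("third array dimension must match the number of composite dates")
  if (length(dates) > 1 && any(diff(dates) <= 0))
    stop("composite dates must be strictly increasing")
  if (res_m <= 0) stop("resolution must be > 0")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    stop("NDVI values must lie in [-1, 1] (or NA)")
  structure(list(values = values, origin = as.numeric(origin),
                 res_m = res_m, dates = dates),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<ndvi_stack> ", d[1], "x", d[2], " pixels @ ", x$res_m, " m, ",
      d[3], " composites (", format(min(x$dates)), " .. ",
      format(max(x$dates)), ")\n", sep = "")
  invisible(x)
}

#' Community zone layout implied by a simulation configuration
#'
#' Communities are axis-aligned rectangles on a tile lattice inside the
#' raster extent (real geography is out of scope; rectangles keep distance
#' and containment computations exactly testable).  Tiles are assigned to
#' community types left to right -- cities on the low-greenness side,
#' townships on the high side -- which, combined with the per-type NDVI
#' offsets, yields the city < borough < township greenness ordering.
#'
#' @param config a [sim_config()].
#' @return A data.frame with one row per community: `community_id`,
#'   `community_type`, zone bounds `xmin/xmax/ymin/ymax` (metres), and the
#'   community NDVI offset.
#' @export
community_zones <- function(config) {
  types <- c("city", "borough", "township")
  counts <- config$n_communities[types]
  counts[config$n_births[types] == 0] <- 0L
  m <- sum(counts)
  if (m == 0) stop("no communities requested")
  ext <- config$grid_dim * config$res_m
  margin <- 6 * config$res_m          # keep 1250 m buffers inside the grid
  ncol_t <- ceiling(sqrt(m))
  nrow_t <- ceiling(m / ncol_t)
  tw <- (ext[1] - 2 * margin) / ncol_t
  th <- (ext[2] - 2 * margin) / nrow_t
  idx <- seq_len(m) - 1L
  col <- idx %/% nrow_t               # fill columns first: left -> right
  row <- idx %% nrow_t
  pad_x <- 0.1 * tw
  pad_y <- 0.1 * th
  # community-level NDVI heterogeneity, proportional to the spatial texture
  jit <- with_seed(derive_seed(config$seed, "zones"),
                   rnorm(m, 0, 0.3 * config$spatial_sd))
  data.frame(
    community_id = sprintf("c%03d", seq_len(m)),
    community_type = rep(types, counts),
    xmin = margin + col * tw + pad_x, xmax = margin + (col + 1) * tw - pad_x,
    ymin = margin + row * th + pad_y, ymax = margin + (row + 1) * th - pad_y,
    ndvi_offset = config$type_offset[rep(types, counts)] + jit,
    stringsAsFactors = FALSE)
}

#' Simulate an NDVI composite raster stack
#'
#' Generates a smooth spatial NDVI field (large-scale gradient plus
#' low-frequency noise), lowers or raises it inside community zones by the
#' per-type offsets (cities less green than townships), and adds a seasonal
#' sinusoid peaking in late summer plus per-composite white noise.  Values
#' are clamped to `[-1, 1]`.
#'
#' @param config a [sim_config()]; grid must be at least 16 x 16 and the
#'   composite series must span at least two years.
#' @param zones optional precomputed [community_zones()] layout.
#' @return An [ndvi_stack()].
#' @export
simulate_raster <- function(config, zones = community_zones(config)) {
  validate_sim_config(config)
  if (any(config$grid_dim < 16)) stop("invalid config: grid must be at least 16 x 16")
  dates <- seq(config$raster_start, config$raster_end, by = 16)
  if (as.numeric(config$raster_end - config$raster_start) < 2 * 365)
    stop("invalid config: composite series must span at least 2 years")
  nx <- config$grid_dim[1]; ny <- config$grid_dim[2]
  res <- config$res_m
  cx <- (seq_len(nx) - 0.5) * res
  cy <- (seq_len(ny) - 0.5) * res
  with_seed(derive_seed(config$seed, "raster"), {
    u <- (cx / (nx * res)) - 0.5
    v <- (cy / (ny * res)) - 0.5
    base <- matrix(config$base_ndvi, nx, ny)
    if (config$spatial_sd > 0) {
      base <- base + outer(1.0 * config$spatial_sd * u, rep(1, ny)) # west-east gradient
      for (k in 1:4) {                                   # low-frequency texture
        fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
        ph <- runif(1, 0, 2 * pi)
        base <- base + (config$spatial_sd / 2) *
          cos(2 * pi * outer(fx * u, fy * v, "+") + ph)
      }
    }
    for (z in seq_len(nrow(zones))) {
      zi <- which(cx >= zones$xmin[z] & cx <= zones$xmax[z])
      zj <- which(cy >= zones$ymin[z] & cy <= zones$ymax[z])
      base[zi, zj] <- base[zi, zj] + zones$ndvi_offset[z]
    }
    doy <- as.numeric(format(dates, "%j"))
    seas <- config$season_ndvi_amplitude *
      cos(2 * pi * (doy - config$season_peak_doy) / 365.25)
    vals <- array(NA_real_, c(nx, ny, length(dates)))
    for (t in seq_along(dates)) {
      layer <- base + seas[t]
      if (config$pixel_noise_sd > 0)
        layer <- layer + rnorm(nx * ny, 0, config$pixel_noise_sd)
      vals[, , t] <- layer
    }
    vals <- pmin(pmax(vals, -1), 1)
    if (config$missing_rate > 0) {
      drop <- runif(length(vals)) < config$missing_rate
      vals[drop] <- NA_real_
    }
    ndvi_stack(vals, origin = c(0, 0), res_m = res, dates = dates)
  })
}

#' Write / read an NDVI stack as plain-text grids with a JSON sidecar
#'
#' One whitespace-delimited grid file per composite date plus
#' `stack.json` recording origin, resolution and dates.
#'
#' @param raster an [ndvi_stack()].
#' @param dir directory to write to (created if needed).
#' @return `write_ndvi_stack` returns `dir` invisibly; `read_ndvi_stack`
#'   returns the reconstructed [ndvi_stack()].
#' @export
write_ndvi_stack <- function(raster, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("ndvi_%s.txt", format(raster$dates, "%Y%m%d"))
  for (t in seq_along(raster$dates))
    write(raster$values[, , t], file.path(dir, files[t]),
          ncolumns = dim(raster$values)[1])
  sidecar <- list(origin = raster$origin, res_m = raster$res_m,
                  dates = format(raster$dates), files = files,
                  dim = dim(raster$values)[1:2])
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ndvi_stack
#' @export
read_ndvi_stack <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  nx <- sc$dim[1]; ny <- sc$dim[2]
  vals <- array(NA_real_, c(nx, ny, length(sc$files)))
  for (t in seq_along(sc$files))
    vals[, , t] <- matrix(scan(file.path(dir, sc$files[t]), quiet = TRUE),
                          nx, ny)
  ndvi_stack(vals, origin = sc$origin, res_m = sc$res_m,
             dates = as.Date(sc$dates))
}
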