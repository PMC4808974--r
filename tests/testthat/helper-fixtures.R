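# shared fixtures: small configurations and hand-built rasters

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed,
               n_births = c(city = 300, borough = 300, township = 400),
               n_communities = c(city = 3, borough = 3, township = 4),
               grid_dim = c(48L, 48L))
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# constant-field configuration (degenerate raster)
flat_config <- function(seed = 1, base = 0.5) {
  tiny_config(seed = seed,
              season_ndvi_amplitude = 0, spatial_sd = 0,
              pixel_noise_sd = 0, base_ndvi = base,
              type_offset = c(city = 0, borough = 0, township = 0))
}

# small raster with explicit values
make_stack <- function(values, res_m = 250, dates = as.Date("2007-06-10")) {
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  ndvi_stack(values, origin = c(0, 0), res_m = res_m, dates = dates)
}

# brute-force buffer mean: double loop over pixels x dates
brute_buffer_mean <- function(raster, x, y, radius_m, dates = raster$dates) {
  d <- dim(raster$values)
  res <- raster$res_m
  home_i <- floor((x - raster$origin[1]) / res) + 1
  home_j <- floor((y - raster$origin[2]) / res) + 1
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    cx <- raster$origin[1] + (i - 0.5) * res
    cy <- raster$origin[2] + (j - 0.5) * res
    inside <- sqrt((cx - x)^2 + (cy - y)^2) <= radius_m + 1e-9 ||
      (i == home_i && j == home_j)
    if (!inside) next
    for (t in which(raster$dates %in% dates)) {
      v <- raster$values[i, j, t]
      if (!is.na(v)) vals <- c(vals, v)
    }
  }
  if (length(vals) == 0) stop("all missing")
  mean(vals)
}

# brute-force linear-interpolation percentile (quantile type 7 by hand)
brute_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force trim oracle: sort, index percentiles, filter
brute_trim <- function(scores, exposed, lower_pct = 1, upper_pct = 99) {
  lo <- brute_percentile(scores[exposed], lower_pct / 100)
  hi <- brute_percentile(scores[!exposed], upper_pct / 100)
  scores >= lo & scores <= hi
}
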