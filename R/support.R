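#' Trim to the region of propensity-score common support
#'
#' Retains subjects whose propensity score lies (inclusively) between the
#' 1st percentile of scores among the exposed and the 99th percentile among
#' the unexposed (linear-interpolation empirical percentiles).  Restricting
#' to this overlap region removes subjects without comparable counterparts
#' at the other exposure level and so repairs practical positivity
#' violations.
#'
#' @param scores propensity scores.
#' @param exposed logical exposure indicator (both groups nonempty).
#' @param lower_pct,upper_pct trim percentiles (defaults 1 and 99).
#' @return List with `keep` (logical), and `bounds`: `lower`, `upper`, and
#'   per-group excluded counts and fractions.
#' @export
trim_common_support <- function(scores, exposed, lower_pct = 1,
                                upper_pct = 99) {
  exposed <- as.logical(exposed)
  if (!any(exposed) || !any(!exposed))
    stop("both exposure groups must be nonempty")
  lower <- unname(quantile(scores[exposed], lower_pct / 100, type = 7))
  upper <- unname(quantile(scores[!exposed], upper_pct / 100, type = 7))
  if (lower > upper)
    stop(sprintf(paste0("no common support: lower bound %.6f (p%s among ",
                        "exposed) exceeds upper bound %.6f (p%s among ",
                        "unexposed)"),
                 lower, format(lower_pct), upper, format(upper_pct)))
  keep <- scores >= lower & scores <= upper
  bounds <- list(
    lower = lower, upper = upper,
    lower_pct = lower_pct, upper_pct = upper_pct,
    n_exposed = sum(exposed), n_unexposed = sum(!exposed),
    excluded_exposed = sum(exposed & !keep),
    excluded_unexposed = sum(!exposed & !keep),
    frac_excluded_exposed = mean(!keep[exposed]),
    frac_excluded_unexposed = mean(!keep[!exposed]),
    # per-side shares fixed by the percentile definition itself
    frac_exposed_below_lower = mean(scores[exposed] < lower),
    frac_unexposed_above_upper = mean(scores[!exposed] > upper))
  list(keep = keep, bounds = bounds)
}

#' Overlap diagnostics for the trimmed analysis
#'
#' Histograms of the score distributions per exposure group on a common
#' grid, the trim bounds, and the share of each group lacking counterparts
#' (below the lower bound for the unexposed side of the exposed group and
#' vice versa) -- the quantities shown in a mirrored-histogram overlap plot.
#'
#' @param scores propensity scores.
#' @param exposed logical exposure indicator.
#' @param bounds `bounds` element from [trim_common_support()].
#' @param breaks number of histogram cells.
#' @return An `overlap_report` list.
#' @export
overlap_report <- function(scores, exposed, bounds, breaks = 30) {
  exposed <- as.logical(exposed)
  grid <- seq(min(scores), max(scores), length.out = breaks + 1)
  grid[1] <- grid[1] - 1e-12; grid[length(grid)] <- grid[length(grid)] + 1e-12
  h_exp <- hist(scores[exposed], breaks = grid, plot = FALSE)
  h_un <- hist(scores[!exposed], breaks = grid, plot = FALSE)
  structure(list(
    breaks = grid, counts_exposed = h_exp$counts,
    counts_unexposed = h_un$counts, bounds = bounds,
    share_no_counterpart_exposed = mean(scores[exposed] < bounds$lower |
                                          scores[exposed] > bounds$upper),
    share_no_counterpart_unexposed = mean(scores[!exposed] < bounds$lower |
                                            scores[!exposed] > bounds$upper)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> bounds [", sprintf("%.4f", x$bounds$lower), ", ",
      sprintf("%.4f", x$bounds$upper), "]\n", sep = "")
  cat(sprintf("  %.1f%% of exposed and %.1f%% of unexposed lack counterparts\n",
              100 * x$share_no_counterpart_exposed,
              100 * x$share_no_counterpart_unexposed))
  invisible(x)
}

#' Mirrored-histogram overlap plot
#'
#' Exposed counts above the axis, unexposed below, with the common-support
#' bounds marked; the regions outside the bounds are the subjects removed
#' by trimming.
#'
#' @param x an [overlap_report()].
#' @param ... ignored.
#' @export
plot.overlap_report <- function(x, ...) {
  mids <- (head(x$breaks, -1) + x$breaks[-1]) / 2
  ylim <- c(-max(x$counts_unexposed), max(x$counts_exposed))
  plot(mids, x$counts_exposed, type = "h", lwd = 4, col = "darkgreen",
       ylim = ylim, xlab = "propensity score", ylab = "count",
       main = "propensity-score overlap")
  graphics::lines(mids, -x$counts_unexposed, type = "h", lwd = 4,
                  col = "palegreen3")
  graphics::abline(v = c(x$bounds$lower, x$bounds$upper), lty = 2, col = "grey30")
  graphics::abline(h = 0)
  invisible(x)
}
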