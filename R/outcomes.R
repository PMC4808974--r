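#' Apply the exclusion cascade
#'
#' Removes records failing any criterion and tallies one reason per record
#' in priority order: linkage/geography first, then non-singleton birth,
#' stillbirth, serious birth defect, birth weight < 500 g, and gestational
#' age < 22 weeks.
#'
#' @param cohort raw cohort data.frame carrying `linked`, `plurality`,
#'   `stillbirth`, `birth_defect`, `birth_weight_g`, `gestational_age`.
#' @return List with `included` (the analysis cohort) and `ledger` (named
#'   counts per reason plus `raw`/`included` totals).
#' @export
apply_exclusions <- function(cohort) {
  reasons <- c("could not be linked or geocoded",
               "non-singleton births",
               "stillbirths",
               "neonates with serious birth defects",
               "birth weights <500 g",
               "gestational ages <22 weeks")
  fail <- cbind(
    !cohort$linked,
    cohort$plurality > 1L,
    cohort$stillbirth,
    cohort$birth_defect,
    cohort$birth_weight_g < 500,
    cohort$gestational_age < 22)
  first <- apply(fail, 1, function(f) if (any(f)) which(f)[1] else NA_integer_)
  counts <- vapply(seq_along(reasons), function(k) sum(first == k, na.rm = TRUE),
                   integer(1))
  names(counts) <- reasons
  included <- cohort[is.na(first), , drop = FALSE]
  list(included = included,
       ledger = list(raw = nrow(cohort), included = nrow(included),
                     excluded = counts))
}

#' Internal sex-by-gestational-week growth reference
#'
#' Computes the 10th-percentile birth weight per (sex, completed week) cell
#' with linear-interpolation quantiles on the included births.  Cells with
#' fewer than `min_cell` births are pooled with data from progressively
#' nearer weeks until the minimum is met (pooling is logged), and the
#' percentile curve is then repaired to be nondecreasing in gestational week
#' within sex (isotonic regression; repairs are logged).
#'
#' @param included analysis cohort with `sex`, `gestational_age`,
#'   `birth_weight_g`.
#' @param min_cell minimum cell size before pooling.
#' @return A `growth_reference`: data.frame with `sex`, `week`, `p10`,
#'   `n_cell`, `pooled`, `repaired`.
#' @export
build_growth_reference <- function(included, min_cell = 20) {
  if (nrow(included) == 0) stop("no data to build a growth reference")
  wk <- floor(included$gestational_age)
  ref <- list()
  for (sx in sort(unique(as.character(included$sex)))) {
    si <- included$sex == sx
    weeks <- sort(unique(wk[si]))
    p10 <- numeric(length(weeks)); ncell <- integer(length(weeks))
    pooled <- logical(length(weeks))
    for (k in seq_along(weeks)) {
      use <- si & wk == weeks[k]
      ncell[k] <- sum(use)
      width <- 0
      while (sum(use) < min_cell && width < 25) {
        width <- width + 1
        use <- si & abs(wk - weeks[k]) <= width
        pooled[k] <- TRUE
      }
      p10[k] <- unname(quantile(included$birth_weight_g[use], 0.1, type = 7))
    }
    iso <- cummax(isoreg(weeks, p10)$yf)
    ref[[sx]] <- data.frame(sex = sx, week = weeks, p10 = iso,
                            n_cell = ncell, pooled = pooled,
                            repaired = abs(iso - p10) > 1e-9,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ref)
  rownames(out) <- NULL
  class(out) <- c("growth_reference", "data.frame")
  out
}

#' Classify the four birth outcomes
#'
#' SGA is birth weight strictly below the sex-specific 10th percentile for
#' completed gestational week; preterm is gestational age < 37.0 weeks
#' (continuous); low Apgar is a 5-minute score < 7; term birth weight is
#' recorded only for births at >= 37 weeks.  Missing outcome fields yield
#' missing flags -- records are not excluded here.
#'
#' @param included analysis cohort.
#' @param reference a [build_growth_reference()] result covering every
#'   (sex, week) present.
#' @return Data.frame keyed by `birth_id` with `sga`, `preterm`,
#'   `low_apgar`, `term_weight_g`.
#' @export
classify_outcomes <- function(included, reference) {
  wk <- floor(included$gestational_age)
  key <- paste(included$sex, wk)
  rkey <- paste(reference$sex, reference$week)
  idx <- match(key, rkey)
  if (anyNA(idx[!is.na(included$gestational_age)]))
    stop("growth reference does not cover all sex-by-week cells present")
  p10 <- reference$p10[idx]
  data.frame(
    birth_id = included$birth_id,
    sga = ifelse(is.na(included$birth_weight_g), NA,
                 included$birth_weight_g < p10),
    preterm = ifelse(is.na(included$gestational_age), NA,
                     included$gestational_age < 37),
    low_apgar = ifelse(is.na(included$apgar5), NA, included$apgar5 < 7),
    term_weight_g = ifelse(!is.na(included$gestational_age) &
                             included$gestational_age >= 37,
                           included$birth_weight_g, NA_real_),
    stringsAsFactors = FALSE)
}
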