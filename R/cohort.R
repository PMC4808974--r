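# per-completed-week mean birth weight (g); step function so that the
# sex-by-week 10th percentile of the generating distribution is exact
week_weight_mean <- function(week) {
  knots <- c(20, 24, 28, 32, 34, 36, 37, 38, 39, 40, 41, 42)
  means <- c(400, 700, 1150, 1900, 2350, 2800, 3000, 3200, 3350, 3480, 3580, 3620)
  stats::approx(knots, means, xout = pmin(pmax(week, 20), 42))$y
}

# true covariate coefficients on the outcome log-odds scale (ground truth)
outcome_gammas <- function() {
  list(
    preterm = c(black = 0.25, hispanic = 0.10, smoking = 0.35,
                medical_assistance = 0.20, under = 0.35, obese = 0.15,
                nulliparous = 0.10, age2 = 0.0015),
    sga = c(black = 0.30, hispanic = 0.10, smoking = 0.50,
            medical_assistance = 0.20, under = 0.40, obese = -0.05,
            nulliparous = 0.15, age2 = 0.0010))
}

draw_categorical <- function(base, tilt = NULL) {
  # base: n x k matrix of baseline proportions (rows sum to 1);
  # tilt: n x k additive log tilts
  lp <- log(base)
  if (!is.null(tilt)) lp <- lp + tilt
  p <- exp(lp); p <- p / rowSums(p)
  cs <- p
  for (k in seq_len(ncol(p))[-1]) cs[, k] <- cs[, k - 1] + p[, k]
  u <- runif(nrow(p))
  colnames(base)[1L + rowSums(u > cs + 1e-12)]
}

#' Simulate a birth cohort with known ground truth
#'
#' Places mothers inside community zones, assigns birth dates, computes each
#' birth's three-season window NDVI from the raster (250 m buffer mean, the
#' same computation the exposure module performs), and then draws covariates
#' whose distributions tilt with the within-community-type greenness rank
#' (structural confounding), gestational age, birth weight, and outcomes
#' from logistic models with the configured true effects.
#'
#' The latent small-for-gestational-age channel works through birth weight:
#' a latent SGA indicator is drawn from its logistic model and the birth
#' weight is then sampled from the lower 10% (latent SGA) or upper 90%
#' (otherwise) of the sex-by-completed-week Gaussian, so that downstream
#' classification against an internal 10th-percentile reference recovers the
#' configured SGA odds ratio.
#'
#' When `structural_overlap_violation` is on, a `public_housing` stratum is
#' planted only among city mothers in the lower greenness tail none of whose
#' births are exposed, so the stratum's exposure probability is exactly
#' zero; stratum membership additionally raises preterm/SGA risk by
#' `stratum$outcome_shift`, which is *not* part of the outcome-model
#' adjustment set.
#'
#' @param config a [sim_config()].
#' @param raster an [ndvi_stack()] covering all community zones, e.g. from
#'   [simulate_raster()].
#' @return A list with `cohort` (one row per birth), `communities`
#'   (community table with walkability and deprivation components), and
#'   `truth` (a `ground_truth` object: configured effects, covariate
#'   coefficients, per-birth true exposure, greenness rank, latent SGA and
#'   overlap flags).
#' @export
simulate_cohort <- function(config, raster) {
  validate_sim_config(config)
  zones <- community_zones(config)
  ext <- config$grid_dim * config$res_m
  if (any(zones$xmax > ext[1]) || any(zones$ymax > ext[2]))
    stop("raster does not cover all community zones")
  types <- c("city", "borough", "township")
  gam <- outcome_gammas()

  with_seed(derive_seed(config$seed, "cohort"), {
    ## ---- mothers, addresses, births -------------------------------------
    rows <- list()
    d0 <- config$birth_window[1]
    span <- as.numeric(config$birth_window[2] - d0)
    for (tp in types) {
      n_t <- config$n_births[[tp]]
      if (n_t == 0) next
      zt <- zones[zones$community_type == tp, ]
      alloc <- as.vector(stats::rmultinom(1, n_t, rep(1, nrow(zt))))
      for (z in seq_len(nrow(zt))) {
        n_c <- alloc[z]
        if (n_c == 0) next
        sizes <- 1L + rbinom(n_c, 1L, config$multiple_birth_rate)
        keep <- which(cumsum(sizes) - sizes < n_c)
        sizes <- sizes[keep]
        sizes[length(sizes)] <- n_c - sum(sizes[-length(sizes)])
        if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
        nm <- length(sizes)
        mx <- runif(nm, zt$xmin[z], zt$xmax[z])
        my <- runif(nm, zt$ymin[z], zt$ymax[z])
        first <- d0 + round(runif(nm, 0, span))
        midx0 <- rep(seq_len(nm), sizes)
        border <- sequence(sizes)
        bd <- first[midx0]
        sec <- border == 2L
        if (any(sec))
          bd[sec] <- pmin(bd[sec] + round(runif(sum(sec), 330, 560)),
                          config$birth_window[2])
        rows[[length(rows) + 1L]] <- data.frame(
          mother_key = paste0(zt$community_id[z], "_", midx0),
          community_id = zt$community_id[z], community_type = tp,
          x = mx[midx0], y = my[midx0], birth_date = bd, birth_order = border,
          stringsAsFactors = FALSE)
      }
    }
    co <- do.call(rbind, rows)
    co$mother_id <- sprintf("m%05d", match(co$mother_key, unique(co$mother_key)))
    co$mother_key <- NULL
    co$birth_id <- sprintf("b%05d", seq_len(nrow(co)))
    n <- nrow(co)

    ## ---- true exposure from the raster ----------------------------------
    w <- window_ndvi_vec(raster, co$x, co$y, co$birth_date, 250, "mean")
    co$true_window_ndvi <- w
    exposed <- logical(n); u <- numeric(n)
    for (tp in types) {
      idx <- which(co$community_type == tp)
      if (length(idx) == 0) next
      q1 <- unname(quantile(w[idx], 1 / 3, type = 7))
      exposed[idx] <- w[idx] > q1
      u[idx] <- (rank(w[idx], ties.method = "first") - 0.5) / length(idx)
    }

    ## ---- mother-level covariates with confounding tilt ------------------
    mothers <- co[co$birth_order == 1L,
                  c("mother_id", "community_type", "birth_id")]
    mu <- u[match(mothers$birth_id, co$birth_id)]   # rank of first birth
    tilt <- config$confounding_strength * (0.5 - mu)
    cw <- config$confound_weights
    nm <- nrow(mothers)
    mlist <- config$covariate_mixtures[mothers$community_type]
    getp <- function(field) vapply(mlist, function(m) m[[field]][[1]], numeric(1))
    race_tilt <- cbind(white = 0, black = cw[["black"]] * tilt,
                       hispanic = cw[["hispanic"]] * tilt, other = 0)
    race_base <- t(vapply(mlist, function(m) m$race, numeric(4)))
    colnames(race_base) <- c("white", "black", "hispanic", "other")
    race <- draw_categorical(race_base, race_tilt)
    ma <- rbinom(nm, 1, plogis(qlogis(getp("medical_assistance")) +
                                 cw[["medical_assistance"]] * tilt))
    smoking <- rbinom(nm, 1, plogis(qlogis(getp("smoking")) +
                                      cw[["smoking"]] * tilt))
    bmi_base <- t(vapply(mlist, function(m) m$bmi_class, numeric(4)))
    colnames(bmi_base) <- c("under", "normal", "over", "obese")
    bmi_tilt <- cbind(under = 0, normal = 0, over = cw[["overweight"]] * tilt,
                      obese = 0)
    bmi_class <- draw_categorical(bmi_base, bmi_tilt)
    bmi_val <- c(under = 17.4, normal = 21.8, over = 27.3, obese = 34.5)[bmi_class] +
      rnorm(nm, 0, 0.6)
    age <- rnorm(nm, getp("age_mean") - 1.0 * tilt, getp("age_sd"))
    age <- pmin(pmax(age, 16), 45)
    pcare <- rbinom(nm, 1, plogis(qlogis(getp("primary_care")) +
                                    cw[["primary_care"]] * tilt))
    hosp <- sample(c("GMC", "GWV"), nm, replace = TRUE)
    midx <- match(co$mother_id, mothers$mother_id)
    co$race <- race[midx]
    co$maternal_age <- round(age[midx] + (co$birth_order - 1L) * 1.3, 1)
    co$bmi <- round(bmi_val[midx], 1)
    co$primary_care <- pcare[midx] == 1L
    co$hospital <- hosp[midx]
    mtilt <- tilt[midx]

    ## ---- birth-level covariates -----------------------------------------
    lam <- vapply(config$covariate_mixtures[co$community_type],
                  function(m) m$antibiotics_lambda, numeric(1))
    co$antibiotic_orders <- rpois(n, lam * exp(cw[["antibiotics"]] * mtilt))
    p_nul <- vapply(config$covariate_mixtures[co$community_type],
                    function(m) m$nulliparous, numeric(1))
    nul <- rbinom(n, 1, plogis(qlogis(p_nul) + cw[["nulliparous"]] * mtilt)) == 1L
    co$nulliparous <- ifelse(co$birth_order > 1L, FALSE, nul)
    co$sex <- ifelse(runif(n) < 0.515, "male", "female")
    smoke_this <- rbinom(n, 1, ifelse(smoking[midx] == 1L, 0.85, 0.03)) == 1L
    co$ma_qualifying_encounters <- ifelse(ma[midx] == 1L, 3L + rpois(n, 2),
                                          pmin(rpois(n, 0.6), 2L))

    ## ---- structural-overlap stratum -------------------------------------
    co$public_housing <- FALSE
    if (config$structural_overlap_violation) {
      agg_ok <- tapply(!exposed & u <= config$stratum$max_rank &
                         co$community_type == "city", co$mother_id, all)
      elig <- agg_ok[co$mother_id]
      memb <- rbinom(nm, 1, config$stratum$rate) == 1L
      co$public_housing <- as.vector(elig) & memb[midx]
    }

    ## ---- outcomes --------------------------------------------------------
    mix <- config$covariate_mixtures
    exp_x <- function(tp, g) {  # E[gamma %*% X | community type]
      m <- mix[[tp]]
      g["black"] * m$race[["black"]] + g["hispanic"] * m$race[["hispanic"]] +
        g["smoking"] * m$smoking + g["medical_assistance"] * m$medical_assistance +
        g["under"] * m$bmi_class[["under"]] + g["obese"] * m$bmi_class[["obese"]] +
        g["nulliparous"] * m$nulliparous +
        g["age2"] * ((m$age_mean - 27)^2 + m$age_sd^2)
    }
    lp_cov <- function(g) {
      g["black"] * (co$race == "black") + g["hispanic"] * (co$race == "hispanic") +
        g["smoking"] * smoke_this + g["medical_assistance"] * (co$ma_qualifying_encounters > 2) +
        g["under"] * (co$bmi < 18.5) + g["obese"] * (co$bmi >= 30) +
        g["nulliparous"] * co$nulliparous + g["age2"] * (co$maternal_age - 27)^2
    }
    lp_outcome <- function(which) {
      g <- gam[[which]]
      base <- config$outcome_base[[which]][co$community_type]
      centre <- vapply(co$community_type, exp_x, numeric(1), g = g)
      lp <- qlogis(base) + lp_cov(g) - centre +
        config$true_effects[[which]][co$community_type] * exposed
      if (config$structural_overlap_violation)
        lp <- lp + config$stratum$outcome_shift[[which]] * co$public_housing
      lp
    }
    preterm <- rbinom(n, 1, plogis(lp_outcome("preterm"))) == 1L
    ga <- numeric(n)
    ga[preterm] <- pmax(37 - rgamma(sum(preterm), shape = 1.6, scale = 1.8), 20.2)
    ga[preterm] <- pmin(ga[preterm], 36.99)
    ga[!preterm] <- 37 + 5.2 * rbeta(sum(!preterm), 2.2, 2.6)
    co$gestational_age <- round(ga, 2)
    sga_latent <- rbinom(n, 1, plogis(lp_outcome("sga"))) == 1L
    v <- ifelse(sga_latent, runif(n, 0, 0.1), runif(n, 0.1, 1))
    mu_w <- week_weight_mean(floor(co$gestational_age)) + 60 * (co$sex == "male")
    shift <- config$true_effects$weight_g_per_ndvi[co$community_type] *
      (w - stats::ave(w, co$community_type))
    co$birth_weight_g <- pmax(round(qnorm(v, mu_w + shift,
                                          pmax(0.11 * mu_w, 70))), 150)
    # no covariate or preterm dependence: the default is an exact null
    low_ap <- rbinom(n, 1, plogis(qlogis(config$outcome_base$low_apgar) +
      config$true_effects$low_apgar[co$community_type] * exposed)) == 1L
    co$apgar5 <- ifelse(low_ap, sample(0:6, n, replace = TRUE),
                        sample(7:10, n, replace = TRUE, prob = c(0.05, 0.15, 0.55, 0.25)))
    # smoking record date (day offset within gestation) for the covariate op
    conception <- co$birth_date - round(co$gestational_age * 7)
    co$smoking_record_date <- as.Date(ifelse(
      smoke_this,
      conception + round(runif(n, 5, pmax(co$gestational_age * 7 - 5, 6))),
      ifelse(runif(n) < 0.15, conception - round(runif(n, 10, 200)), NA)),
      origin = "1970-01-01")
    co$conception_date <- conception

    ## ---- planted exclusions ---------------------------------------------
    er <- config$exclusion_rates
    co$linked <- runif(n) >= er[["unlinked"]]
    co$plurality <- ifelse(runif(n) < er[["non_singleton"]], 2L, 1L)
    co$stillbirth <- runif(n) < er[["stillbirth"]]
    co$birth_defect <- runif(n) < er[["birth_defect"]]

    ## ---- community table -------------------------------------------------
    comm <- zones
    ct <- config$covariate_mixtures
    wk_mean <- vapply(ct[comm$community_type], function(m) m$walkability[["mean"]], numeric(1))
    wk_sd <- vapply(ct[comm$community_type], function(m) m$walkability[["sd"]], numeric(1))
    cs_mean <- vapply(ct[comm$community_type], function(m) m$csd[["mean"]], numeric(1))
    cs_sd <- vapply(ct[comm$community_type], function(m) m$csd[["sd"]], numeric(1))
    for (v3 in c("pop_density", "landuse_mix", "connectivity"))
      comm[[v3]] <- rnorm(nrow(comm), wk_mean / 3, wk_sd / sqrt(3) + 0.2)
    for (v6 in c("low_education", "unemployed", "not_in_labor_force",
                 "poverty", "public_assistance", "no_car"))
      comm[[v6]] <- rnorm(nrow(comm), cs_mean / 6, cs_sd / sqrt(6) + 0.1)
    comm$municipal_water <- comm$community_type != "township" | runif(nrow(comm)) < 0.3

    truth <- structure(list(
      effects = config$true_effects,
      covariate_coefficients = gam,
      outcome_base = config$outcome_base,
      exposed = exposed, greenness_rank = u,
      sga_latent = sga_latent, preterm_true = preterm,
      overlap = !co$public_housing,
      stratum = co$public_housing,
      structural_overlap_violation = config$structural_overlap_violation),
      class = "ground_truth")

    cols <- c("birth_id", "mother_id", "community_id", "community_type",
              "x", "y", "birth_date", "birth_order", "sex", "maternal_age",
              "race", "bmi", "nulliparous", "primary_care", "hospital",
              "antibiotic_orders", "ma_qualifying_encounters",
              "smoking_record_date", "conception_date", "gestational_age",
              "birth_weight_g", "apgar5", "public_housing", "linked",
              "plurality", "stillbirth", "birth_defect", "true_window_ndvi")
    list(cohort = co[, cols], communities = comm, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> n =", length(x$exposed), "births;",
      "structural violation:", x$structural_overlap_violation, "\n")
  cat("  true preterm OR:",
      paste(names(x$effects$preterm),
            sprintf("%.2f", exp(x$effects$preterm)), collapse = ", "), "\n")
  invisible(x)
}
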