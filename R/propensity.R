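#' Binomial negative log-likelihood risk
#'
#' Mean negative Bernoulli log-likelihood of predicted probabilities,
#' clipped away from 0/1; the cross-validated loss the ensemble weights
#' minimize.
#'
#' @param p predicted probabilities.
#' @param y 0/1 outcomes.
#' @param eps clipping constant.
#' @return Scalar risk.
#' @export
binomial_risk <- function(p, y, eps = 1e-4) {
  p <- .clip(p, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Stratified cross-validation folds
#'
#' Folds are stratified by the exposure label so every fold sees both
#' exposure levels; within each stratum fold sizes differ by at most one.
#'
#' @param n number of subjects.
#' @param v number of folds (>= 2, with `n >= 2 v`).
#' @param strata exposure labels (or any stratification factor) of length
#'   `n`; every stratum must have at least `v` members.
#' @param seed integer seed.
#' @return Integer fold assignment in `1..v`.
#' @export
make_folds <- function(n, v, strata, seed) {
  stopifnot(v >= 2, n >= 2 * v, length(strata) == n)
  folds <- integer(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < v)
        stop("stratum '", s, "' has fewer members (", length(idx),
             ") than folds (", v, ")")
      folds[idx] <- sample(rep_len(seq_len(v), length(idx)))
    }
  })
  folds
}

# ---- base learner registry -------------------------------------------------

spline_design <- function(X, bases = NULL) {
  cols <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (is.null(bases)) {
      if (length(unique(x)) > 8) splines::ns(x, df = 3) else cbind(x)
    } else {
      b <- bases[[j]]
      if (inherits(b, "ns")) predict(b, x) else cbind(x)
    }
  })
  list(mat = do.call(cbind, cols), bases = if (is.null(bases)) {
    lapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      if (length(unique(x)) > 8) splines::ns(x, df = 3) else NULL
    })
  } else bases)
}

#' Base learner library for propensity estimation
#'
#' Each learner is a `fit(X, y)` / `predict(fit, X)` pair mapping a numeric
#' design matrix to exposure probabilities:
#' \describe{
#'   \item{mean}{intercept-only (marginal prevalence).}
#'   \item{logistic}{plain maximum-likelihood logistic regression.}
#'   \item{ridge}{L2-penalized logistic regression (glmnet, alpha = 0).}
#'   \item{spline}{logistic regression with natural cubic spline expansion
#'     (df = 3) of continuous columns -- a generalized-additive surrogate.}
#'   \item{xgb}{shallow gradient-boosted trees (depth 2, 60 rounds).}
#' }
#'
#' @param names which learners to include.
#' @return Named list of learner definitions.
#' @export
sl_library <- function(names = c("mean", "ridge", "spline", "xgb")) {
  all <- list(
    mean = list(
      fit = function(X, y) mean(y),
      predict = function(fit, X) rep(fit, nrow(X))),
    logistic = list(
      fit = function(X, y)
        suppressWarnings(glm.fit(cbind(1, X), y, family = binomial())),
      predict = function(fit, X) {
        co <- fit$coefficients; co[is.na(co)] <- 0
        as.vector(plogis(cbind(1, X) %*% co))
      }),
    ridge = list(
      # glmnet needs >= 2 columns; pad single-covariate designs with a zero
      fit = function(X, y) {
        if (ncol(X) < 2) X <- cbind(X, `..pad` = 0)
        suppressWarnings(glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                        lambda = c(0.3, 0.1, 0.03, 0.01)))
      },
      predict = function(fit, X) {
        if (ncol(X) < 2) X <- cbind(X, `..pad` = 0)
        as.vector(predict(fit, X, s = 0.01, type = "response"))
      }),
    spline = list(
      fit = function(X, y) {
        sd <- spline_design(X)
        f <- suppressWarnings(glm.fit(cbind(1, sd$mat), y, family = binomial()))
        list(coef = f$coefficients, bases = sd$bases)
      },
      predict = function(fit, X) {
        m <- spline_design(X, fit$bases)$mat
        co <- fit$coef; co[is.na(co)] <- 0
        as.vector(plogis(cbind(1, m) %*% co))
      }),
    xgb = list(
      fit = function(X, y)
        xgboost::xgb.train(
          params = list(max_depth = 2, eta = 0.3,
                        objective = "binary:logistic", nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = y), nrounds = 60,
          verbose = 0),
      predict = function(fit, X) predict(fit, xgboost::xgb.DMatrix(X))))
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown learner(s): ", paste(missing, collapse = ", "))
  all[names]
}

#' Cross-validated base-learner predictions
#'
#' Entry (i, l) is learner l's predicted exposure probability for subject i
#' from a model trained on all folds except subject i's.  A learner that
#' fails on any fold is dropped with a warning and recorded.
#'
#' @param X numeric design matrix.
#' @param y 0/1 exposure.
#' @param folds fold assignment from [make_folds()].
#' @param library learner list from [sl_library()] (>= 2 learners).
#' @return Matrix (n x learners) with attribute `"dropped"`.
#' @export
cv_predictions <- function(X, y, folds, library) {
  stopifnot(length(library) >= 1)
  n <- length(y)
  Z <- matrix(NA_real_, n, length(library),
              dimnames = list(NULL, names(library)))
  dropped <- character(0)
  for (l in seq_along(library)) {
    ok <- TRUE
    for (v in sort(unique(folds))) {
      tr <- folds != v
      pred <- tryCatch({
        fit <- library[[l]]$fit(X[tr, , drop = FALSE], y[tr])
        library[[l]]$predict(fit, X[!tr, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(pred, "error") || anyNA(pred)) { ok <- FALSE; break }
      Z[!tr, l] <- pred
    }
    if (!ok) {
      dropped <- c(dropped, names(library)[l])
      Z[, l] <- NA_real_
    }
  }
  if (length(dropped)) {
    warning("dropped failing learner(s): ", paste(dropped, collapse = ", "))
    Z <- Z[, setdiff(colnames(Z), dropped), drop = FALSE]
  }
  attr(Z, "dropped") <- dropped
  Z
}

#' Convex ensemble weights minimizing cross-validated binomial risk
#'
#' Minimizes the mean binomial negative log-likelihood of the convex
#' combination of cross-validated learner predictions over the probability
#' simplex, by exponentiated-gradient descent with a monotone line search.
#' Iteration stops when the Frank-Wolfe optimality gap falls below `tol`,
#' which certifies that the ensemble risk is within `tol` of every vertex
#' (in particular of the best single learner).  With identical learners the
#' symmetric updates leave the uniform initial weights untouched (tie rule).
#'
#' @param Z cross-validated prediction matrix (n x learners), finite.
#' @param y 0/1 exposure.
#' @param tol optimality-gap tolerance.
#' @param max_iter iteration cap; exceeding it with a gap above 1e-6 is a
#'   convergence error.
#' @param eps probability clipping constant.
#' @return Weight vector on the simplex (named as the learners).
#' @export
solve_weights <- function(Z, y, tol = 1e-8, max_iter = 50000, eps = 1e-4) {
  Z <- as.matrix(Z)
  if (anyNA(Z) || any(!is.finite(Z))) stop("prediction matrix must be finite")
  L <- ncol(Z)
  if (L == 1L) return(setNames(1, colnames(Z)))
  Zc <- .clip(Z, eps)
  risk <- function(w) binomial_risk(as.vector(Zc %*% w), y, eps)
  grad <- function(w) {
    p <- .clip(as.vector(Zc %*% w), eps)
    as.vector(crossprod(Zc, (1 - y) / (1 - p) - y / p)) / length(y)
  }
  w <- rep(1 / L, L)
  r <- risk(w)
  eta <- 0.5 / max(abs(grad(w)), 1e-12)
  gap <- Inf
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    gap <- sum(w * g) - min(g)
    if (gap < tol) break
    accepted <- FALSE
    for (bt in 1:40) {
      wn <- w * exp(-eta * (g - mean(g)))
      wn <- wn / sum(wn)
      rn <- risk(wn)
      if (rn <= r + 1e-15) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break   # cannot improve: at numerical optimum
    w <- wn; r <- rn; eta <- eta * 1.2
  }
  if (gap >= 1e-6) {
    # stalled short of certification: fall back to the best vertex unless
    # the current point already matches it
    corner <- apply(Zc, 2, binomial_risk, y = y, eps = eps)
    if (min(corner) < r - 1e-9) {
      best <- which(corner <= min(corner) + 1e-12)
      w <- rep(0, L); w[best] <- 1 / length(best)
    } else if (gap > 1e-4) {
      stop("weight optimization did not converge (gap = ",
           format(gap), " after ", max_iter, " iterations)")
    }
  }
  setNames(w, colnames(Z))
}

#' Fit super-learner propensity scores
#'
#' Estimates each subject's probability of high greenness exposure
#' (community tertile 2-3 vs 1) from baseline covariates with a stacking
#' ensemble: V-fold cross-validated base-learner predictions, convex weights
#' minimizing the cross-validated binomial risk, and final scores from the
#' weighted base learners refit on the full sample.  Run separately within
#' each community type.
#'
#' @param covariates data.frame of baseline covariates (factors allowed).
#' @param exposure logical or 0/1 exposure vector.
#' @param v number of cross-validation folds.
#' @param library learner names for [sl_library()].
#' @param seed integer seed for fold assignment.
#' @param eps score clipping constant.
#' @return A `propensity_fit`: folds, cross-validated prediction matrix,
#'   weights, per-learner and ensemble CV risks, and final scores in
#'   `[eps, 1 - eps]`.
#' @export
fit_propensity <- function(covariates, exposure, v = 10,
                           library = c("mean", "ridge", "spline", "xgb"),
                           seed = 1, eps = 1e-4) {
  y <- as.integer(exposure)
  stopifnot(all(y %in% 0:1))
  X <- model.matrix(~ . - 1, data = covariates)
  keep <- apply(X, 2, var) > 0
  X <- X[, keep, drop = FALSE]
  lib <- sl_library(library)
  folds <- make_folds(length(y), v, y, seed)
  Z <- cv_predictions(X, y, folds, lib)
  lib <- lib[colnames(Z)]
  w <- solve_weights(Z, y, eps = eps)
  risks <- apply(.clip(Z, eps), 2, binomial_risk, y = y, eps = eps)
  ens_risk <- binomial_risk(as.vector(.clip(Z, eps) %*% w), y, eps)
  full <- lapply(lib, function(ln) ln$fit(X, y))
  preds <- vapply(seq_along(lib), function(l)
    .clip(lib[[l]]$predict(full[[l]], X), eps), numeric(length(y)))
  scores <- .clip(as.vector(preds %*% w), eps)
  structure(list(folds = folds, cv_predictions = Z, weights = w,
                 learner_risks = risks, ensemble_risk = ens_risk,
                 scores = scores, library = names(lib), v = v, seed = seed,
                 eps = eps, dropped = attr(Z, "dropped")),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> n =", length(x$scores), ", V =", x$v, "\n")
  cat("  weights:", paste(names(x$weights), sprintf("%.3f", x$weights),
                          sep = "=", collapse = ", "), "\n")
  cat("  CV risk: ensemble", sprintf("%.5f", x$ensemble_risk),
      "| best learner", sprintf("%.5f", min(x$learner_risks)), "\n")
  invisible(x)
}
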