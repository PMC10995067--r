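#' @name metafit
#' @title Fitted meta-analysis / meta-regression objects
#' @description All pooling routines return a `metafit` object: a list with
#'   the model kind (`"fixed"`, `"random"`, `"metareg"`, `"gls"`), the
#'   polynomial `degree` and `centre` (years), named `coef`, `se`,
#'   `ci_low` / `ci_high` (95%), the between-study variance `tau2`
#'   (residual \eqn{\tau^2} when moderators are present), Cochran's `Q`
#'   with `df` and the derived `I2` percentage, the number of studies `k`,
#'   the GLS coefficient covariance `vcov`, and the span of study mean
#'   ages used for extrapolation flagging.
NULL

new_metafit <- function(model, coef, vcov, tau2, Q, df, k, degree, centre,
                        age_span, knapp_hartung = FALSE, crit = NULL) {
  se <- sqrt(diag(as.matrix(vcov)))
  if (is.null(crit)) crit <- stats::qnorm(0.975)
  I2 <- if (df >= 1 && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(model = model,
                 degree = degree, centre = centre,
                 coef = coef, se = se,
                 ci_low = coef - crit * se, ci_high = coef + crit * se,
                 tau2 = tau2, Q = Q, df = df, I2 = I2, k = k,
                 vcov = as.matrix(vcov), age_span = age_span,
                 knapp_hartung = knapp_hartung, crit = crit),
            class = "metafit")
}

#' @export
print.metafit <- function(x, ...) {
  kind <- switch(x$model,
                 fixed = "Fixed-effect meta-analysis",
                 random = "Random-effects meta-analysis (REML)",
                 metareg = sprintf("Random-effects meta-regression (degree %d, centre %g)",
                                   x$degree, x$centre),
                 gls = sprintf("GLS meta-regression with overlap-adjusted weights (degree %d, centre %g)",
                               x$degree, x$centre))
  cat(kind, sprintf("on k = %d studies\n\n", x$k))
  tab <- data.frame(estimate = x$coef, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 6))
  cat(sprintf("\ntau2 = %.6g   Q = %.4g (df = %d)   I2 = %.2f%%\n",
              x$tau2, x$Q, x$df, x$I2))
  invisible(x)
}

age_span_of <- function(summaries) {
  ma <- summaries$mean_age
  if (is.null(ma) || !any(is.finite(ma))) return(c(NA_real_, NA_real_))
  range(ma, na.rm = TRUE)
}

check_summaries <- function(summaries, k_min = 2L, need_age = FALSE) {
  need <- c("beta1", "se")
  if (need_age) need <- c(need, "mean_age", "sd_age")
  if (!all(need %in% names(summaries))) {
    stop_agemeta(paste0("summaries need columns: ", paste(need, collapse = ", ")),
                 "config")
  }
  if (any(!is.finite(summaries$beta1)) || any(summaries$se <= 0)) {
    stop_agemeta("effects must be finite and standard errors positive", "config")
  }
  if (nrow(summaries) < k_min) {
    stop_agemeta(sprintf("at least %d studies are required", k_min),
                 subclass = "insufficient_studies")
  }
  invisible(summaries)
}

coef_names <- c("beta_snp", "beta_snp_age", "beta_snp_age2", "beta_snp_age3")

#' Moderator rows from reported age moments
#'
#' Builds the study-level moderator values for a polynomial age
#' meta-regression from the study mean and SD of age alone, centred at
#' `centre` years: \eqn{m_1 = \bar a - c}, \eqn{m_2 = SD^2 + (\bar a - c)^2}
#' (the mean of squared centred age, via the variance identity), and, for
#' cubic models, \eqn{m_3 = (\bar a - c)^3 + 3 (\bar a - c) SD^2} — the mean
#' cubed centred age under the assumption of zero within-study age skewness
#' (exact for uniform and any symmetric age distribution).  A user-supplied
#' `mean_age3` (the raw mean of age cubed) overrides that assumption.
#'
#' @param mean_age,sd_age study mean and SD of age (years), vectorised.
#' @param centre centring age `c` in years.
#' @param degree polynomial degree 0--3.
#' @param mean_age3 optional raw third moments `mean(age^3)` per study.
#' @return A `length(mean_age) x (degree + 1)` moderator matrix with
#'   columns `intercept`, `m1`, `m2`, `m3` as applicable.
#' @export
derive_age_moments <- function(mean_age, sd_age, centre = 0, degree = 1,
                               mean_age3 = NULL) {
  if (degree < 0 || degree > 3) {
    stop_agemeta("only polynomial degrees 0 to 3 are supported",
                 subclass = "unsupported_degree")
  }
  if (any(sd_age < 0)) stop_agemeta("sd_age must be non-negative", "config")
  k <- length(mean_age)
  d <- mean_age - centre
  X <- matrix(1, k, 1, dimnames = list(NULL, "intercept"))
  if (degree >= 1) X <- cbind(X, m1 = d)
  if (degree >= 2) X <- cbind(X, m2 = sd_age^2 + d^2)
  if (degree >= 3) {
    m3 <- if (!is.null(mean_age3)) {
      # shift the raw third moment to the centre:
      # E[(a-c)^3] = E[a^3] - 3c E[a^2] + 3c^2 E[a] - c^3
      mean_age3 - 3 * centre * (sd_age^2 + mean_age^2) +
        3 * centre^2 * mean_age - centre^3
    } else {
      d^3 + 3 * d * sd_age^2
    }
    X <- cbind(X, m3 = m3)
  }
  X
}

# Restricted log-likelihood of y ~ N(X b, diag(v) + tau2 I), up to an
# additive constant.  Vectorised over tau2 for the intercept-only model so
# the brute-force grid oracle in the tests stays cheap.
reml_loglik <- function(tau2, y, v, X) {
  sapply(tau2, function(t2) {
    w <- 1 / (v + t2)
    if (any(!is.finite(w))) return(-Inf)
    Xs <- X * sqrt(w)
    sc <- sqrt(colSums(Xs^2))
    sc[sc == 0] <- 1
    Xs <- sweep(Xs, 2, sc, "/")
    A <- crossprod(Xs)
    b <- solve(A, crossprod(Xs, sqrt(w) * y)) / sc
    r <- y - X %*% b
    # log det(X'WX) = log det(A) + 2 sum(log sc); the scaling term is
    # tau2-free only when sc is, so keep it explicit
    -0.5 * (sum(log(v + t2)) +
              as.numeric(determinant(A, logarithm = TRUE)$modulus) +
              2 * sum(log(sc)) +
              sum(w * r^2))
  })
}


# Restricted score d ll / d tau2 = -0.5 (tr(P) - y' P P y) with
# P = W - W X (X' W X)^{-1} X' W, used to polish the REML maximiser.
reml_score <- function(t2, y, v, X) {
  w <- 1 / (v + t2)
  if (any(!is.finite(w))) return(NA_real_)
  Xw <- X * w
  A <- crossprod(Xw, X)
  b <- tryCatch(solve(A, crossprod(Xw, y)), error = function(e) NULL)
  if (is.null(b)) return(NA_real_)
  Py <- w * (y - drop(X %*% b))
  tr_term <- sum(diag(solve(A, crossprod(Xw))))
  -0.5 * (sum(w) - tr_term - sum(Py^2))
}

reml_score_polish <- function(t0, y, v, X, upper) {
  half <- max(t0 * 0.5, 1e-8)
  lo <- max(t0 - half, 0)
  hi <- min(t0 + half, upper)
  s_lo <- reml_score(lo, y, v, X)
  s_hi <- reml_score(hi, y, v, X)
  if (!is.finite(s_lo) || !is.finite(s_hi) || s_lo <= 0 || s_hi >= 0) {
    return(t0)
  }
  stats::uniroot(reml_score, c(lo, hi), y = y, v = v, X = X,
                 tol = 1e-12)$root
}

#' REML estimate of the between-study variance
#'
#' Maximises the restricted log-likelihood of
#' \eqn{y \sim N(X\beta, \mathrm{diag}(v) + \tau^2 I)} over
#' \eqn{\tau^2 \ge 0} by derivative-free bounded search (golden-section /
#' parabolic, tolerance `tol`), truncating a negative unconstrained optimum
#' at zero.  With an intercept-only `X` this is the usual random-effects
#' meta-analysis \eqn{\hat\tau^2}; with age-moment moderators it is the
#' residual heterogeneity \eqn{\hat\tau^2_{res}}.
#'
#' @param y effect estimates.
#' @param v their sampling variances (`se^2`).
#' @param X moderator matrix (default intercept-only).
#' @param tol convergence tolerance of the 1-D search.
#' @param upper upper search bound; defaults to
#'   `1e3 * max(v, var(y))`.
#' @return The estimate (scalar), with the achieved restricted
#'   log-likelihood in `attr(, "loglik")`.
#' @export
reml_tau2 <- function(y, v, X = matrix(1, length(y), 1), tol = 1e-8,
                      upper = NULL) {
  k <- length(y)
  X <- as.matrix(X)
  if (k <= ncol(X)) {
    stop_agemeta("REML needs more studies than coefficients",
                 subclass = "insufficient_studies")
  }
  if (is.null(upper)) upper <- 1e3 * max(v, stats::var(y))
  opt <- stats::optimize(reml_loglik, c(0, upper), maximum = TRUE, tol = tol,
                         y = y, v = v, X = X)
  ll0 <- suppressWarnings(reml_loglik(0, y, v, X))
  if (!is.finite(ll0)) ll0 <- -Inf
  if (ll0 >= opt$objective) {
    tau2 <- 0
    ll <- ll0
  } else {
    # polish with the analytic restricted score: optimize() localises the
    # maximiser only to ~sqrt(machine eps) from likelihood values alone
    tau2 <- reml_score_polish(opt$maximum, y, v, X, upper)
    ll <- reml_loglik(tau2, y, v, X)
    if (ll < opt$objective - 1e-8) {  # guard against a failed polish only
      tau2 <- opt$maximum
      ll <- opt$objective
    }
  }
  if (!is.finite(ll)) {
    stop_agemeta("REML optimisation did not converge to a finite restricted likelihood",
                 subclass = "nonconvergence")
  }
  structure(tau2, loglik = ll)
}

# Weighted (GLS) fit with diagonal weights 1/(v + tau2); returns coef and
# covariance (X' W X)^{-1}, plus the Knapp-Hartung variant on request.
wls_fit <- function(y, v, X, tau2, knapp_hartung = FALSE) {
  w <- 1 / (v + tau2)
  # column equilibration keeps raw cubic age moments (entries up to ~1e5)
  # numerically solvable to near machine precision
  Xs <- X * sqrt(w)
  sc <- sqrt(colSums(Xs^2))
  sc[sc == 0] <- 1
  Xs <- sweep(Xs, 2, sc, "/")
  A <- crossprod(Xs)
  vcov_s <- tryCatch(chol2inv(chol(A)), error = function(e) {
    stop_agemeta("moderator matrix is computationally singular",
                 subclass = "collinearity")
  })
  coef <- drop(vcov_s %*% crossprod(Xs, sqrt(w) * y)) / sc
  # one step of iterative refinement: the raw moments make the normal
  # equations moderately ill-conditioned even after equilibration
  resid <- y - drop(X %*% coef)
  coef <- coef + drop(vcov_s %*% crossprod(Xs, sqrt(w) * resid)) / sc
  vcov <- vcov_s / tcrossprod(sc)
  names(coef) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  crit <- stats::qnorm(0.975)
  if (knapp_hartung) {
    df <- length(y) - ncol(X)
    s2 <- sum(w * (y - X %*% coef)^2) / df
    vcov <- vcov * max(s2, 1)  # KH with truncation at 1, the usual variant
    crit <- stats::qt(0.975, df)
  }
  list(coef = coef, vcov = vcov, crit = crit)
}

# Cochran's (residual) Q with fixed-effect weights 1/v and the
# FE-weighted projection on X, plus df.
cochran_q <- function(y, v, X) {
  w <- 1 / v
  fit <- wls_fit(y, v, X, 0)
  r <- y - X %*% fit$coef
  list(Q = sum(w * r^2), df = length(y) - ncol(X))
}

#' Fixed-effect meta-analysis
#'
#' Inverse-variance pooling under a common true effect: weights
#' \eqn{w_j = 1/s_j^2}, pooled estimate \eqn{\sum w_j y_j / \sum w_j},
#' standard error \eqn{(\sum w_j)^{-1/2}}, 95% Wald CI.  With age-varying
#' effects the pooled value estimates the genetic effect at the
#' inverse-variance weighted mean age of the studies, not at any chosen
#' reference age.
#'
#' @param summaries study-summary data frame (columns `beta1`, `se`).
#' @return A [metafit] with `model = "fixed"` and `tau2 = 0`.
#' @export
fixed_effect_ma <- function(summaries) {
  check_summaries(summaries)
  y <- summaries$beta1
  v <- summaries$se^2
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "beta_snp"))
  fit <- wls_fit(y, v, X, 0)
  q <- cochran_q(y, v, X)
  new_metafit("fixed", fit$coef, fit$vcov, 0, q$Q, q$df, length(y),
              degree = 0, centre = NA_real_,
              age_span = age_span_of(summaries))
}

#' Random-effects meta-analysis with REML heterogeneity
#'
#' Inverse-variance pooling with weights \eqn{w_j^* = 1/(s_j^2 +
#' \hat\tau^2)}, \eqn{\hat\tau^2} estimated by [reml_tau2()] on the
#' intercept-only model.  Reduces numerically to [fixed_effect_ma()] when
#' \eqn{\hat\tau^2 = 0}.
#'
#' @inheritParams fixed_effect_ma
#' @param knapp_hartung use the Knapp-Hartung small-sample adjustment
#'   (t critical values and scaled covariance); off by default.
#' @return A [metafit] with `model = "random"`.
#' @export
random_effects_ma <- function(summaries, knapp_hartung = FALSE) {
  check_summaries(summaries)
  y <- summaries$beta1
  v <- summaries$se^2
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "beta_snp"))
  tau2 <- as.numeric(reml_tau2(y, v, X))
  fit <- wls_fit(y, v, X, tau2, knapp_hartung)
  q <- cochran_q(y, v, X)
  new_metafit("random", fit$coef, fit$vcov, tau2, q$Q, q$df, length(y),
              degree = 0, centre = NA_real_,
              age_span = age_span_of(summaries),
              knapp_hartung = knapp_hartung, crit = fit$crit)
}

#' Inverse-variance weighted mean age
#'
#' The weighted mean age over all studies with weights \eqn{1/s_j^2}; the
#' age at which a plain meta-analysis estimate is interpretable when the
#' genetic effect varies (at most linearly) with age, and the centring
#' choice that minimises the intercept SE of a meta-regression.
#'
#' @inheritParams fixed_effect_ma
#' @return Scalar age in years.
#' @export
weighted_mean_age <- function(summaries) {
  check_summaries(summaries, need_age = TRUE)
  w <- 1 / summaries$se^2
  sum(w * summaries$mean_age) / sum(w)
}

build_moderators <- function(summaries, degree, centre) {
  if (is.character(centre)) {
    centre <- match.arg(centre, "weighted_mean")
    centre <- weighted_mean_age(summaries)
  }
  X <- derive_age_moments(summaries$mean_age, summaries$sd_age, centre, degree,
                          mean_age3 = summaries$mean_age3)
  if (degree >= 1) colnames(X) <- coef_names[seq_len(degree + 1)]
  else colnames(X) <- coef_names[1]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # name the moderator columns that add no information (e.g. all study
    # mean ages equal -> m1 constant), mirroring the low-age-diversity
    # failure mode
    bad <- colnames(X)[-1][apply(as.matrix(X[, -1, drop = FALSE]), 2,
                                 function(col) stats::sd(col) < 1e-12)]
    if (!length(bad)) bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop_agemeta(paste0("moderator matrix is rank deficient; offending column(s): ",
                        paste(bad, collapse = ", "),
                        " (studies may lack age diversity)"),
                 subclass = "collinearity")
  }
  list(X = X, centre = centre)
}

#' Random-effects meta-regression on age moments
#'
#' Regresses per-study genetic effect estimates on polynomial age moments
#' derived from each study's mean and SD of age (see
#' [derive_age_moments()]), with residual between-study variance
#' \eqn{\hat\tau^2_{res}} estimated by REML and coefficients by generalized
#' least squares with weights \eqn{1/(s_j^2 + \hat\tau^2_{res})}.  The
#' intercept is the genetic effect at age `centre`; the remaining
#' coefficients are the linear, quadratic and cubic SNP-by-age interaction
#' terms, which do not depend on the centring.  `degree = 0` reduces
#' exactly to [random_effects_ma()].
#'
#' @inheritParams random_effects_ma
#' @param degree polynomial degree 0--3.
#' @param centre centring age in years, or `"weighted_mean"` for the
#'   inverse-variance weighted mean age.
#' @return A [metafit] with `model = "metareg"`; `Q`/`I2` are the residual
#'   heterogeneity statistics after the age moderators.
#' @export
meta_regression <- function(summaries, degree = 1, centre = 0,
                            knapp_hartung = FALSE) {
  check_summaries(summaries, k_min = degree + 2L, need_age = degree >= 1)
  y <- summaries$beta1
  v <- summaries$se^2
  mod <- if (degree >= 1) build_moderators(summaries, degree, centre)
         else list(X = matrix(1, length(y), 1, dimnames = list(NULL, coef_names[1])),
                   centre = if (is.character(centre)) weighted_mean_age(summaries) else centre)
  tau2 <- as.numeric(reml_tau2(y, v, mod$X))
  fit <- wls_fit(y, v, mod$X, tau2, knapp_hartung)
  q <- cochran_q(y, v, mod$X)
  new_metafit("metareg", fit$coef, fit$vcov, tau2, q$Q, q$df, length(y),
              degree = degree, centre = mod$centre,
              age_span = age_span_of(summaries),
              knapp_hartung = knapp_hartung, crit = fit$crit)
}

#' Refit a meta-regression at a new centring age
#'
#' Recentring changes only the intercept (the genetic effect at the centre,
#' which transforms as the fitted polynomial evaluated at the new centre)
#' and its SE; the interaction coefficients are invariant.
#'
#' @param fit a `metafit` from [meta_regression()].
#' @param summaries the study summaries the fit was produced from.
#' @param new_centre new centring age (years) or `"weighted_mean"`.
#' @return A new [metafit] at `new_centre`.
#' @export
recentre <- function(fit, summaries, new_centre) {
  if (!inherits(fit, "metafit") || !fit$model %in% c("metareg")) {
    stop_agemeta("recentre() expects a meta-regression fit", "config")
  }
  meta_regression(summaries, degree = fit$degree, centre = new_centre,
                  knapp_hartung = fit$knapp_hartung)
}

#' Heterogeneity statistics of a fitted model
#'
#' Cochran's \eqn{Q = \sum_j w_j (y_j - \hat y_j)^2} with fixed-effect
#' weights \eqn{w_j = 1/s_j^2} and fitted values from the FE-weighted
#' (moderator) regression, and \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#' For moderator models these are the residual statistics, so comparing
#' `I2` before and after adding age moments shows how much between-study
#' heterogeneity the age structure explains.
#'
#' @param fit a [metafit].
#' @return Named numeric vector `c(Q, I2)`.
#' @export
heterogeneity <- function(fit) {
  stopifnot(inherits(fit, "metafit"))
  if (fit$df < 1) {
    stop_agemeta("heterogeneity is undefined with zero residual degrees of freedom",
                 subclass = "undefined_heterogeneity")
  }
  c(Q = fit$Q, I2 = fit$I2)
}

#' Predicted genetic effect across age
#'
#' Evaluates the fitted effect-by-age polynomial in powers of
#' `(age - centre)` with delta-method standard errors
#' \eqn{\sqrt{x' V x}} and 95% CIs on an age grid.  Note prediction uses
#' plain centred powers: the derived moments of [derive_age_moments()]
#' belong to fitting only, where they stand in for the study-level mean of
#' each power.  Ages outside the span of the study mean ages are allowed
#' but flagged as extrapolation.
#'
#' @param fit a [metafit] with `degree >= 0`.
#' @param ages numeric age grid (years).
#' @return Data frame `age`, `effect`, `se`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
predict_effect_at_age <- function(fit, ages) {
  stopifnot(inherits(fit, "metafit"))
  if (!fit$model %in% c("metareg", "gls", "random", "fixed")) {
    stop_agemeta("unsupported fit object", "config")
  }
  centre <- if (is.na(fit$centre)) 0 else fit$centre
  d <- ages - centre
  Xp <- stats::poly(d, degree = max(fit$degree, 1), raw = TRUE, simple = TRUE)
  Xp <- cbind(1, Xp)[, seq_len(fit$degree + 1), drop = FALSE]
  eff <- drop(Xp %*% fit$coef)
  se <- sqrt(rowSums((Xp %*% fit$vcov) * Xp))
  extrap <- if (all(is.finite(fit$age_span))) {
    ages < fit$age_span[1] | ages > fit$age_span[2]
  } else rep(NA, length(ages))
  data.frame(age = ages, effect = eff, se = se,
             ci_low = eff - fit$crit * se, ci_high = eff + fit$crit * se,
             extrapolated = extrap)
}

#' Serialise a fitted model to JSON
#'
#' @param fit a [metafit].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_metafit_json <- function(fit, path) {
  out <- fit[c("model", "degree", "centre", "coef", "se", "ci_low", "ci_high",
               "tau2", "Q", "df", "I2", "k", "knapp_hartung")]
  out$coef <- as.list(out$coef)
  out$se <- as.list(stats::setNames(fit$se, names(fit$coef)))
  out$ci_low <- as.list(stats::setNames(fit$ci_low, names(fit$coef)))
  out$ci_high <- as.list(stats::setNames(fit$ci_high, names(fit$coef)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
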