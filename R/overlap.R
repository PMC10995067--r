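#' Covariance of effect estimates under sample overlap
#'
#' When one cohort contributes several measurement occasions to a
#' meta-analysis, the occasion-level effect estimates are correlated
#' because they are computed on (largely) the same participants.  This
#' builds the block-diagonal covariance matrix of the estimates: diagonal
#' \eqn{s_j^2}, and within-cohort off-diagonals \eqn{r_{jk} s_j s_k}.
#' When correlations are not supplied, repeated measures on one cohort
#' default to \eqn{r_{jk} = n_{shared} / \sqrt{n_j n_k}} with
#' \eqn{n_{shared} = \min(n_j, n_k)} — complete overlap of the smaller
#' occasion in the larger.  Rows from different cohorts are independent.
#'
#' @param summaries study-summary data frame with `se`, `n` and
#'   `cohort_id` (every row must be mapped to a cohort).
#' @param correlations optional: a full `k x k` correlation matrix, or a
#'   named list of per-cohort correlation matrices (ordered as the
#'   cohort's rows appear).
#' @return A `k x k` covariance matrix.  Non-positive-semidefinite blocks
#'   are projected to the nearest PSD matrix (eigenvalue clipping) with a
#'   warning reporting the adjustment magnitude.
#' @export
build_covariance <- function(summaries, correlations = NULL) {
  check_summaries(summaries, k_min = 1L)
  k <- nrow(summaries)
  cohort <- summaries$cohort_id
  if (is.null(cohort) || any(is.na(cohort))) {
    stop_agemeta("every row must carry a cohort_id to build the overlap covariance",
                 "config")
  }
  s <- summaries$se
  V <- diag(s^2, k)
  if (is.matrix(correlations) && nrow(correlations) == k) {
    R <- correlations
    check_corr(R)
    V <- R * tcrossprod(s)
    return(psd_guard(V))
  }
  for (cc in unique(cohort)) {
    idx <- which(cohort == cc)
    if (length(idx) < 2) next
    R <- if (is.list(correlations) && !is.null(correlations[[cc]])) {
      correlations[[cc]]
    } else {
      n <- summaries$n[idx]
      outer(n, n, function(a, b) pmin(a, b) / sqrt(a * b))
    }
    check_corr(R, length(idx))
    V[idx, idx] <- R * tcrossprod(s[idx])
  }
  psd_guard(V)
}

check_corr <- function(R, k = nrow(R)) {
  if (nrow(R) != k || ncol(R) != k ||
      max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8 ||
      max(abs(R)) > 1 + 1e-8) {
    stop_agemeta("correlation matrices must be symmetric with unit diagonal and entries in [-1, 1]",
                 "config")
  }
  invisible(R)
}

# Clip negative eigenvalues to zero if the matrix is not PSD; warn with the
# size of the adjustment.
psd_guard <- function(V) {
  eg <- eigen(V, symmetric = TRUE)
  tol <- -1e-10 * max(abs(eg$values))
  if (min(eg$values) < tol) {
    adj <- -min(eg$values)
    warning(sprintf("covariance block not positive semidefinite; projected to nearest PSD (eigenvalue adjustment %.3g)", adj))
    lam <- pmax(eg$values, 0)
    V <- eg$vectors %*% (lam * t(eg$vectors))
  }
  V
}

# REML + GLS under a general PSD covariance Sigma + tau2 I.  The problem is
# rotated to the eigenbasis of Sigma, where it becomes the diagonal-variance
# problem with v = eigenvalues; components whose total variance vanishes and
# that carry no design information (exactly redundant rows) drop out.
gls_engine <- function(y, Sigma, X, tau2 = NULL) {
  k <- length(y)
  p <- ncol(X)
  eg <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  z <- drop(crossprod(eg$vectors, y))
  M <- crossprod(eg$vectors, X)
  scale <- max(lam, 1)
  if (is.null(tau2)) {
    live <- lam > scale * 1e-12 | abs(z) > 1e-10 | rowSums(abs(M)) > 1e-10
    if (sum(live) <= p) {
      stop_agemeta("overlap covariance leaves fewer informative components than coefficients",
                   subclass = "insufficient_studies")
    }
    tau2 <- as.numeric(reml_tau2(z[live], lam[live],
                                 M[live, , drop = FALSE]))
  }
  d <- lam + tau2
  keep <- d > scale * 1e-12
  dk <- d[keep]
  Mk <- M[keep, , drop = FALSE]
  zk <- z[keep]
  # redundant components (d ~ 0) must carry no information; if they do the
  # weight matrix is singular in a way no reweighting can fix
  if (any(!keep & (abs(z) > 1e-8 * max(abs(y), 1) | rowSums(abs(M)) > 1e-8))) {
    stop_agemeta(sprintf("singular overlap weight matrix (condition number %.3g): perfectly correlated rows disagree", max(d) / max(min(d), .Machine$double.xmin)),
                 subclass = "singular_weights")
  }
  Ms <- Mk / sqrt(dk)
  sc <- sqrt(colSums(Ms^2))
  sc[sc == 0] <- 1
  Ms <- sweep(Ms, 2, sc, "/")
  A <- crossprod(Ms)
  vcov_s <- tryCatch(chol2inv(chol(A)), error = function(e) {
    stop_agemeta("moderator matrix is computationally singular under the overlap weights",
                 subclass = "collinearity")
  })
  vcov <- vcov_s / tcrossprod(sc)
  coef <- drop(vcov %*% crossprod(Mk, zk / dk))
  names(coef) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = coef, vcov = vcov, tau2 = tau2)
}

#' GLS meta-regression with overlap-adjusted (generalized) weights
#'
#' Generalizes the inverse-variance machinery to correlated effect
#' estimates: coefficients solve the generalized least squares problem
#' with weight matrix \eqn{(\Sigma + \tau^2 I)^{-1}}, where \eqn{\Sigma}
#' is the overlap covariance from [build_covariance()] and \eqn{\tau^2}
#' is, unless supplied, estimated by REML on the whitened (eigenbasis)
#' problem.  With a diagonal \eqn{\Sigma} the fit reduces exactly to
#' [meta_regression()] (or [random_effects_ma()] at degree 0).
#'
#' @inheritParams meta_regression
#' @param covariance covariance matrix of the effect estimates; defaults
#'   to [build_covariance()] on `summaries` (requiring `cohort_id`).
#' @param tau2 optional fixed between-study variance; `NULL` (default)
#'   estimates it by REML.
#' @return A [metafit] with `model = "gls"`.  `Q`/`I2` are computed with
#'   the standard independence fixed-effect weights so they remain
#'   comparable with unadjusted fits.
#' @export
gls_meta_fit <- function(summaries, covariance = NULL, degree = 0, centre = 0,
                         tau2 = NULL) {
  check_summaries(summaries, k_min = degree + 2L, need_age = degree >= 1)
  if (is.null(covariance)) covariance <- build_covariance(summaries)
  k <- nrow(summaries)
  if (!is.matrix(covariance) || any(dim(covariance) != k)) {
    stop_agemeta("covariance must be a k x k matrix matching the summary rows",
                 "config")
  }
  y <- summaries$beta1
  mod <- if (degree >= 1) build_moderators(summaries, degree, centre)
         else list(X = matrix(1, k, 1, dimnames = list(NULL, coef_names[1])),
                   centre = if (is.character(centre)) weighted_mean_age(summaries) else centre)
  fit <- gls_engine(y, covariance, mod$X, tau2)
  q <- cochran_q(y, summaries$se^2, mod$X)
  new_metafit("gls", fit$coef, fit$vcov, fit$tau2, q$Q, q$df, k,
              degree = degree, centre = mod$centre,
              age_span = age_span_of(summaries))
}
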