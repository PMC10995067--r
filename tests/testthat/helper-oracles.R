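# Independent oracles and shared fixtures for the test suite.

# Random k-study summary fixture with heterogeneity of order tau ~ 0.5-1.
rand_summaries <- function(k, seed, tau = 0.8) {
  set.seed(seed)
  data.frame(study_id = paste0("s", seq_len(k)), cohort_id = NA_character_,
             beta1 = stats::rnorm(k, 1, tau), se = stats::runif(k, 0.1, 0.5),
             n = 1000, mean_age = stats::runif(k, 10, 60),
             sd_age = stats::runif(k, 1, 6), occasion_age = NA_real_)
}

# Brute-force restricted-likelihood grid maximiser for the intercept-only
# model, written from the closed-form profile (independent of the package's
# matrix formulation) and fully vectorised over the tau2 grid.
grid_reml_tau2 <- function(y, v, upper = 10, step = 1e-4) {
  tg <- seq(0, upper, by = step)
  Vt <- outer(v, tg, "+")
  W <- 1 / Vt
  sw <- colSums(W)
  swy <- colSums(W * y)
  swy2 <- colSums(W * y^2)
  ll <- -0.5 * (colSums(log(Vt)) + log(sw) + swy2 - swy^2 / sw)
  tg[which.max(ll)]
}

# Noiseless meta-regression fixture: per-study effects generated exactly
# from the centred-moment linear predictor with equal, tiny variances.
noiseless_metareg_fixture <- function(coefs, centre, k = 12, seed = 5) {
  set.seed(seed)
  mean_age <- stats::runif(k, 10, 60)
  sd_age <- stats::runif(k, 1, 5)
  d <- mean_age - centre
  X <- cbind(1, d, sd_age^2 + d^2, d^3 + 3 * d * sd_age^2)
  X <- X[, seq_along(coefs), drop = FALSE]
  data.frame(study_id = paste0("s", seq_len(k)), cohort_id = NA_character_,
             beta1 = drop(X %*% coefs), se = 1e-4, n = 1000,
             mean_age = mean_age, sd_age = sd_age, occasion_age = NA_real_)
}
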