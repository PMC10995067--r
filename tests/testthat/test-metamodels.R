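test_that("fixed-effect pooling matches the closed form and a brute-force oracle", {
  two <- data.frame(beta1 = c(1, 3), se = c(1, 1), mean_age = c(20, 40))
  fit <- fixed_effect_ma(two)
  expect_equal(unname(fit$coef), 2)
  expect_equal(unname(fit$se), 1 / sqrt(2))
  expect_equal(unname(fit$ci_low), 2 - qnorm(0.975) / sqrt(2))

  expect_error(fixed_effect_ma(two[1, , drop = FALSE]),
               class = "agemeta_insufficient_studies_error")

  five <- rand_summaries(5, seed = 41)
  fit5 <- fixed_effect_ma(five)
  w <- 1 / five$se^2
  expect_equal(unname(fit5$coef), sum(w * five$beta1) / sum(w), tolerance = 1e-14)
  expect_equal(unname(fit5$se), 1 / sqrt(sum(w)), tolerance = 1e-14)

  # invariance to splitting a study into two halves with the same effect
  # and weights summing to the original
  split <- rbind(five, five[3, ])
  split$se[c(3, 6)] <- five$se[3] * sqrt(2)
  expect_equal(unname(fixed_effect_ma(split)$coef), unname(fit5$coef))
  expect_equal(unname(fixed_effect_ma(split)$se), unname(fit5$se))
})

test_that("REML tau2 matches the brute-force grid and handles boundaries", {
  # identical effects: no heterogeneity
  same <- data.frame(beta1 = rep(1.3, 6), se = runif(6, 0.2, 0.5))
  expect_equal(as.numeric(reml_tau2(same$beta1, same$se^2)), 0)

  # inflated-spread fixture against the closed-form profile grid
  s <- rand_summaries(6, seed = 55, tau = 1.2)
  t_opt <- as.numeric(reml_tau2(s$beta1, s$se^2))
  t_grid <- grid_reml_tau2(s$beta1, s$se^2)
  expect_equal(t_opt, t_grid, tolerance = 2e-4)

  expect_error(reml_tau2(1.2, 0.1), class = "agemeta_insufficient_studies_error")
})

test_that("random-effects pooling nests the fixed-effect fit and matches metafor", {
  skip_if_not_installed("metafor")
  # tau2-hat = 0: numerically identical to fixed effect
  same <- data.frame(beta1 = rep(2, 5), se = runif(5, 0.2, 0.6),
                     mean_age = 1:5)
  expect_equal(random_effects_ma(same)$coef, fixed_effect_ma(same)$coef)
  expect_equal(random_effects_ma(same)$se, fixed_effect_ma(same)$se)

  # symmetric two-study case pools to the midpoint regardless of tau2
  sym <- data.frame(beta1 = c(0, 4), se = c(1, 1))
  expect_equal(unname(random_effects_ma(sym)$coef), 2)

  for (seed in c(7, 19, 33)) {
    s <- rand_summaries(12, seed = seed)
    mine <- random_effects_ma(s)
    ref <- metafor::rma(yi = s$beta1, vi = s$se^2, method = "REML")
    expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(ref$se), tolerance = 1e-6)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-5)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-8)
    # RE SE is never smaller than the FE SE on the same input
    expect_gte(unname(mine$se), unname(fixed_effect_ma(s)$se))
  }
})

test_that("age moments derive correctly from reported mean and SD", {
  m <- derive_age_moments(30, 5, centre = 10, degree = 2)
  expect_equal(unname(m[1, ]), c(1, 20, 25 + 400))

  # point mass: moments collapse to pure powers
  m0 <- derive_age_moments(7, 0, centre = 2, degree = 3)
  expect_equal(unname(m0[1, ]), c(1, 5, 25, 125))

  # uniform ages on [a, b]: derived m2 and m3 equal the exact uniform
  # moments (independent closed-form integrals)
  a <- 12; b <- 38; cc <- 10
  mu <- (a + b) / 2; sdv <- sqrt((b - a)^2 / 12)
  m <- derive_age_moments(mu, sdv, centre = cc, degree = 3)
  m2_exact <- ((b - cc)^3 - (a - cc)^3) / (3 * (b - a))
  m3_exact <- ((b - cc)^4 - (a - cc)^4) / (4 * (b - a))
  expect_equal(unname(m[1, 3]), m2_exact)
  expect_equal(unname(m[1, 4]), m3_exact)

  # Jensen: m2 >= m1^2 row-wise for arbitrary inputs
  s <- rand_summaries(20, seed = 3)
  M <- derive_age_moments(s$mean_age, s$sd_age, centre = 10, degree = 2)
  expect_true(all(M[, 3] >= M[, 2]^2))

  expect_error(derive_age_moments(10, 1, degree = 4),
               class = "agemeta_unsupported_degree_error")
})

test_that("meta-regression recovers exact coefficients and matches metafor", {
  # noiseless fixture: machine-precision recovery
  truth <- c(1.5, 0.02)
  s <- noiseless_metareg_fixture(truth, centre = 10)
  fit <- meta_regression(s, degree = 1, centre = 10)
  expect_equal(unname(fit$coef), truth, tolerance = 1e-8)
  expect_equal(fit$tau2, 0, tolerance = 1e-10)

  # degree 0 reduces to random-effects meta-analysis
  s <- rand_summaries(15, seed = 21)
  expect_equal(meta_regression(s, degree = 0)$coef,
               random_effects_ma(s)$coef, tolerance = 1e-12,
               ignore_attr = TRUE)

  skip_if_not_installed("metafor")
  for (deg in 1:3) {
    X <- derive_age_moments(s$mean_age, s$sd_age, centre = 10, degree = deg)
    ref <- metafor::rma(yi = s$beta1, vi = s$se^2,
                        mods = X[, -1, drop = FALSE], method = "REML")
    mine <- meta_regression(s, degree = deg, centre = 10)
    expect_equal(unname(mine$coef), unname(drop(ref$beta)), tolerance = 1e-5)
    expect_equal(unname(mine$se), unname(ref$se), tolerance = 1e-4)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-6)
    expect_equal(mine$df, ref$k - ref$p)
  }
})

test_that("equal study mean ages raise a collinearity error naming the column", {
  s <- rand_summaries(8, seed = 13)
  s$mean_age <- 30
  s$sd_age <- 2
  err <- tryCatch(meta_regression(s, degree = 1, centre = 10),
                  error = identity)
  expect_s3_class(err, "agemeta_collinearity_error")
  expect_match(conditionMessage(err), "beta_snp_age")
})

test_that("recentring changes only the intercept, optimally at the weighted mean age", {
  s <- rand_summaries(20, seed = 29)
  fit10 <- meta_regression(s, degree = 2, centre = 10)
  fit0 <- recentre(fit10, s, 0)
  # interaction coefficients are invariant under recentring (absolute)
  expect_lt(abs(fit0$coef[["beta_snp_age2"]] - fit10$coef[["beta_snp_age2"]]),
            1e-10)
  # the intercept transforms as the fitted polynomial at the new centre
  expect_equal(fit0$coef[["beta_snp"]],
               unname(fit10$coef[1] - 10 * fit10$coef[2] + 100 * fit10$coef[3]),
               tolerance = 1e-8)

  lin10 <- meta_regression(s, degree = 1, centre = 10)
  lin0 <- recentre(lin10, s, 0)
  expect_lt(abs(lin0$coef[["beta_snp_age"]] - lin10$coef[["beta_snp_age"]]),
            1e-10)
  expect_equal(lin0$coef[["beta_snp"]],
               unname(lin10$coef[1] - 10 * lin10$coef[2]), tolerance = 1e-8)

  # intercept SE is smallest when centring at the inverse-variance weighted
  # mean age (checked on a homogeneous fixture where tau2-hat = 0, so the
  # GLS weights coincide with the 1/s^2 weights defining that mean)
  sh <- rand_summaries(20, seed = 47, tau = 0.03)
  lin <- meta_regression(sh, degree = 1, centre = 10)
  wma <- weighted_mean_age(sh)
  se_at <- vapply(seq(5, 60, by = 2.5), function(cc) {
    meta_regression(sh, degree = 1, centre = cc)$se[["beta_snp"]]
  }, numeric(1))
  se_wma <- recentre(lin, sh, "weighted_mean")$se[["beta_snp"]]
  expect_true(all(se_wma <= se_at + 1e-10))
  expect_equal(recentre(lin, sh, "weighted_mean")$centre, wma)
})

test_that("heterogeneity statistics follow the Q / I2 definitions", {
  # zero residuals: Q = 0, I2 = 0
  s <- noiseless_metareg_fixture(c(1, 0.1), centre = 0)
  fit <- meta_regression(s, degree = 1, centre = 0)
  expect_equal(unname(heterogeneity(fit)["Q"]), 0, tolerance = 1e-10)
  expect_equal(unname(heterogeneity(fit)["I2"]), 0)

  # two studies at +/- sqrt(2) with unit variances: Q = 4 = 4 df, I2 = 75%
  s2 <- data.frame(beta1 = c(sqrt(2), -sqrt(2)), se = c(1, 1))
  fit2 <- fixed_effect_ma(s2)
  expect_equal(unname(heterogeneity(fit2)), c(4, 75))

  # Q = df boundary gives I2 = 0
  s3 <- data.frame(beta1 = c(sqrt(1 / 2), -sqrt(1 / 2)), se = c(1, 1))
  expect_equal(unname(heterogeneity(fixed_effect_ma(s3))["I2"]), 0)

  fit2$df <- 0
  expect_error(heterogeneity(fit2),
               class = "agemeta_undefined_heterogeneity_error")
})

test_that("effect-by-age prediction evaluates the centred polynomial with delta-method SEs", {
  # exact linear fit with known coefficients: effect at age 4 is 1 + 0.5*4
  s <- noiseless_metareg_fixture(c(1, 0.5), centre = 0)
  fit <- meta_regression(s, degree = 1, centre = 0)
  pred <- predict_effect_at_age(fit, c(0, 4))
  expect_equal(pred$effect, c(1, 3), tolerance = 1e-8)

  # prediction at the centre returns the intercept and its SE
  s <- rand_summaries(15, seed = 61)
  fit <- meta_regression(s, degree = 2, centre = 10)
  at_centre <- predict_effect_at_age(fit, 10)
  expect_equal(at_centre$effect, unname(fit$coef[1]))
  expect_equal(at_centre$se, unname(fit$se[1]))

  # extrapolation beyond the span of study mean ages is flagged
  pred <- predict_effect_at_age(fit, c(min(s$mean_age) - 5, mean(s$mean_age)))
  expect_equal(pred$extrapolated, c(TRUE, FALSE))
})

test_that("Knapp-Hartung widens intervals via t critical values when requested", {
  s <- rand_summaries(8, seed = 71)
  plain <- random_effects_ma(s)
  kh <- random_effects_ma(s, knapp_hartung = TRUE)
  expect_gt(kh$crit, plain$crit)
  expect_gte(kh$ci_high[1] - kh$ci_low[1], plain$ci_high[1] - plain$ci_low[1])
})
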