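test_that("age windows follow the overlap geometry", {
  # two disjoint halves
  w <- make_age_windows(sim_design(2, 10, c(10, 59), 0, seed = 1))
  expect_equal(unname(w), rbind(c(10, 34.5), c(34.5, 59)))

  # complete overlap: every window is the full range
  w <- make_age_windows(sim_design(40, 10, c(10, 59), 100, seed = 1))
  expect_true(all(w[, 1] == 10) && all(w[, 2] == 59))

  # 3 windows, range [0, 30], 50%: width 15, centres 7.5/15/22.5,
  # adjacent overlap 7.5 years (solved analytically from the geometry)
  w <- make_age_windows(sim_design(3, 10, c(0, 30), 50, seed = 1))
  expect_equal(unname(w), rbind(c(0, 15), c(7.5, 22.5), c(15, 30)))
  expect_equal(unname(w[1, 2] - w[2, 1]), 7.5)

  # geometry invariants across all levels and study counts
  for (p in c(0, 25, 50, 75, 100)) {
    for (k in c(2, 5, 40)) {
      w <- make_age_windows(sim_design(k, 10, c(10, 59), p, seed = 1))
      widths <- w[, 2] - w[, 1]
      expect_equal(max(widths) - min(widths), 0)        # equal widths
      expect_equal(c(min(w), max(w)), c(10, 59))        # union spans range
      centres <- rowMeans(w)
      expect_equal(centres, rev(10 + 59 - centres))     # symmetric centres
      if (p == 0 && k > 1) {
        expect_true(all(w[-k, 2] <= w[-1, 1] + 1e-12))  # disjoint tiling
      }
      if (k > 1) {
        # adjacent overlap fraction = p/100 of the window width
        expect_equal(unname((w[1, 2] - w[2, 1]) / widths[1]), p / 100)
      }
    }
  }

  expect_error(sim_design(3, 10, c(0, 30), 37, seed = 1),
               class = "agemeta_config_error")
  # explicit windows override the parametric geometry
  win <- rbind(c(1, 5), c(4, 9))
  d <- sim_design(2, 10, c(0, 10), age_windows = win, seed = 1)
  expect_equal(unname(make_age_windows(d)), win)
  expect_error(sim_design(2, 10, c(0, 4), age_windows = win, seed = 1),
               class = "agemeta_config_error")
})

test_that("the generating equation and scenario nesting are exact", {
  # noiseless scenario 1: y = 25 + 0.010 age + 1.5 snp exactly; at age 10
  # with 2 alleles that is 25 + 0.1 + 3.0 = 28.1
  sp <- scenario_spec(1, sigma_within = 0, sigma_between = 0)
  d <- sim_design(2, 200, c(10, 10 + 1e-9), 100, seed = 3)
  s1 <- simulate_collection(d, sp)$studies[[1]]
  expect_equal(s1$y, 25 + 0.010 * s1$age + 1.5 * s1$snp)
  expect_true(any(s1$snp == 2))
  expect_equal(unique(round(s1$y[s1$snp == 2], 6)), 28.1)

  # zeroing the extra term of a richer scenario reproduces the nested one
  # under the same seed (identical draws, reduced equation)
  d <- sim_design(4, 50, c(10, 59), 25, seed = 11)
  pairs <- list(list(rich = scenario_spec(2, beta_snp_age = 0),
                     base = scenario_spec(1)),
                list(rich = scenario_spec(4, beta_snp_age = 0),
                     base = scenario_spec(3)),
                list(rich = scenario_spec(5, beta_snp_age2 = 0),
                     base = scenario_spec(4)))
  for (pr in pairs) {
    rich_y <- simulate_collection(d, pr$rich)$studies
    base_y <- simulate_collection(d, pr$base)$studies
    for (j in seq_along(rich_y)) expect_equal(rich_y[[j]]$y, base_y[[j]]$y)
  }
})

test_that("draws match their generating distributions", {
  d <- sim_design(10, 5000, c(10, 59), 100, seed = 77)
  coll <- simulate_collection(d, scenario_spec(1))
  all_rows <- do.call(rbind, coll$studies)

  # Hardy-Weinberg proportions at MAF 0.2: (0.64, 0.32, 0.04)
  p_hat <- tabulate(all_rows$snp + 1L, 3L) / nrow(all_rows)
  expect_equal(p_hat, c(0.64, 0.32, 0.04), tolerance = 0.02)

  # uniform age moments per study window
  s1 <- coll$studies[[1]]
  expect_equal(mean(s1$age), 34.5, tolerance = 0.5)
  expect_equal(sd(s1$age), sqrt(49^2 / 12), tolerance = 0.3)

  # determinism and per-study sub-stream independence
  again <- simulate_collection(d, scenario_spec(1))
  expect_identical(coll$studies, again$studies)
  d2 <- sim_design(10, c(100, rep(5000, 9)), c(10, 59), 100, seed = 77)
  coll2 <- simulate_collection(d2, scenario_spec(1))
  expect_identical(coll2$studies[[2]], coll$studies[[2]])
})

test_that("between-study deviations have the specified variance", {
  d <- sim_design(10000, 3, c(10, 59), 100, seed = 123)
  coll <- simulate_collection(d, scenario_spec(1, sigma_between = 1))
  expect_equal(var(coll$truth$u), 1, tolerance = 0.05)
  coll0 <- simulate_collection(d, scenario_spec(1, sigma_between = 0))
  expect_true(all(coll0$truth$u == 0))
})

test_that("the emulated applied table has the documented shape and truth", {
  tab <- emulate_applied_table(seed = 9)
  expect_equal(nrow(tab), 80)
  expect_equal(length(unique(tab$cohort_id)), 8)
  expect_true(all(tab$se > 0))
  expect_true(all(tab$n >= 569 & tab$n <= 7482))
  expect_true(all(tab$occasion_age >= 0 & tab$occasion_age <= 13))
  expect_identical(tab, emulate_applied_table(seed = 9))

  # the generating cubic is negative below 3, positive above 5.5, with a
  # single sign change in between (root located independently)
  cf <- attr(tab, "true_coefs")
  expect_true(all(applied_true_curve(seq(0, 3, 0.1), cf) < 0))
  expect_true(all(applied_true_curve(seq(5.5, 13, 0.1), cf) > 0))
  root <- uniroot(function(a) applied_true_curve(a, cf), c(3, 5.5))$root
  expect_gt(root, 3)
  expect_lt(root, 5.5)
})

test_that("simulation configs round-trip through YAML", {
  sp <- scenario_spec(4, sigma_between = 2)
  d <- sim_design(12, 500, c(5, 40), 75, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(sp, d, path)
  back <- read_sim_config(path)
  expect_equal(back$spec, sp)
  expect_equal(back$design, d)
})
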