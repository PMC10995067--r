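#' Phenotype-generating scenario specification
#'
#' Defines one of five data-generating mechanisms for a quantitative trait
#' influenced by a single SNP whose effect may vary with age.  The phenotype
#' of participant \eqn{i} in study \eqn{j} is generated as
#' \deqn{y_{ij} = \beta_0 + \beta_{age} age_{ij} + \beta_{age^2} age_{ij}^2 +
#'   (\beta_{SNP} + u_j) SNP_{ij} + \beta_{SNP \times age}\, age_{ij} SNP_{ij} +
#'   \beta_{SNP \times age^2}\, age_{ij}^2 SNP_{ij} + \epsilon_{ij}}
#' with \eqn{u_j \sim N(0, \sigma_{between}^2)} a study-level shift of the SNP
#' coefficient only, and \eqn{\epsilon_{ij} \sim N(0, \sigma_{within}^2)}.
#' The five scenarios switch terms on and off:
#' \describe{
#'   \item{1}{age + genotype}
#'   \item{2}{scenario 1 + linear SNP-by-age interaction}
#'   \item{3}{age + quadratic age + genotype}
#'   \item{4}{scenario 3 + linear SNP-by-age interaction}
#'   \item{5}{scenario 4 + quadratic SNP-by-age interaction}
#' }
#' Coefficients of terms absent from the chosen scenario's equation are
#' forced to zero regardless of the supplied values.  The defaults are the
#' base-case parameterisation: baseline 25, age effect 0.010 per year,
#' quadratic age effect 0.001, main genetic effect 1.5 per allele, linear
#' interaction 0.020 per allele-year, quadratic interaction 0.001, unit
#' within- and between-study SDs, MAF 0.2.
#'
#' @param scenario integer 1--5 selecting the generating equation.
#' @param beta0 baseline phenotype mean at age 0 with 0 alleles.
#' @param beta_age linear age effect (phenotype units per year).
#' @param beta_age2 quadratic age effect (per year squared).
#' @param beta_snp main genetic effect (per allele).
#' @param beta_snp_age linear SNP-by-age interaction (per allele per year).
#' @param beta_snp_age2 quadratic SNP-by-age interaction (per allele per
#'   year squared).
#' @param sigma_within SD of the individual-level error; `>= 0` (zero is
#'   permitted so noiseless fixtures can be generated).
#' @param sigma_between SD of the study-level SNP-effect deviation `u_j`.
#' @param maf minor allele frequency in (0, 0.5].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario,
                          beta0 = 25, beta_age = 0.010, beta_age2 = 0.001,
                          beta_snp = 1.5, beta_snp_age = 0.020,
                          beta_snp_age2 = 0.001,
                          sigma_within = 1, sigma_between = 1, maf = 0.2) {
  if (length(scenario) != 1L || !scenario %in% 1:5) {
    stop_agemeta("scenario must be a single integer in 1..5", "config")
  }
  scenario <- as.integer(scenario)
  # terms not present in the scenario's equation are forced to 0
  if (scenario %in% c(1L, 2L)) beta_age2 <- 0
  if (scenario %in% c(1L, 3L)) beta_snp_age <- 0
  if (scenario != 5L) beta_snp_age2 <- 0
  if (sigma_within < 0 || sigma_between < 0) {
    stop_agemeta("sigma_within and sigma_between must be non-negative", "config")
  }
  if (maf <= 0 || maf > 0.5) {
    stop_agemeta("maf must lie in (0, 0.5]", "config")
  }
  structure(list(scenario = scenario, beta0 = beta0, beta_age = beta_age,
                 beta_age2 = beta_age2, beta_snp = beta_snp,
                 beta_snp_age = beta_snp_age, beta_snp_age2 = beta_snp_age2,
                 sigma_within = sigma_within, sigma_between = sigma_between,
                 maf = maf),
            class = "scenario_spec")
}

#' Multi-study simulation design
#'
#' Collection-level design: number of studies, per-study sample sizes, the
#' global age range, and the degree of between-study age overlap.  The
#' overlap percentage controls how much the per-study age windows share
#' support: 0% gives pairwise-disjoint windows tiling the global range (high
#' age diversity), 100% gives identical full-range windows (no age
#' diversity), with 25% steps in between.
#'
#' @param n_studies number of studies (>= 2).
#' @param n_per_study a single sample size or a vector of length `n_studies`.
#' @param age_range global `[min, max]` age in years.
#' @param overlap_pct one of 0, 25, 50, 75, 100 (ignored when
#'   `age_windows` is supplied).
#' @param age_windows optional explicit per-study age windows (matrix or
#'   list of `[lo, hi]`), overriding the parametric overlap geometry.
#' @param seed root RNG seed (mandatory; spawns independent per-study
#'   sub-streams).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_studies = 40, n_per_study = 1000,
                       age_range = c(10, 59), overlap_pct = 0,
                       age_windows = NULL, seed) {
  if (missing(seed)) stop_agemeta("sim_design() requires an explicit seed", "config")
  if (n_studies < 2) stop_agemeta("n_studies must be at least 2", "config")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop_agemeta("age_range must be an increasing [min, max] pair", "config")
  }
  if (!is.null(age_windows)) {
    if (is.list(age_windows)) age_windows <- do.call(rbind, age_windows)
    age_windows <- matrix(as.numeric(age_windows), ncol = 2L)
    if (nrow(age_windows) != n_studies) {
      stop_agemeta("age_windows must supply one [lo, hi] pair per study", "config")
    }
    if (any(age_windows[, 1] >= age_windows[, 2]) ||
        any(age_windows[, 1] < age_range[1] - 1e-8) ||
        any(age_windows[, 2] > age_range[2] + 1e-8)) {
      stop_agemeta("explicit age windows must be increasing and lie inside age_range",
                   "config")
    }
  } else if (!overlap_pct %in% c(0, 25, 50, 75, 100)) {
    stop_agemeta("overlap_pct must be one of 0, 25, 50, 75, 100 (or supply age_windows)",
                 "config")
  }
  n_per_study <- rep_len(as.numeric(n_per_study), n_studies)
  if (any(n_per_study < 3)) {
    stop_agemeta("each study needs at least 3 participants", "config")
  }
  structure(list(n_studies = as.integer(n_studies), n_per_study = n_per_study,
                 age_range = as.numeric(age_range),
                 overlap_pct = as.numeric(overlap_pct),
                 age_windows = age_windows, seed = as.integer(seed)),
            class = "sim_design")
}

#' Per-study age windows for a given overlap level
#'
#' Computes equal-width age windows with equally spaced centres spanning the
#' design's global age range.  With overlap fraction `p = overlap_pct / 100`
#' adjacent windows share a fraction `p` of their common width `w`, which
#' forces `w = span / (1 + (k - 1)(1 - p))` and centre spacing `w (1 - p)`.
#' At 0% the windows tile the range disjointly; at 100% every window equals
#' the full range.  The union of the windows always equals the global range.
#'
#' @param design a [sim_design()] object.
#' @return A `n_studies x 2` matrix of `[lo, hi]` windows (years).
#' @export
make_age_windows <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$age_windows)) return(design$age_windows)
  k <- design$n_studies
  lo <- design$age_range[1]
  span <- diff(design$age_range)
  p <- design$overlap_pct / 100
  w <- span / (1 + (k - 1) * (1 - p))
  step <- w * (1 - p)
  starts <- lo + step * (seq_len(k) - 1)
  cbind(lo = starts, hi = starts + w)
}

# Evaluate the generating equation for vectors of age/snp draws.
eval_phenotype <- function(spec, age, snp, u, eps) {
  spec$beta0 + spec$beta_age * age + spec$beta_age2 * age^2 +
    (spec$beta_snp + u) * snp +
    spec$beta_snp_age * age * snp +
    spec$beta_snp_age2 * age^2 * snp +
    eps
}

#' Simulate a collection of cross-sectional studies
#'
#' For each study `j` the study-level deviation `u_j ~ N(0, sigma_between^2)`
#' is drawn once; each participant then receives an age uniform on the
#' study's window, an allele count Binomial(2, MAF), and an error
#' `N(0, sigma_within^2)`, and the phenotype is evaluated from the scenario
#' equation.  Each study consumes an independent RNG sub-stream derived from
#' the root seed, so the draws of study `j` depend only on the seed and `j`.
#'
#' @param design a [sim_design()].
#' @param spec a [scenario_spec()].
#' @return An object of class `study_collection`: a list with `studies`
#'   (list of per-study data frames with columns `study`, `age`, `snp`,
#'   `y`), `truth` (per-study `u`, window, sub-seed), and the `design` and
#'   `spec` used.
#' @export
simulate_collection <- function(design, spec) {
  stopifnot(inherits(design, "sim_design"), inherits(spec, "scenario_spec"))
  windows <- make_age_windows(design)
  k <- design$n_studies
  seeds <- derive_seeds(design$seed, k)
  studies <- vector("list", k)
  u <- numeric(k)
  for (j in seq_len(k)) {
    set.seed(seeds[j])
    u[j] <- stats::rnorm(1, 0, spec$sigma_between)
    n <- design$n_per_study[j]
    age <- stats::runif(n, windows[j, 1], windows[j, 2])
    snp <- stats::rbinom(n, 2L, spec$maf)
    eps <- stats::rnorm(n, 0, spec$sigma_within)
    studies[[j]] <- data.frame(study = j, age = age, snp = snp,
                               y = eval_phenotype(spec, age, snp, u[j], eps))
  }
  structure(list(studies = studies,
                 truth = data.frame(study = seq_len(k), u = u,
                                    lo = windows[, 1], hi = windows[, 2],
                                    seed = seeds),
                 design = design, spec = spec),
            class = "study_collection")
}

#' True effect-by-age cubic used by the emulated applied table
#'
#' @param age ages in years.
#' @param coefs cubic coefficients `c(b0, b1, b2, b3)` of
#'   `b0 + b1 age + b2 age^2 + b3 age^3`.
#' @return Effect sizes at `age`.
#' @export
applied_true_curve <- function(age, coefs = c(-0.07, 0.005, 0.0032, -0.00014)) {
  coefs[1] + coefs[2] * age + coefs[3] * age^2 + coefs[4] * age^3
}

#' Emulate a cohort-by-occasion applied summary table
#'
#' Generates a synthetic summary table shaped like a per-SNP lookup across
#' several cohorts each measured at multiple ages in childhood: one row per
#' cohort-occasion carrying the estimated per-allele effect, its standard
#' error, the cohort sample size and the occasion age.  The true effect
#' follows a built-in cubic in age (default: negative below age 3, a single
#' sign change before age 5.5, positive thereafter), so the sign-change
#' behaviour of a cubic meta-regression can be exercised without any
#' external data.  Cohort-level deviations induce realistic between-cohort
#' heterogeneity; rows from the same cohort share that deviation, mimicking
#' the sample overlap of repeated measurement occasions.
#'
#' @param n_cohorts number of cohorts (>= 2).
#' @param occasions_per_cohort measurement occasions per cohort.
#' @param age_range `[min, max]` occasion ages in years.
#' @param seed RNG seed (byte-identical output for equal seeds).
#' @param coefs generating cubic, see [applied_true_curve()].
#' @param sigma_cohort SD of the cohort-level effect deviation.
#' @param n_range `[min, max]` cohort sample sizes.
#' @return A study-summary data frame (see [fit_study()] for the column
#'   schema) with `cohort_id` and `occasion_age` filled in and
#'   `sd_age = 0` (each occasion is a single-age measurement).
#' @export
emulate_applied_table <- function(n_cohorts = 8, occasions_per_cohort = 10,
                                  age_range = c(0, 13), seed,
                                  coefs = c(-0.07, 0.005, 0.0032, -0.00014),
                                  sigma_cohort = 0.01,
                                  n_range = c(569, 7482)) {
  if (missing(seed)) stop_agemeta("emulate_applied_table() requires a seed", "config")
  if (n_cohorts < 2) stop_agemeta("n_cohorts must be at least 2", "config")
  seeds <- derive_seeds(seed, n_cohorts)
  ages <- seq(age_range[1], age_range[2], length.out = occasions_per_cohort)
  rows <- vector("list", n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    set.seed(seeds[cc])
    n <- round(stats::runif(1, n_range[1], n_range[2]))
    u <- stats::rnorm(1, 0, sigma_cohort)
    se <- 1.5 / sqrt(n)
    beta1 <- applied_true_curve(ages, coefs) + u +
      stats::rnorm(occasions_per_cohort, 0, se)
    rows[[cc]] <- data.frame(
      study_id = paste0("cohort", cc, "_t", seq_along(ages)),
      cohort_id = paste0("cohort", cc),
      beta1 = beta1, se = se, n = n,
      mean_age = ages, sd_age = 0, occasion_age = ages
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_coefs") <- coefs
  out
}

#' Read / write a simulation configuration
#'
#' Round-trips a [scenario_spec()] plus [sim_design()] pair through a YAML
#' (or JSON) file with top-level keys `scenario` and `design`.
#'
#' @param path file path.
#' @return `read_sim_config()` returns `list(spec, design)`.
#' @export
read_sim_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_agemeta(paste0("cannot parse config '", path, "': ",
                        conditionMessage(e)), "config")
  })
  if (is.null(cfg$scenario) || is.null(cfg$design)) {
    stop_agemeta("config must contain 'scenario' and 'design' sections", "config")
  }
  spec <- do.call(scenario_spec, cfg$scenario)
  design <- do.call(sim_design, cfg$design)
  list(spec = spec, design = design)
}

#' @rdname read_sim_config
#' @param spec a [scenario_spec()].
#' @param design a [sim_design()].
#' @export
write_sim_config <- function(spec, design, path) {
  design_fields <- design[c("n_studies", "n_per_study", "age_range",
                            "overlap_pct", "seed")]
  if (!is.null(design$age_windows)) {
    design_fields$age_windows <- apply(design$age_windows, 1, as.list)
  }
  yaml::write_yaml(list(scenario = unclass(spec), design = design_fields), path)
  invisible(path)
}
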