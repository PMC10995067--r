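#' True coefficient values implied by a scenario and centring
#'
#' In a large age-adjusted study the per-allele regression coefficient
#' converges to \eqn{\beta_{SNP} + \beta_{SNP\times age}\,\bar a_j +
#' \beta_{SNP\times age^2}\,\overline{a^2_j}}, so the polynomial
#' meta-regression centred at `c` has true coefficients: intercept
#' \eqn{\beta_{SNP} + \beta_{SNP\times age} c + \beta_{SNP\times age^2} c^2}
#' (the genetic effect at age `c`), linear term
#' \eqn{\beta_{SNP\times age} + 2 c \beta_{SNP\times age^2}} (the slope of
#' the effect-by-age curve at `c`), and quadratic term
#' \eqn{\beta_{SNP\times age^2}}.  These are the estimand truths used for
#' bias and coverage — computed from the generating parameters, never
#' entered by hand.
#'
#' @param spec a [scenario_spec()].
#' @param centre centring age (years).
#' @return Named vector `beta_snp`, `beta_snp_age`, `beta_snp_age2`.
#' @export
true_effects <- function(spec, centre = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  c(beta_snp = spec$beta_snp + spec$beta_snp_age * centre +
      spec$beta_snp_age2 * centre^2,
    beta_snp_age = spec$beta_snp_age + 2 * centre * spec$beta_snp_age2,
    beta_snp_age2 = spec$beta_snp_age2)
}

estimator_defs <- list(
  fe  = list(fun = function(s, centre) fixed_effect_ma(s),  degree = 0L),
  re  = list(fun = function(s, centre) random_effects_ma(s), degree = 0L),
  mr1 = list(fun = function(s, centre) meta_regression(s, 1, centre), degree = 1L),
  mr2 = list(fun = function(s, centre) meta_regression(s, 2, centre), degree = 2L),
  mr3 = list(fun = function(s, centre) meta_regression(s, 3, centre), degree = 3L)
)

#' Run one simulation cell
#'
#' One cell of the factorial experiment: repeatedly simulate a collection
#' under the given scenario and design, reduce each study by [fit_study()],
#' apply each estimator, and record per-replicate coefficient estimates,
#' SEs and 95% CIs.  Deterministic given `seed`; estimator failures are
#' recorded per replicate (message in `error`, `NA` estimates), never
#' dropped silently.  Because replicate sub-seeds are drawn in a single
#' block, the first `R` replicates of a longer run reproduce a shorter run
#' exactly, so cells scale linearly and split cleanly across configs.
#'
#' @param scenario scenario id 1--5.
#' @param n_studies,n_per_study,age_range,overlap_pct design parameters
#'   (see [sim_design()]).
#' @param sigma_within,sigma_between,maf generating parameters
#'   (see [scenario_spec()]).
#' @param estimators subset of `"fe"`, `"re"`, `"mr1"`, `"mr2"`, `"mr3"`.
#' @param centre centring age for the meta-regressions (years).
#' @param reps number of Monte Carlo replicates.
#' @param seed root seed for the cell.
#' @return Data frame with one row per replicate x estimator x estimand:
#'   `rep`, `estimator`, `estimand`, `est`, `se`, `ci_low`, `ci_high`,
#'   `df`, `tau2`, `error`.
#' @export
run_cell <- function(scenario = 1, n_studies = 40, n_per_study = 1000,
                     age_range = c(10, 59), overlap_pct = 0,
                     sigma_within = 1, sigma_between = 1, maf = 0.2,
                     estimators = c("fe", "re", "mr1", "mr2"),
                     centre = 10, reps = 500, seed) {
  if (missing(seed)) stop_agemeta("run_cell() requires a seed", "config")
  if (reps < 1) stop_agemeta("reps must be at least 1", "config")
  estimators <- match.arg(estimators, names(estimator_defs), several.ok = TRUE)
  spec <- scenario_spec(scenario, sigma_within = sigma_within,
                        sigma_between = sigma_between, maf = maf)
  rep_seeds <- derive_seeds(seed, reps)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    design <- sim_design(n_studies, n_per_study, age_range, overlap_pct,
                         seed = rep_seeds[r])
    summaries <- suppressWarnings(fit_studies(simulate_collection(design, spec)))
    rows <- lapply(estimators, function(est) {
      def <- estimator_defs[[est]]
      fit <- tryCatch(def$fun(summaries, centre), error = function(e) e)
      nm <- coef_names[seq_len(def$degree + 1)]
      if (inherits(fit, "error")) {
        data.frame(rep = r, estimator = est, estimand = nm,
                   est = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   df = NA_integer_, tau2 = NA_real_,
                   error = conditionMessage(fit))
      } else {
        data.frame(rep = r, estimator = est, estimand = nm,
                   est = unname(fit$coef), se = unname(fit$se),
                   ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
                   df = fit$df, tau2 = fit$tau2, error = NA_character_)
      }
    })
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "spec") <- spec
  attr(res, "centre") <- centre
  res
}

mcse_cols <- c("mean", "bias", "coverage", "emp_se", "mean_se")

#' Performance measures with Monte Carlo standard errors
#'
#' Summarises replicate-level estimates into the five standard simulation
#' performance measures per estimator x estimand: mean estimate, bias
#' (mean minus truth), coverage of the 95% CI, empirical SE (SD of the
#' estimates) and mean reported SE, each with its Monte Carlo SE
#' (mean/bias: EmpSE / sqrt(R); coverage: sqrt(p (1 - p) / R); EmpSE:
#' EmpSE / sqrt(2 (R - 1)); MeanSE: SD(SE) / sqrt(R)).  Replicates whose
#' estimator failed count towards `n_fail` and are excluded from the
#' measure denominators (no CI was produced).
#'
#' @param replicates output of [run_cell()].
#' @param truth named truth vector per estimand; defaults to
#'   [true_effects()] of the cell's generating scenario and centre.
#' @return A `perf_table` data frame, one row per estimator x estimand.
#' @export
summarise_replicates <- function(replicates, truth = NULL) {
  if (is.null(truth)) {
    spec <- attr(replicates, "spec")
    if (is.null(spec)) {
      stop_agemeta("supply truth explicitly for replicate tables without a recorded scenario",
                   "config")
    }
    truth <- true_effects(spec, attr(replicates, "centre"))
  }
  groups <- unique(replicates[, c("estimator", "estimand")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- replicates[replicates$estimator == groups$estimator[i] &
                      replicates$estimand == groups$estimand[i], ]
    ok <- g[is.na(g$error), ]
    R <- nrow(ok)
    if (R < 2) {
      stop_agemeta("at least 2 successful replicates are required per cell",
                   subclass = "insufficient_replication")
    }
    tv <- unname(truth[groups$estimand[i]])
    emp_se <- stats::sd(ok$est)
    cov <- mean(ok$ci_low <= tv & tv <= ok$ci_high)
    data.frame(
      estimator = groups$estimator[i], estimand = groups$estimand[i],
      truth = tv, n_reps = R, n_fail = nrow(g) - R,
      mean = mean(ok$est), mean_mcse = emp_se / sqrt(R),
      bias = mean(ok$est) - tv, bias_mcse = emp_se / sqrt(R),
      coverage = cov, coverage_mcse = sqrt(cov * (1 - cov) / R),
      emp_se = emp_se, emp_se_mcse = emp_se / sqrt(2 * (R - 1)),
      mean_se = mean(ok$se), mean_se_mcse = stats::sd(ok$se) / sqrt(R)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("perf_table", "data.frame")
  out
}

#' Reshape a performance table
#'
#' `"wide"` is the native layout (one row per estimator x estimand with
#' one column per measure and its MCSE); `"long"` stacks the five measures
#' into `measure` / `value` / `mcse` rows.  The reshaping is lossless:
#' long -> wide -> long is the identity.
#'
#' @param perf a `perf_table` (wide) or its long form.
#' @param shape target shape, `"long"` or `"wide"`.
#' @return The reshaped data frame.
#' @export
render_tables <- function(perf, shape = c("long", "wide")) {
  shape <- match.arg(shape)
  id_cols <- c("estimator", "estimand", "truth", "n_reps", "n_fail")
  if (shape == "long") {
    stopifnot(all(mcse_cols %in% names(perf)))
    rows <- lapply(mcse_cols, function(m) {
      cbind(perf[, id_cols], measure = m, value = perf[[m]],
            mcse = perf[[paste0(m, "_mcse")]])
    })
    out <- do.call(rbind, rows)
    out <- out[order(match(out$estimator, unique(perf$estimator)),
                     out$estimand, match(out$measure, mcse_cols)), ]
    rownames(out) <- NULL
    out
  } else {
    stopifnot(all(c("measure", "value", "mcse") %in% names(perf)))
    keys <- unique(perf[, id_cols])
    out <- keys
    for (m in mcse_cols) {
      sub <- perf[perf$measure == m, ]
      ord <- match(interaction(keys$estimator, keys$estimand),
                   interaction(sub$estimator, sub$estimand))
      out[[m]] <- sub$value[ord]
      out[[paste0(m, "_mcse")]] <- sub$mcse[ord]
    }
    rownames(out) <- NULL
    class(out) <- c("perf_table", "data.frame")
    out
  }
}

#' Run a factorial experiment grid
#'
#' Expands the supplied design factors into cells, runs [run_cell()] on
#' each with an independent sub-seed derived from the root seed, and binds
#' the per-cell performance tables with the cell configuration attached as
#' columns.  Each cell is independent, so the full published-scale grid is
#' purely a configuration change (and cells can be re-run or distributed
#' individually).
#'
#' @param scenarios,overlaps,n_studies,n_per_study,sigmas_between vectors
#'   of factor levels (crossed).
#' @param estimators,centre,reps,seed as in [run_cell()].
#' @return A `perf_table` with cell-identifying columns prepended.
#' @export
run_grid <- function(scenarios = 1, overlaps = 0, n_studies = 40,
                     n_per_study = 1000, sigmas_between = 1,
                     estimators = c("fe", "re", "mr1", "mr2"),
                     centre = 10, reps = 500, seed) {
  if (missing(seed)) stop_agemeta("run_grid() requires a seed", "config")
  cells <- expand.grid(scenario = scenarios, overlap_pct = overlaps,
                       n_studies = n_studies, n_per_study = n_per_study,
                       sigma_between = sigmas_between)
  cell_seeds <- derive_seeds(seed, nrow(cells))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    reps_df <- run_cell(scenario = cells$scenario[i],
                        n_studies = cells$n_studies[i],
                        n_per_study = cells$n_per_study[i],
                        overlap_pct = cells$overlap_pct[i],
                        sigma_between = cells$sigma_between[i],
                        estimators = estimators, centre = centre,
                        reps = reps, seed = cell_seeds[i])
    perf_i <- summarise_replicates(reps_df)
    cbind(cells[rep(i, nrow(perf_i)), , drop = FALSE], perf_i)
  })
  perf <- do.call(rbind, out)
  rownames(perf) <- NULL
  class(perf) <- c("perf_table", "data.frame")
  perf
}
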