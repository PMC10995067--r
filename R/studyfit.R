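#' Reduce one study to GWAS-style summary statistics
#'
#' Ordinary least squares of the phenotype on an intercept, the allele
#' count, and age — the usual age-adjusted single-SNP GWAS model.  No
#' interaction or higher-order terms are ever included at this stage; the
#' age dependence of the genetic effect is recovered downstream from the
#' between-study variation in mean age.  The per-allele coefficient, its
#' conventional residual-variance standard error, and the sample mean and
#' SD of age (n - 1 denominator, as cohorts conventionally report) are
#' returned.
#'
#' @param table data frame with columns `age`, `snp`, `y` (one row per
#'   participant).
#' @param study_id label for the study (defaults to the `study` column or
#'   `"study1"`).
#' @param cohort_id optional cohort label for overlap bookkeeping.
#' @return One-row data frame with columns `study_id`, `cohort_id`,
#'   `beta1`, `se`, `n`, `mean_age`, `sd_age`, `occasion_age`.  A study
#'   with zero residual variance is returned with `se = 0` and flagged via
#'   `attr(, "zero_residual")`.
#' @section Errors: a monomorphic SNP, constant age, or fewer than 3
#'   participants make the three-parameter design singular and raise a
#'   `degenerate_study` error; [fit_studies()] drops such studies with a
#'   warning.
#' @export
fit_study <- function(table, study_id = NULL, cohort_id = NA_character_) {
  need <- c("age", "snp", "y")
  if (!all(need %in% names(table))) {
    stop_agemeta("study table needs columns age, snp, y", "config")
  }
  n <- nrow(table)
  if (n < 3L) {
    stop_agemeta("a study needs at least 3 participants", subclass = "degenerate_study")
  }
  X <- cbind(1, table$snp, table$age)
  XtX <- crossprod(X)
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXinv)) {
    stop_agemeta("singular design (monomorphic SNP or constant age)",
                 subclass = "degenerate_study")
  }
  coefs <- XtXinv %*% crossprod(X, table$y)
  resid <- table$y - X %*% coefs
  sigma2 <- sum(resid^2) / (n - 3)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  if (is.null(study_id)) {
    study_id <- if ("study" %in% names(table)) as.character(table$study[1]) else "study1"
  }
  out <- data.frame(study_id = study_id, cohort_id = cohort_id,
                    beta1 = coefs[2], se = se, n = n,
                    mean_age = mean(table$age), sd_age = stats::sd(table$age),
                    occasion_age = NA_real_)
  if (sigma2 < .Machine$double.eps * max(mean(table$y)^2, 1)) {
    attr(out, "zero_residual") <- TRUE
  }
  out
}

#' Reduce every study in a collection
#'
#' Applies [fit_study()] to each study of a [simulate_collection()] result
#' (or a plain list of study tables).  Degenerate studies (e.g. a SNP that
#' happens to be monomorphic in sample) are dropped deterministically with
#' a warning naming them, never imputed.
#'
#' @param collection a `study_collection` or list of study data frames.
#' @return Study-summary data frame, one row per retained study.
#' @export
fit_studies <- function(collection) {
  studies <- if (inherits(collection, "study_collection")) collection$studies else collection
  rows <- vector("list", length(studies))
  dropped <- character(0)
  for (j in seq_along(studies)) {
    rows[[j]] <- tryCatch(fit_study(studies[[j]]),
      agemeta_degenerate_study_error = function(e) {
        dropped <<- c(dropped, as.character(j))
        NULL
      })
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d degenerate stud%s: %s",
                    length(dropped), if (length(dropped) == 1) "y" else "ies",
                    paste(dropped, collapse = ", ")))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_agemeta("all studies were degenerate", subclass = "degenerate_study")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summary_cols <- c("study_id", "cohort_id", "beta1", "se", "n",
                  "mean_age", "sd_age", "occasion_age")

#' Read / write study-summary tables
#'
#' Plain-CSV interchange with the fixed column order `study_id, cohort_id,
#' beta1, se, n, mean_age, sd_age, occasion_age`, so files produced by
#' third parties can be consumed directly.  Extra columns are preserved on
#' read; missing optional columns (`cohort_id`, `occasion_age`) are filled
#' with `NA`.
#'
#' @param path CSV file path.
#' @param summaries study-summary data frame.
#' @return `read_study_summaries()` returns the data frame.
#' @export
read_study_summaries <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_agemeta(paste0("cannot read '", path, "': ",
                                       conditionMessage(e)), "config")
                 })
  required <- c("beta1", "se", "n", "mean_age")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_agemeta(paste0("summary file is missing column(s): ",
                        paste(miss, collapse = ", ")), "config")
  }
  for (col in setdiff(summary_cols, names(df))) {
    df[[col]] <- if (col %in% c("study_id", "cohort_id")) NA_character_ else NA_real_
  }
  if (all(is.na(df$study_id))) df$study_id <- paste0("study", seq_len(nrow(df)))
  if (all(is.na(df$sd_age))) df$sd_age <- 0
  if (any(df$se <= 0, na.rm = TRUE)) {
    stop_agemeta("all standard errors must be positive", "config")
  }
  df[, c(summary_cols, setdiff(names(df), summary_cols))]
}

#' @rdname read_study_summaries
#' @export
write_study_summaries <- function(summaries, path) {
  extra <- setdiff(names(summaries), summary_cols)
  for (col in setdiff(summary_cols, names(summaries))) {
    summaries[[col]] <- NA
  }
  utils::write.csv(summaries[, c(summary_cols, extra)], path, row.names = FALSE)
  invisible(path)
}
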