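#' Predictive-validity regression
#'
#' Ordinary-least-squares fit of an outcome on the participant's mean iRT
#' (plus intercept; plus age when requested), with two-sided coefficient
#' tests. Rows with a missing outcome or predictor are deleted listwise and
#' the analyzed n is reported. p values are unadjusted; when several
#' outcomes are fitted, multiplicity is the reader's to weigh.
#'
#' @param records Data frame with one row per participant, containing
#'   `mean_irt_s`, `age_years` (when used) and the outcome column.
#' @param outcome Name of the outcome column.
#' @param include_age Add `age_years` as a covariate.
#' @param min_n Minimum complete cases required (default 10).
#' @return A `cpcst_regression` list: `outcome`, `coefficients` (estimate,
#'   SE, t, p per term), `f_statistic`, `df1`, `df2`, `r_squared`, `n`,
#'   `covariates`, and the underlying `lm` fit.
#' @section Errors: a rank-deficient design (e.g. constant predictor)
#'   raises a singular-design error.
#' @export
fit_validity_model <- function(records, outcome, include_age = FALSE,
                               min_n = 10L) {
  stopifnot(is.data.frame(records), outcome %in% names(records),
            "mean_irt_s" %in% names(records))
  preds <- c("mean_irt_s", if (include_age) "age_years")
  stopifnot(all(preds %in% names(records)))
  dat <- records[, c(outcome, preds)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_n)
    stop("insufficient complete records for regression: ", nrow(dat),
         " < ", min_n)
  if (any(vapply(dat[preds], function(v) sd(v) == 0, logical(1))))
    stop("singular design: a predictor is constant")
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                  paste(preds, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (fit$rank < length(preds) + 1L)
    stop("singular design: predictors are collinear")
  sm <- summary(fit)
  structure(list(outcome = outcome,
                 coefficients = as.data.frame(sm$coefficients),
                 f_statistic = unname(sm$fstatistic[1]),
                 df1 = unname(sm$fstatistic[2]),
                 df2 = unname(sm$fstatistic[3]),
                 r_squared = sm$r.squared,
                 n = nrow(dat),
                 covariates = if (include_age) "irt+age" else "irt",
                 fit = fit),
            class = "cpcst_regression")
}

#' @export
print.cpcst_regression <- function(x, ...) {
  cat(sprintf("validity model: %s ~ %s (n = %d)\n", x$outcome,
              x$covariates, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("  F(%d, %d) = %.3f, R^2 = %.4f\n", x$df1, x$df2,
              x$f_statistic, x$r_squared))
  invisible(x)
}

#' Confidence intervals for a validity model
#'
#' @param object A `cpcst_regression`.
#' @param parm,level,... Passed to [stats::confint()].
#' @export
confint.cpcst_regression <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$fit, parm = parm, level = level, ...)
}

#' Simulate opaque outcome measures for a synthetic cohort
#'
#' Ability/achievement/fitness-style outcomes are out of software scope as
#' instruments; they are emulated as declared linear-plus-noise functions
#' of the cohort's latent traits: the attentional lapse rate (which also
#' raises measured iRT) and age, plus Gaussian noise. This makes a
#' positive iRT-outcome association hold by construction through the
#' shared latent trait rather than by regressing a function of iRT on iRT.
#'
#' @param manifest Cohort manifest from [cohort_manifest()] (needs
#'   `lapse_rate_hz` and `age_years`).
#' @param intercept,b_lapse,b_age Generating coefficients.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return Numeric outcome vector aligned with the manifest rows.
#' @export
simulate_outcome <- function(manifest, intercept = 100, b_lapse = -120,
                             b_age = -0.2, noise_sd = 6, seed = 1L) {
  stopifnot(all(c("lapse_rate_hz", "age_years") %in% names(manifest)))
  set.seed(seed)
  intercept + b_lapse * manifest$lapse_rate_hz + b_age * manifest$age_years +
    rnorm(nrow(manifest), 0, noise_sd)
}

#' Write a regression result as a structured (JSON) report
#'
#' @param model A `cpcst_regression`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regression_report <- function(model, path) {
  stopifnot(inherits(model, "cpcst_regression"))
  co <- model$coefficients
  jsonlite::write_json(
    list(outcome = model$outcome, covariates = model$covariates,
         n = model$n,
         terms = lapply(rownames(co), function(tm) list(
           term = tm, estimate = co[tm, 1], se = co[tm, 2],
           t = co[tm, 3], p = co[tm, 4])),
         f_statistic = model$f_statistic, df1 = model$df1, df2 = model$df2,
         r_squared = model$r_squared,
         note = "p values are unadjusted for multiplicity"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @importFrom stats complete.cases
NULL
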