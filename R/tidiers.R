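# broom-style tidiers for the pipeline's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_line_models One row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`; Poisson/log and log-weight models
#'   also report `exp_estimate` (proportionate response relative to
#'   integrated females).
#' @param x A `hatch_line_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hatch_line_fit <- function(x, ...) {
  co <- summary(x)$coefficients
  out <- tibble::tibble(
    trait = x$trait, term = rownames(co), estimate = co[, 1],
    std_error = co[, 2], statistic = co[, 3], p_value = co[, 4])
  if (x$trait %in% c("age", "weight_kg")) {
    out$exp_estimate <- ifelse(out$term == "log(length_cm)", NA_real_,
                               exp(out$estimate))
  }
  out
}

#' @describeIn fit_line_models One-row model summary: trait, family, n, and
#'   fit statistics.
#' @exportS3Method generics::glance
glance.hatch_line_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, family = x$family_label,
                 n = length(x$residuals),
                 df_residual = x$df.residual,
                 deviance = if (inherits(x, "glm")) x$deviance else
                   sum(resid(x)^2),
                 aic = stats::AIC(x))
}

#' @describeIn backward_purge Predictor loci as a tibble (`trait`, `locus`,
#'   `rank` by removal order, retained loci first).
#' @param x A `hatch_predictors`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hatch_predictors <- function(x, ...) {
  tibble::tibble(trait = x$trait, locus = x$loci)
}

#' @describeIn backward_purge One-row summary (`trait`, `n_loci`,
#'   `metric_kind`, `metric`).
#' @exportS3Method generics::glance
glance.hatch_predictors <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_loci = length(x$loci),
                 metric_kind = x$metric_kind, metric = x$metric)
}

#' @describeIn qc_pipeline Long bookkeeping table of the cascade.
#' @param x A `hatch_qc`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hatch_qc <- function(x, ...) {
  tidyr::pivot_longer(x$report, dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @describeIn qc_pipeline The one-row cascade report.
#' @exportS3Method generics::glance
glance.hatch_qc <- function(x, ...) x$report
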