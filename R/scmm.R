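#' Sequential conditional mean model for the one-year treatment effect
#'
#' Pooled regression of the visit-`t` outcome on the current (continuous) or
#' previous-year (count) treatment, the treatment one further visit back, the
#' previous outcome values and baseline covariates, optionally augmented with
#' the fitted propensity score (a doubly robust specification) and a
#' treatment-by-modifier interaction. Only the one-year effect is returned:
#' with time-dependent confounding a conditional regression identifies short-
#' term effects but not longer-term ones, which are partly mediated by future
#' treatment.
#'
#' Model-based standard errors are the default (`se` column); under a
#' correctly specified model with a well-estimated propensity score they
#' approximate the sampling standard error. Cluster-robust SEs are also
#' stored (`se_model` holds the classical value for comparison).
#'
#' @param panel A `panel_df`.
#' @param family `"linear"` or `"zinb"`.
#' @param adjust_propensity Include the propensity score as a covariate.
#' @param propensity Optional [fit_propensity()] result to reuse; fitted
#'   internally when needed.
#' @param interaction If `TRUE`, adds a treatment-by-modifier interaction
#'   (modifier: previous continuous outcome for `linear`, previous count for
#'   `zinb`) and reports its per-unit slope.
#' @param warm,warm_key Optional environment (and key) holding warm-start
#'   values for repeated zero-inflated fits across simulation replicates.
#' @return Effect table with the lag-1 row(s) (plus interaction rows when
#'   requested). The `se` column holds the model-based SE, `se_model` the
#'   cluster-robust SE.
#' @export
fit_scmm <- function(panel, family = c("linear", "zinb"),
                     adjust_propensity = TRUE, propensity = NULL,
                     interaction = FALSE, warm = NULL, warm_key = "scmm") {
  family <- match.arg(family)
  av <- analysis_view(panel)
  if (adjust_propensity) {
    if (is.null(propensity)) propensity <- fit_propensity(panel)
    pt <- rep(NA_real_, nrow(av))
    m <- match(paste(propensity$data$id, propensity$data$visit),
               paste(av$id, av$visit))
    pt[m] <- stats::predict(propensity$denominator$fit,
                            newdata = propensity$data, type = "response")
    av$pt <- pt
    # the count model's treatment is X_{s-1}: use that visit's propensity
    av$pt_lag1 <- lag_within(av$pt, av$id, 1)
  }

  if (family == "linear") {
    rows <- av$visit >= 1 & av$observed == 1
    dat <- av[rows, , drop = FALSE]
    dat$z1 <- dat$x
    dat$mod <- dat$y_cont_lag1
    terms <- c("z1", "x_lag1", "y_cont_lag1", "y_count", "age",
               "factor(visit)")
    if (adjust_propensity) terms <- c(terms, "pt")
    if (interaction) terms <- c(terms, "z1:mod")
    f <- stats::as.formula(paste("y_cont ~", paste(terms, collapse = " + ")))
    fit <- fit_glm(f, dat, family = "linear", cluster = dat$id)
    if (!fit$converged) {
      return(failed_effects("scmm", "linear", "mean", 1,
                            terms = if (interaction)
                              c("treat", "interaction") else "treat"))
    }
    out <- extract_lags("scmm", "linear", "mean", coef(fit), fit$vcov_model,
                        fit$vcov_sandwich, 1, interaction)
    return(out)
  }

  rows <- av$visit >= 2 & av$observed == 1
  dat <- av[rows, , drop = FALSE]
  dat$z1 <- dat$x_lag1
  dat$mod <- dat$y_count_lag1
  terms <- c("z1", "x_lag2", "y_count_lag1", "y_cont_lag1", "age",
             "factor(visit)")
  if (adjust_propensity) terms <- c(terms, "pt_lag1")
  if (interaction) terms <- c(terms, "z1:mod")
  f <- stats::as.formula(paste("y_count ~", paste(terms, collapse = " + ")))
  zf <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  fit <- fit_zinb(f, zf, dat, cluster = dat$id,
                  start = warm_get(warm, warm_key))
  warm_set(warm, warm_key, fit)
  if (!fit$converged) {
    return(failed_effects("scmm", "count", c("zero", "rate"), 1,
                          terms = if (interaction)
                            c("treat", "interaction") else "treat"))
  }
  out <- zinb_effect_rows("scmm", fit, 1, interaction)
  # swap: model-based SE is the default for SCMM
  tmp <- out$se; out$se <- out$se_model; out$se_model <- tmp
  out
}
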