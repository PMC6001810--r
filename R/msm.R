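#' Inverse-probability-weighted marginal structural model
#'
#' Fits the final MSM on the observed data reweighted by stabilized treatment
#' weights (optionally multiplied by censoring weights): a pooled regression
#' of the visit-`s` outcome on separate terms for treatment at each lag, with
#' per-visit intercepts and no time-varying covariates. For the continuous
#' outcome lag 1 is the current visit's treatment (`X_s` on `F_s`); for the
#' count outcome lag 1 is the previous visit's treatment (`X_{s-1}` on `V_s`),
#' so the count horizon is at most `T - 1`. Robust (person-clustered sandwich)
#' standard errors are reported.
#'
#' @param panel A `panel_df`.
#' @param weights A `weight_set` from [stabilized_weights()] (possibly
#'   truncated).
#' @param family `"linear"` or `"zinb"`.
#' @param horizon Number of lag terms.
#' @param censoring Optional `weight_set` from [censoring_weights()]; combined
#'   multiplicatively with the treatment weights.
#' @param visits Optional subset of outcome visits to pool over (default all
#'   visits 1..T).
#' @param warm,warm_key Optional environment (and key) holding warm-start
#'   values for repeated zero-inflated fits across simulation replicates.
#' @return Effect table (one row per part/lag) with robust SEs; on
#'   non-convergence the rows are flagged and estimates are `NA`.
#' @export
fit_ipw_msm <- function(panel, weights, family = c("linear", "zinb"),
                        horizon = NULL, censoring = NULL, visits = NULL,
                        warm = NULL, warm_key = "ipw") {
  family <- match.arg(family)
  tt <- attr(panel, "n_visits")
  if (is.null(horizon)) horizon <- if (family == "linear") tt else tt - 1
  offset <- if (family == "linear") 1 else 0
  if (horizon + (1 - offset) > tt) {
    stop("horizon too large for this panel/family", call. = FALSE)
  }
  av <- analysis_view(panel)
  av <- add_lag_design(av, horizon, offset)
  # treatment weight indexed at the last treatment visit in the design
  wvisit <- av$visit - (1 - offset)
  m <- match(paste(av$id, pmax(wvisit, 0)), paste(weights$id, weights$visit))
  av$w <- ifelse(wvisit < 0, 1, weights$sw[m])
  if (!is.null(censoring)) {
    mc <- match(paste(av$id, av$visit), paste(censoring$id, censoring$visit))
    av$w <- av$w * censoring$cw[mc]
  }
  rows <- av$visit >= 1 & av$observed == 1 & !is.na(av$w)
  if (!is.null(visits)) rows <- rows & av$visit %in% visits
  dat <- av[rows, , drop = FALSE]
  lag_terms <- paste0("z", seq_len(horizon), collapse = " + ")
  visit_term <- if (length(unique(dat$visit)) > 1) " + factor(visit)" else ""
  if (family == "linear") {
    f <- stats::as.formula(paste("y_cont ~", lag_terms, visit_term))
    fit <- fit_glm(f, dat, family = "linear", weights = dat$w,
                   cluster = dat$id)
    if (!fit$converged) return(failed_effects("ipw", "linear", "mean", horizon))
    return(extract_lags("ipw", "linear", "mean", coef(fit),
                        fit$vcov_sandwich, fit$vcov_model, horizon))
  }
  f <- stats::as.formula(paste("y_count ~", lag_terms, visit_term))
  zf <- stats::as.formula(paste("~", lag_terms, visit_term))
  fit <- fit_zinb(f, zf, dat, weights = dat$w, cluster = dat$id,
                  start = warm_get(warm, warm_key))
  warm_set(warm, warm_key, fit)
  if (!fit$converged) return(failed_effects("ipw", "count", c("zero", "rate"),
                                            horizon))
  zinb_effect_rows("ipw", fit, horizon)
}

# shared extraction for zinb fits: zero part reported on the log-odds scale
# with the sign convention of an effect on the odds of a zero count
#' @keywords internal
zinb_effect_rows <- function(method, fit, horizon, interaction = FALSE) {
  par <- fit$par
  vc <- fit$vcov_sandwich
  vcm <- fit$vcov_model
  zero_cf <- par[fit$idx$zero]
  names(zero_cf) <- sub("^zero_", "", names(zero_cf))
  zero_vc <- if (!is.null(vc)) {
    v <- vc[fit$idx$zero, fit$idx$zero, drop = FALSE]
    dimnames(v) <- list(names(zero_cf), names(zero_cf)); v
  }
  zero_vcm <- if (!is.null(vcm)) {
    v <- vcm[fit$idx$zero, fit$idx$zero, drop = FALSE]
    dimnames(v) <- list(names(zero_cf), names(zero_cf)); v
  }
  count_cf <- par[fit$idx$count]
  names(count_cf) <- names(fit$coefficients)
  count_vc <- if (!is.null(vc)) {
    v <- vc[fit$idx$count, fit$idx$count, drop = FALSE]
    dimnames(v) <- list(names(count_cf), names(count_cf)); v
  }
  count_vcm <- if (!is.null(vcm)) {
    v <- vcm[fit$idx$count, fit$idx$count, drop = FALSE]
    dimnames(v) <- list(names(count_cf), names(count_cf)); v
  }
  rbind(extract_lags(method, "count", "zero", zero_cf, zero_vc, zero_vcm,
                     horizon, interaction),
        extract_lags(method, "count", "rate", count_cf, count_vc, count_vcm,
                     horizon, interaction))
}
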