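#' Fit pooled propensity-score models
#'
#' Fits the denominator (full-history) and numerator (treatment history and
#' baseline covariates only) logistic models for the probability of receiving
#' treatment at each visit, pooled over visits 1..T on uncensored rows. The
#' numerator may only contain treatment-history lags, baseline covariates and
#' visit terms: a numerator conditioning on time-varying covariates would
#' define conditional rather than marginal stabilized weights and is rejected.
#'
#' @param panel A `panel_df`.
#' @param denominator Formula for the denominator model; default adjusts for
#'   the previous treatment, previous lung function, current count and age.
#' @param numerator Formula for the numerator model; default conditions on the
#'   previous treatment and visit only (marginal estimand).
#' @return List with elements `denominator`, `numerator` ([fitted_model]s) and
#'   `data` (the analysis rows used, visits >= 1, observed only).
#' @export
fit_propensity <- function(panel, denominator = NULL, numerator = NULL) {
  av <- analysis_view(panel)
  rows <- av$visit >= 1 & av$observed == 1
  dat <- av[rows, , drop = FALSE]
  tt <- attr(panel, "n_visits")
  # defaults adapt to the panel: visit intercepts and the treatment-history
  # lag only exist with more than one post-baseline visit
  if (is.null(denominator)) {
    denominator <- stats::as.formula(paste(
      "x ~", paste(c(if (tt >= 2) "x_lag1", "y_cont_lag1", "log1p(y_count)",
                     "age", if (tt >= 2) "factor(visit)"), collapse = " + ")))
  }
  if (is.null(numerator)) {
    numerator <- stats::as.formula(paste(
      "x ~", paste(c(if (tt >= 2) c("x_lag1", "factor(visit)") else "1"),
                   collapse = " + ")))
  }
  check_numerator_terms(numerator, baseline = attr(panel, "baseline"))
  den <- fit_glm(denominator, dat, family = "logistic", cluster = dat$id)
  num <- fit_glm(numerator, dat, family = "logistic", cluster = dat$id)
  list(denominator = den, numerator = num, data = dat)
}

#' @keywords internal
check_numerator_terms <- function(numerator, baseline) {
  labs <- attr(stats::terms(numerator), "term.labels")
  vars <- unique(unlist(lapply(labs, function(l) all.vars(stats::as.formula(
    paste("~", l))))))
  allowed <- c(paste0("x_lag", 1:10), baseline, "visit")
  bad <- setdiff(vars, allowed)
  if (length(bad) > 0) {
    stop("numerator may only condition on treatment history, baseline ",
         "covariates and visit; offending terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Per person-visit, the weight is the running product over visits `i = 1..t`
#' of the ratio of the numerator to the denominator fitted probability of the
#' treatment actually received (the fitted probability for treated rows, one
#' minus it for untreated rows).
#'
#' @param panel A `panel_df`.
#' @param propensity Result of [fit_propensity()].
#' @return A `weight_set` data frame with columns `id`, `visit`, `p`
#'   (denominator propensity of the received treatment level), `fac` (per-visit
#'   numerator/denominator ratio) and `sw` (cumulative stabilized weight);
#'   visit-0 rows carry `fac = sw = 1`.
#' @export
stabilized_weights <- function(panel, propensity) {
  dat <- propensity$data
  p_den <- received_prob(propensity$denominator, dat)
  p_num <- received_prob(propensity$numerator, dat)
  bad <- p_den <= .Machine$double.eps | p_den >= 1 - .Machine$double.eps
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("positivity violation: fitted probability %g for ",
                        "person %s at visit %d"),
                 p_den[i], dat$id[i], dat$visit[i]), call. = FALSE)
  }
  build_weight_set(panel, dat, p_den, p_num, col = "sw")
}

#' @keywords internal
received_prob <- function(model, dat) {
  p1 <- stats::predict(model$fit, newdata = dat, type = "response")
  ifelse(dat$x == 1, p1, 1 - p1)
}

#' @keywords internal
build_weight_set <- function(panel, dat, p_den, p_num, col) {
  fac <- p_num / p_den
  ws <- data.frame(id = panel$id, visit = panel$visit, p = NA_real_,
                   fac = NA_real_)
  ws$fac[panel$visit == 0] <- 1
  key_all <- paste(ws$id, ws$visit)
  key_dat <- paste(dat$id, dat$visit)
  m <- match(key_dat, key_all)
  ws$fac[m] <- fac
  ws$p[m] <- p_den
  cum <- rep(NA_real_, nrow(ws))
  ok <- !is.na(ws$fac)
  # cumulative product within person over the observed prefix
  cum[ok] <- stats::ave(ws$fac[ok], ws$id[ok], FUN = cumprod)
  ws[[col]] <- cum
  structure(ws, truncation = NULL, class = c("weight_set", "data.frame"))
}

#' Stabilized inverse-probability-of-censoring weights
#'
#' Models the probability of remaining under observation at each visit given
#' the previous visit's variables, for persons observed at the previous visit.
#' The numerator is marginal (visit terms only); the cumulative stabilized
#' weight at visit `t` multiplies the per-visit ratios for `i = 1..t` and is
#' defined only for rows still observed.
#'
#' @param panel A `panel_df`.
#' @param denominator Formula for the hazard-of-remaining model; responses are
#'   created internally as `obs_now`.
#' @param numerator Marginal numerator formula.
#' @return A `weight_set` with columns `id`, `visit`, `p`, `fac`, `cw`. If the
#'   panel is fully observed all weights are exactly 1.
#' @export
censoring_weights <- function(panel, denominator = NULL, numerator = NULL) {
  tt <- attr(panel, "n_visits")
  if (is.null(denominator)) {
    denominator <- stats::as.formula(paste(
      "obs_now ~", paste(c("x_lag1", "y_cont_lag1", "log1p(y_count_lag1)",
                           "age", if (tt >= 2) "factor(visit)"),
                         collapse = " + ")))
  }
  if (is.null(numerator)) {
    numerator <- stats::as.formula(
      if (tt >= 2) "obs_now ~ factor(visit)" else "obs_now ~ 1")
  }
  av <- analysis_view(panel)
  if (all(panel$observed == 1)) {
    ws <- data.frame(id = panel$id, visit = panel$visit, p = 1, fac = 1,
                     cw = 1)
    return(structure(ws, truncation = NULL,
                     class = c("weight_set", "data.frame")))
  }
  obs_prev <- lag_within(panel$observed, panel$id, 1)
  at_risk <- av$visit >= 1 & obs_prev == 1
  dat <- av[at_risk, , drop = FALSE]
  dat$obs_now <- dat$observed
  # lagged covariates come from the last observed visit
  den <- fit_glm(denominator, dat, family = "logistic", cluster = dat$id)
  num <- fit_glm(numerator, dat, family = "logistic", cluster = dat$id)
  p_den <- stats::predict(den$fit, newdata = dat, type = "response")
  p_num <- stats::predict(num$fit, newdata = dat, type = "response")
  keep <- dat$obs_now == 1  # weights only for rows that remain observed
  ws <- build_weight_set(panel, dat[keep, , drop = FALSE], p_den[keep],
                         p_num[keep], col = "cw")
  ws
}

#' Origin-indexed (history-adjusted) weights
#'
#' The weight for treatment at origin visit `t` acting on the outcome at visit
#' `s >= t` multiplies the per-visit stabilized ratios for visits `t..s` only.
#' With origin 1 this reproduces the ordinary stabilized weight. Computed from
#' a [stabilized_weights()] set as the ratio of cumulative products.
#'
#' @param weights A `weight_set` from [stabilized_weights()].
#' @param origin Origin visit `t` (1 <= t <= T).
#' @return Data frame `id`, `visit` (the outcome visit `s >= origin`), `w`.
#' @export
ha_weights <- function(weights, origin) {
  tt <- max(weights$visit)
  if (origin < 1 || origin > tt) {
    stop("origin must lie in 1..", tt, call. = FALSE)
  }
  base <- weights[weights$visit == origin - 1, c("id", "sw")]
  names(base)[2] <- "sw_base"
  out <- merge(weights[weights$visit >= origin, c("id", "visit", "sw")],
               base, by = "id")
  out$w <- out$sw / out$sw_base
  out[order(out$id, out$visit), c("id", "visit", "w")]
}

#' Truncate weights at empirical percentiles
#'
#' Weights below the `lo` percentile or above the `hi` percentile (computed
#' from the pooled person-visit weights, linear-interpolation quantiles) are
#' set to the percentile values. Truncating twice at the same bounds is a
#' no-op, and `lo = 0, hi = 100` leaves the weights unchanged.
#'
#' @param weights A `weight_set`.
#' @param lo,hi Percentile bounds in `[0, 100]`.
#' @param column Which weight column to truncate (default the treatment
#'   weight `sw`).
#' @return The `weight_set` with the column truncated and the bounds recorded
#'   in the `truncation` attribute.
#' @export
truncate_weights <- function(weights, lo = 1, hi = 99, column = "sw") {
  if (!(lo >= 0 && lo < hi && hi <= 100)) {
    stop("need 0 <= lo < hi <= 100", call. = FALSE)
  }
  prior <- attr(weights, "truncation")
  if (!is.null(prior) && prior[["lo"]] == lo && prior[["hi"]] == hi) {
    return(weights)  # re-applying the recorded truncation is a no-op
  }
  w <- weights[[column]]
  q <- stats::quantile(w, probs = c(lo, hi) / 100, na.rm = TRUE, names = FALSE)
  weights[[column]] <- pmin(pmax(w, q[1]), q[2])
  attr(weights, "truncation") <- c(lo = lo, hi = hi, q_lo = q[1], q_hi = q[2])
  weights
}
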