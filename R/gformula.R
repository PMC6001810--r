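#' Nuisance models for the parametric g-computation formula
#'
#' Fits the one-year ("short-term") models for both time-varying variables on
#' the observed person-visits: a linear model for the continuous outcome given
#' the current treatment, previous treatment, previous continuous outcome,
#' current count and baseline covariates (its residual RMSE drives the
#' simulation noise), and a zero-inflated negative binomial model for the
#' count given the previous visit's variables and treatment.
#'
#' @param panel A `panel_df`.
#' @param f_formula,v_formula,v_zero_formula Optional overrides of the default
#'   model formulas.
#' @param warm,warm_key Optional environment (and key) holding warm-start
#'   values for repeated zero-inflated fits across simulation replicates.
#' @return List with elements `f_model` (linear [fitted_model] with RMSE) and
#'   `v_model` (zinb [fitted_model]).
#' @export
fit_nuisance_models <- function(panel,
                                f_formula = y_cont ~ x + x_lag1 +
                                  y_cont_lag1 + y_count + age +
                                  x:y_cont_lag1,
                                v_formula = y_count ~ x_lag1 + y_cont_lag1 +
                                  y_count_lag1 + age +
                                  x_lag1:y_count_lag1,
                                v_zero_formula = ~ x_lag1 + y_cont_lag1 +
                                  y_count_lag1 + age +
                                  x_lag1:y_count_lag1,
                                warm = NULL, warm_key = "gf_nuisance") {
  av <- analysis_view(panel)
  dat <- av[av$visit >= 1 & av$observed == 1, , drop = FALSE]
  f_model <- fit_glm(f_formula, dat, family = "linear", cluster = dat$id)
  v_model <- fit_zinb(v_formula, v_zero_formula, dat, cluster = dat$id,
                      start = warm_get(warm, warm_key), se = FALSE)
  warm_set(warm, warm_key, v_model)
  if (!f_model$converged || !v_model$converged) {
    stop("g-formula nuisance model failed to converge: ",
         paste(c(if (!f_model$converged) "continuous",
                 if (!v_model$converged) "count"), collapse = ", "),
         call. = FALSE)
  }
  list(f_model = f_model, v_model = v_model)
}

#' Saturated deterministic treatment regimes
#'
#' @param horizon Number of treatment visits covered by the regimes.
#' @return A `regime_set`: list of 0/1 vectors of length `horizon`, one per
#'   treatment combination (`2^horizon` regimes).
#' @export
make_regimes <- function(horizon) {
  grid <- expand.grid(rep(list(0:1), horizon))[, rev(seq_len(horizon)),
                                               drop = FALSE]
  regimes <- lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  structure(regimes, class = "regime_set", horizon = horizon)
}

#' Simulate counterfactual trajectories under fixed regimes
#'
#' Starting from each person's observed visit-0 values, sequentially simulates
#' the count (zero-inflated negative binomial draw) and then the continuous
#' outcome (fitted mean plus Normal noise with the model RMSE) at each visit,
#' feeding simulated values forward, with treatment fixed by the regime.
#'
#' @param models Result of [fit_nuisance_models()].
#' @param baseline Data frame of visit-0 rows (`id`, `y_cont`, `y_count`, and
#'   baseline covariates).
#' @param regimes A [make_regimes()] set (regime length = number of simulated
#'   visits).
#' @param n_mc Monte-Carlo replicates per person per regime.
#' @param seed Integer seed.
#' @return A `counterfactual_panel` data frame: one row per person x regime x
#'   visit x replicate with simulated `y_cont`, `y_count`, the regime's
#'   treatment, and a regime label.
#' @export
simulate_regimes <- function(models, baseline, regimes, n_mc = 1, seed = 1) {
  stopifnot(n_mc >= 1)
  set.seed(seed)
  tt <- attr(regimes, "horizon")
  if (any(lengths(regimes) != tt)) {
    stop("regime length must equal the simulation horizon", call. = FALSE)
  }
  n_base <- nrow(baseline) * n_mc
  R <- length(regimes)
  reg_mat <- do.call(rbind, regimes)
  # state stacked over person-replicate x regime (regime varies fastest)
  id <- rep(rep(baseline$id, n_mc), each = R)
  mc <- rep(rep(seq_len(n_mc), each = nrow(baseline)), each = R)
  regime_ix <- rep(seq_len(R), n_base)
  age <- rep(rep(baseline$age, n_mc), each = R)
  f_prev <- rep(rep(baseline$y_cont, n_mc), each = R)
  v_prev <- rep(rep(baseline$y_count, n_mc), each = R)
  x_prev <- rep(0L, n_base * R)
  xs <- vector("list", tt); fs <- vector("list", tt); vs <- vector("list", tt)
  for (t in seq_len(tt)) {
    x_t <- reg_mat[regime_ix, t]
    nd <- data.frame(x = x_t, x_lag1 = x_prev, y_cont_lag1 = f_prev,
                     y_count_lag1 = v_prev, age = age, visit = t)
    v_t <- sample_outcome(models$v_model, nd)
    nd$y_count <- v_t
    mu_f <- stats::predict(models$f_model$fit, newdata = nd)
    f_t <- mu_f + stats::rnorm(length(x_t), 0, models$f_model$rmse)
    xs[[t]] <- x_t; fs[[t]] <- unname(f_t); vs[[t]] <- v_t
    f_prev <- f_t; v_prev <- v_t; x_prev <- x_t
  }
  nb <- n_base * R
  cf <- data.frame(id = rep(id, tt), mc = rep(mc, tt),
                   regime = rep(regime_ix, tt),
                   visit = rep(seq_len(tt), each = nb),
                   x = unlist(xs), y_cont = unlist(fs), y_count = unlist(vs))
  attr(cf, "regimes") <- regimes
  class(cf) <- c("counterfactual_panel", "data.frame")
  cf
}

#' Marginal structural model on counterfactual trajectories
#'
#' Contrasts the simulated regimes with an unweighted final MSM with separate
#' lag terms and per-visit intercepts, mirroring the weighted MSM of the IPW
#' route. For the continuous outcome the fit uses the regime-by-visit means
#' (weighted by cell size), which is numerically identical to the row-level
#' least-squares fit because the design is constant within cells. The count
#' fit is a zero-inflated negative binomial on the simulated draws, restricted
#' to regimes that do not treat at the final visit (treatment at `s` cannot
#' affect `V_s`).
#'
#' @param cf A `counterfactual_panel`.
#' @param family `"linear"` or `"zinb"`.
#' @param horizon Number of lag terms.
#' @param warm,warm_key Optional environment (and key) holding warm-start
#'   values for repeated zero-inflated fits across simulation replicates.
#' @return Effect table; SEs are `NA` (use the cluster bootstrap: the sampling
#'   uncertainty of g-computation lives in the fitted nuisance models, not in
#'   the final deterministic contrast).
#' @export
gformula_effects <- function(cf, family = c("linear", "zinb"), horizon,
                             warm = NULL, warm_key = "gformula") {
  family <- match.arg(family)
  regimes <- attr(cf, "regimes")
  reg_mat <- do.call(rbind, regimes)  # regime x visit treatment matrix
  offset <- if (family == "linear") 1 else 0
  lag_col <- function(d, k) {
    vis <- d$visit - k + offset
    val <- reg_mat[cbind(d$regime, pmax(vis, 1))]
    ifelse(vis < 1, 0, val)
  }
  if (family == "linear") {
    key <- paste(cf$regime, cf$visit)
    sums <- rowsum(cbind(y = cf$y_cont, nn = 1), key)
    parts <- do.call(rbind, strsplit(rownames(sums), " ", fixed = TRUE))
    agg <- data.frame(regime = as.integer(parts[, 1]),
                      visit = as.integer(parts[, 2]),
                      y_cont = sums[, "y"] / sums[, "nn"],
                      nn = sums[, "nn"])
    for (k in seq_len(horizon)) agg[[paste0("z", k)]] <- lag_col(agg, k)
    f <- stats::as.formula(paste("y_cont ~",
                                 paste0("z", seq_len(horizon),
                                        collapse = " + "),
                                 "+ factor(visit)"))
    fit <- stats::lm(f, data = agg, weights = agg$nn)
    cf_hat <- stats::coef(fit)
    rows <- lapply(seq_len(horizon), function(k)
      effect_row("gformula", "linear", "mean", k, "treat",
                 unname(cf_hat[paste0("z", k)]), NA_real_))
    return(do.call(rbind, rows))
  }
  tt <- max(cf$visit)
  keep_reg <- which(vapply(regimes, function(r) r[tt] == 0, logical(1)))
  d <- cf[cf$regime %in% keep_reg & cf$visit >= 2, , drop = FALSE]
  for (k in seq_len(horizon)) d[[paste0("z", k)]] <- lag_col(d, k)
  # the design is constant within (regime, visit) cells, so collapsing to
  # unique (cell, count) rows with frequency weights leaves the likelihood
  # unchanged and shrinks the fit by two orders of magnitude
  zcols <- paste0("z", seq_len(horizon))
  key <- do.call(paste, c(d[c(zcols, "visit")], list(d$y_count)))
  tab <- table(key)
  first <- d[match(names(tab), key), c(zcols, "visit", "y_count"),
             drop = FALSE]
  first$.freq <- as.numeric(tab)
  rhs <- paste(paste0("z", seq_len(horizon), collapse = " + "),
               "+ factor(visit)")
  f <- stats::as.formula(paste("y_count ~", rhs))
  zf <- stats::as.formula(paste("~", rhs))
  fit <- fit_zinb(f, zf, first, weights = first$.freq,
                  start = warm_get(warm, warm_key), se = FALSE)
  warm_set(warm, warm_key, fit)
  if (!fit$converged) {
    return(failed_effects("gformula", "count", c("zero", "rate"), horizon))
  }
  out <- zinb_effect_rows("gformula", fit, horizon)
  out$se <- NA_real_; out$se_model <- NA_real_
  out
}

#' One-call parametric g-computation
#'
#' Convenience wrapper: fits the nuisance models, simulates the saturated
#' regime set from the observed baseline rows, and contrasts the regimes with
#' the final MSM.
#'
#' @inheritParams fit_nuisance_models
#' @param family `"linear"` or `"zinb"`.
#' @param horizon Number of lag terms (default `T` for linear, `T - 1` for
#'   count).
#' @param n_mc Monte-Carlo replicates per person per regime.
#' @param seed Seed for the counterfactual simulation.
#' @param models Optional pre-fitted nuisance models.
#' @return Effect table.
#' @export
fit_gformula <- function(panel, family = c("linear", "zinb"), horizon = NULL,
                         n_mc = 1, seed = 1, models = NULL) {
  family <- match.arg(family)
  tt <- attr(panel, "n_visits")
  if (is.null(horizon)) horizon <- if (family == "linear") tt else tt - 1
  if (is.null(models)) models <- fit_nuisance_models(panel)
  baseline <- panel[panel$visit == 0 & panel$observed == 1,
                    c("id", "y_cont", "y_count", attr(panel, "baseline")),
                    drop = FALSE]
  regimes <- make_regimes(tt)
  cf <- simulate_regimes(models, baseline, regimes, n_mc = n_mc, seed = seed)
  gformula_effects(cf, family = family, horizon = horizon)
}
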