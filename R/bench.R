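#' Method specifications for the simulation harness
#'
#' Builds the estimator specification consumed by [run_study()] and
#' [bootstrap_se()]. Available estimators: `"ipw"`, `"hamsm"`, `"scmm"`,
#' `"gformula"`, `"gest"`.
#'
#' @param estimator Estimator name.
#' @param trunc Optional weight-truncation percentiles `c(lo, hi)` (IPW and
#'   HA-MSM only).
#' @param interaction Estimate treatment-by-modifier interactions (HA-MSM,
#'   SCMM, g-estimation only).
#' @param censoring Use inverse-probability-of-censoring weights when the
#'   panel is censored (IPW, HA-MSM, g-estimation; SCMM and g-computation do
#'   not use censoring weights).
#' @param label Column label in outputs; defaults to the estimator name with
#'   `_trunc` / `_int` / `_nocw` suffixes as applicable.
#' @return A `method_spec` list.
#' @export
method_spec <- function(estimator = c("ipw", "hamsm", "scmm", "gformula",
                                      "gest"),
                        trunc = NULL, interaction = FALSE, censoring = TRUE,
                        label = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(label)) {
    label <- paste0(estimator,
                    if (!is.null(trunc)) "_trunc" else "",
                    if (interaction) "_int" else "",
                    if (!censoring) "_nocw" else "")
  }
  structure(list(estimator = estimator, trunc = trunc,
                 interaction = interaction, censoring = censoring,
                 label = label), class = "method_spec")
}

#' @keywords internal
as_method_spec <- function(x) {
  if (inherits(x, "method_spec")) return(x)
  # character shorthand: "ipw", "ipw_trunc", "hamsm_int", "ipw_nocw", ...
  parts <- strsplit(x, "_")[[1]]
  method_spec(parts[1],
              trunc = if ("trunc" %in% parts) c(1, 99) else NULL,
              interaction = "int" %in% parts,
              censoring = !("nocw" %in% parts),
              label = x)
}

# run every requested method on one panel, sharing the propensity fit,
# treatment weights and censoring weights; `state` carries warm starts
#' @keywords internal
run_methods_once <- function(panel, specs, family, horizon, state = NULL) {
  tt <- attr(panel, "n_visits")
  fam_est <- if (family == "cont") "linear" else "zinb"
  fam_gest <- if (family == "cont") "linear" else "count_gamma"
  censored <- any(panel$observed == 0)
  prop <- fit_propensity(panel)
  ws <- stabilized_weights(panel, prop)
  cw <- if (censored) censoring_weights(panel) else NULL
  need_gf <- any(vapply(specs, function(s) s$estimator == "gformula",
                        logical(1)))
  gf_effects <- NULL
  if (need_gf) {
    models <- fit_nuisance_models(panel, warm = state)
    baseline <- panel[panel$visit == 0 & panel$observed == 1,
                      c("id", "y_cont", "y_count", attr(panel, "baseline"))]
    regimes <- make_regimes(tt)
    if (family == "count") {
      # the count MSM only uses regimes untreated at the final visit
      keep <- vapply(regimes, function(r) r[tt] == 0, logical(1))
      regimes <- structure(regimes[keep], class = "regime_set", horizon = tt)
    }
    cf <- simulate_regimes(models, baseline, regimes, n_mc = 1,
                           seed = sample.int(2^31 - 1, 1))
    gf_effects <- gformula_effects(cf, family = fam_est, horizon = horizon,
                                   warm = state)
  }
  out <- lapply(specs, function(sp) {
    res <- tryCatch(switch(
      sp$estimator,
      ipw = {
        w <- if (!is.null(sp$trunc))
          truncate_weights(ws, sp$trunc[1], sp$trunc[2]) else ws
        fit_ipw_msm(panel, w, family = fam_est, horizon = horizon,
                    censoring = if (sp$censoring) cw else NULL,
                    warm = state, warm_key = sp$label)
      },
      hamsm = fit_hamsm(panel, ws, family = fam_est, horizon = horizon,
                        interaction = sp$interaction, trunc = sp$trunc,
                        censoring = if (sp$censoring) cw else NULL,
                        warm = state, warm_key = sp$label),
      scmm = fit_scmm(panel, family = fam_est, adjust_propensity = TRUE,
                      propensity = prop, interaction = sp$interaction,
                      warm = state, warm_key = sp$label),
      gformula = gf_effects,
      gest = g_estimate(panel, family = fam_gest, horizon = horizon,
                        propensity = prop, interaction = sp$interaction,
                        censoring = if (sp$censoring) cw else NULL)),
      error = function(e) NULL)
    if (is.null(res)) {
      fam_lab <- if (family == "cont") "linear" else "count"
      parts <- if (family == "cont") "mean"
      else if (sp$estimator == "gest") "rate" else c("zero", "rate")
      res <- failed_effects(sp$estimator, fam_lab, parts,
                            if (sp$estimator == "scmm") 1 else horizon,
                            terms = if (sp$interaction)
                              c("treat", "interaction") else "treat")
    }
    res$method <- sp$label
    res
  })
  do.call(rbind, out)
}

#' Run a simulation study
#'
#' Simulates `n_reps` cohorts from a scenario configuration, runs each
#' requested estimator on every replicate, and summarizes bias (against the
#' simulated ground truth for the continuous outcome), empirical SE, MSE,
#' mean reported SE, Monte-Carlo SE of the bias, and convergence-failure
#' counts. Count-outcome estimates are summarized without a truth except
#' under a null configuration (truth 0): marginal and conditional count
#' effects are not comparable to one target because the count links are
#' non-collapsible.
#'
#' @param config A `scenario_config`.
#' @param methods List of [method_spec()]s or character shorthands.
#' @param n_reps Number of replicate datasets (>= 2).
#' @param n Persons per replicate.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param family `"cont"` or `"count"`.
#' @param horizon Largest lag (default `T` for continuous, `T - 1` for count).
#' @param truth_n Cohort size for the counterfactual truth computation.
#' @return A `simulation_study` list: `estimates` (per-replicate effect rows),
#'   `summary` (per method/part/lag/term metrics), `truth`, and the call
#'   parameters. Reproducible from `(config, methods, n_reps, n, seed)`.
#' @export
run_study <- function(config, methods, n_reps, n, seed, family = c("cont",
                                                                   "count"),
                      horizon = NULL, truth_n = 200000) {
  family <- match.arg(family)
  stopifnot(n_reps >= 2)
  specs <- lapply(methods, as_method_spec)
  tt <- config$n_visits
  if (is.null(horizon)) horizon <- if (family == "cont") tt else tt - 1

  truth <- if (family == "cont") {
    te <- true_effects(config, horizon, n = truth_n, seed = seed + 777)
    stats::setNames(te$truth, paste0("lag", te$lag))
  } else if (config$ground_truth$null) {
    stats::setNames(rep(0, horizon), paste0("lag", seq_len(horizon)))
  } else {
    stats::setNames(rep(NA_real_, horizon), paste0("lag", seq_len(horizon)))
  }
  int_truth <- if (family == "cont") config$ground_truth$interaction_cont
  else config$ground_truth$interaction_count

  reps <- vector("list", n_reps)
  state <- new.env(parent = emptyenv())  # zinb warm starts across replicates
  for (r in seq_len(n_reps)) {
    panel <- simulate_cohort(config, n, seed + r)
    set.seed(seed + r)  # governs the g-formula counterfactual draw
    est <- run_methods_once(panel, specs, family, horizon, state = state)
    est$rep <- r
    reps[[r]] <- est
  }
  estimates <- do.call(rbind, reps)
  summary <- summarize_study(estimates, truth, int_truth, n_reps)
  structure(list(estimates = estimates, summary = summary, truth = truth,
                 config = config$name, family = family, n_reps = n_reps,
                 n = n, seed = seed, horizon = horizon),
            class = "simulation_study")
}

#' @keywords internal
summarize_study <- function(estimates, truth, int_truth, n_reps) {
  key <- interaction(estimates$method, estimates$part, estimates$lag,
                     estimates$term, drop = TRUE)
  pieces <- lapply(split(estimates, key), function(d) {
    ok <- d$converged & !is.na(d$estimate)
    e <- d$estimate[ok]
    tr <- if (d$term[1] == "interaction") {
      if (length(int_truth) > 1) {
        unname(int_truth[[if (d$part[1] == "zero") "zero" else "rate"]])
      } else int_truth
    } else unname(truth[paste0("lag", d$lag[1])])
    r_used <- length(e)
    emp_se <- stats::sd(e)
    bias <- mean(e) - tr
    data.frame(method = d$method[1], part = d$part[1], lag = d$lag[1],
               term = d$term[1], truth = tr, mean_est = mean(e), bias = bias,
               emp_se = emp_se,
               mse = if (is.na(tr)) NA_real_ else mean((e - tr)^2),
               mean_se = mean(d$se[ok]),
               mc_se = emp_se / sqrt(r_used),
               n_fail = n_reps - r_used, n_used = r_used)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$method, out$part, out$term, out$lag), ]
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("simulation study: scenario '%s', %s outcome, %d reps x n=%d\n",
              x$config, x$family, x$n_reps, x$n))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Cluster bootstrap standard errors
#'
#' Resamples persons with replacement and reruns the full estimation pipeline
#' (propensity models, weights and all) on each resample, returning the
#' bootstrap SD and percentile interval per effect row. Resamples on which
#' the estimator fails are counted and excluded; a result with more than 50%
#' failures is flagged unusable.
#'
#' @param panel A `panel_df`.
#' @param spec A [method_spec()] (or character shorthand).
#' @param family `"cont"` or `"count"`.
#' @param B Number of bootstrap resamples (>= 50).
#' @param seed Integer seed.
#' @param horizon Largest lag.
#' @param level Interval level for the percentile CI.
#' @return Data frame per (part, lag, term): `boot_se`, `ci_lo`, `ci_hi`,
#'   `n_fail`, plus attribute `unusable` if over half the resamples failed.
#' @export
bootstrap_se <- function(panel, spec, family = c("cont", "count"), B = 500,
                         seed = 1, horizon = NULL, level = 0.95) {
  family <- match.arg(family)
  stopifnot(B >= 50)
  spec <- as_method_spec(spec)
  tt <- attr(panel, "n_visits")
  if (is.null(horizon)) horizon <- if (family == "cont") tt else tt - 1
  ids <- unique(panel$id)
  idx <- split(seq_len(nrow(panel)), panel$id)
  set.seed(seed)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(idx[as.character(take)], use.names = FALSE)
    newp <- panel[rows, , drop = FALSE]
    newp$id <- rep(seq_along(take),
                   times = lengths(idx[as.character(take)]))
    newp <- as_panel(as.data.frame(newp), baseline = attr(panel, "baseline"))
    est <- tryCatch(run_methods_once(newp, list(spec), family, horizon),
                    error = function(e) NULL)
    if (!is.null(est)) est$rep <- b
    draws[[b]] <- est
  }
  all <- do.call(rbind, draws)
  alpha <- (1 - level) / 2
  key <- interaction(all$part, all$lag, all$term, drop = TRUE)
  out <- do.call(rbind, lapply(split(all, key), function(d) {
    e <- d$estimate[d$converged & !is.na(d$estimate)]
    data.frame(part = d$part[1], lag = d$lag[1], term = d$term[1],
               boot_se = stats::sd(e),
               ci_lo = unname(stats::quantile(e, alpha)),
               ci_hi = unname(stats::quantile(e, 1 - alpha)),
               n_fail = B - length(e))
  }))
  rownames(out) <- NULL
  attr(out, "unusable") <- any(out$n_fail > B / 2)
  out
}

#' Crossover point of an additive effect-modification relation
#'
#' For a treatment effect `intercept + slope_per10 * (modifier / 10)` (the
#' intercept being the effect at modifier value 0 and the slope the change
#' per 10 modifier units), returns the modifier value at which the effect
#' changes sign.
#'
#' @param intercept Effect at modifier 0 (outcome units).
#' @param slope_per10 Change in effect per 10 modifier units.
#' @return Modifier value `-10 * intercept / slope_per10`.
#' @examples
#' additive_crossover(3.32, -0.57)  # ~58: beneficial below 58% lung function
#' @export
additive_crossover <- function(intercept, slope_per10) {
  if (slope_per10 == 0) {
    stop("zero interaction slope: effect never crosses zero", call. = FALSE)
  }
  -10 * intercept / slope_per10
}

#' Crossover point of a multiplicative effect-modification relation
#'
#' For a ratio-scale treatment effect `base_ratio * ratio_per10^(modifier/10)`
#' (odds or rate ratio at modifier 0 times a multiplicative change per 10
#' modifier units), returns the modifier value at which the ratio reaches 1.
#'
#' @param base_ratio Ratio at modifier 0 (> 0).
#' @param ratio_per10 Multiplicative change per 10 modifier units (> 0, != 1).
#' @return Modifier value `-10 * log(base_ratio) / log(ratio_per10)`.
#' @examples
#' ratio_crossover(0.62, 1.16)  # ~32: odds of zero IV days cross 1 at 32 days
#' @export
ratio_crossover <- function(base_ratio, ratio_per10) {
  if (base_ratio <= 0 || ratio_per10 <= 0) {
    stop("ratios must be positive", call. = FALSE)
  }
  if (ratio_per10 == 1) {
    stop("unit interaction ratio: effect never crosses one", call. = FALSE)
  }
  -10 * log(base_ratio) / log(ratio_per10)
}
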