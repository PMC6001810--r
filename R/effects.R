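# Tidy container for lag-indexed treatment-effect estimates shared by all
# estimators: one row per (part, term). `part` is "mean" for continuous fits
# and "zero"/"rate" for the two components of a zero-inflated count fit
# (g-estimation's gamma model reports a single "rate" part). `term` is
# "treat" for a lag effect or "interaction" for an effect-modification slope
# (per unit of the raw, uncentred modifier).
#' @keywords internal
effect_row <- function(method, family, part, lag, term, estimate, se,
                       se_model = NA_real_, converged = TRUE) {
  data.frame(method = method, family = family, part = part, lag = lag,
             term = term, estimate = estimate, se = se, se_model = se_model,
             converged = converged, stringsAsFactors = FALSE)
}

#' @keywords internal
failed_effects <- function(method, family, parts, horizon, terms = "treat") {
  do.call(rbind, lapply(parts, function(p)
    do.call(rbind, lapply(seq_len(horizon), function(k)
      do.call(rbind, lapply(terms, function(tm)
        effect_row(method, family, p, k, tm, NA_real_, NA_real_,
                   converged = FALSE)))))))
}

#' Tidy effect estimates with confidence intervals
#'
#' @param effects An effect table returned by one of the estimators.
#' @param level Confidence level.
#' @return The table with `ci_lo`/`ci_hi` columns added (Wald intervals; for
#'   `zero`/`rate` parts the estimates are on the log-odds / log-rate scale).
#' @export
effect_ci <- function(effects, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  effects$ci_lo <- effects$estimate - z * effects$se
  effects$ci_hi <- effects$estimate + z * effects$se
  effects
}

# pull lag coefficients named z1..zk (+ optional interactions i1..ik) out of a
# coefficient vector/covariance pair
#' @keywords internal
extract_lags <- function(method, family, part, cf, vc, vc_model, horizon,
                         interaction = FALSE, prefix = "z") {
  rows <- list()
  for (k in seq_len(horizon)) {
    nm <- paste0(prefix, k)
    se <- if (!is.null(vc) && nm %in% rownames(vc)) sqrt(vc[nm, nm]) else NA
    sem <- if (!is.null(vc_model) && nm %in% rownames(vc_model))
      sqrt(vc_model[nm, nm]) else NA
    rows[[length(rows) + 1]] <- effect_row(method, family, part, k, "treat",
                                           unname(cf[nm]), se, sem)
  }
  if (interaction) {
    for (k in seq_len(horizon)) {
      nm <- paste0(prefix, k, ":mod")
      alt <- paste0("mod:", prefix, k)
      if (!nm %in% names(cf) && alt %in% names(cf)) nm <- alt
      if (!nm %in% names(cf)) next
      se <- if (!is.null(vc) && nm %in% rownames(vc)) sqrt(vc[nm, nm]) else NA
      sem <- if (!is.null(vc_model) && nm %in% rownames(vc_model))
        sqrt(vc_model[nm, nm]) else NA
      rows[[length(rows) + 1]] <- effect_row(method, family, part, k,
                                             "interaction", unname(cf[nm]),
                                             se, sem)
    }
  }
  do.call(rbind, rows)
}

# warm-start registry for repeated zinb fits (environment keyed by label)
#' @keywords internal
warm_get <- function(warm, key) {
  if (is.null(warm)) return(NULL)
  if (exists(key, envir = warm, inherits = FALSE)) get(key, envir = warm)
  else NULL
}

#' @keywords internal
warm_set <- function(warm, key, fit) {
  if (!is.null(warm) && isTRUE(fit$converged)) {
    assign(key, list(zero = fit$zero$coefficients, count = fit$coefficients,
                     log_theta = log(fit$theta)), envir = warm)
  }
  invisible(NULL)
}

# build zero-filled treatment-lag design columns z1..zk for outcome rows:
# zk holds treatment at visit (s - k + offset); offset 1 for the continuous
# outcome (lag 1 = current treatment), 0 for the count outcome (lag 1 =
# previous year's treatment). Visits <= 0 are structurally untreated.
#' @keywords internal
add_lag_design <- function(av, horizon, offset) {
  for (k in seq_len(horizon)) {
    shift <- k - offset
    av[[paste0("z", k)]] <- if (shift == 0) av$x
    else av[[paste0("x_lag", shift)]]
  }
  av
}
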