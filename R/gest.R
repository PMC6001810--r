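#' Remove estimated treatment effects from later outcomes ("blanking")
#'
#' For each origin visit `j` and outcome visit `s >= j`, forms the blanked
#' outcome: the observed outcome with the current estimates of the effects of
#' treatments received *after* visit `j` removed — subtracted on the additive
#' scale for the continuous outcome, divided out on the multiplicative
#' (rate-ratio) scale for the count outcome. At `s = j` the blanked outcome is
#' exactly the observed outcome.
#'
#' @param panel A `panel_df`.
#' @param effects Named numeric vector of lag effects `c(lag1 = , lag2 = , ...)`
#'   covering lags `1..max_lag - 1` (empty for `max_lag = 1`). For the count
#'   family these are log rate ratios.
#' @param max_lag Largest origin-to-outcome lag to produce (continuous:
#'   `s - j + 1 <= max_lag`; count: `s - j <= max_lag`).
#' @param family `"linear"` or `"count_gamma"`.
#' @param interactions Optional named vector of per-unit interaction slopes
#'   (same names) with the modifier measured the visit before each treatment
#'   (continuous: previous lung function; count: same-visit count).
#' @return Data frame keyed by `(id, s, j)` with the blanked outcome `H`.
#'   Count-family values are positive (zeros floored at 0.5 before any
#'   division, since the gamma working model has positive support).
#' @export
blank_outcomes <- function(panel, effects, max_lag,
                           family = c("linear", "count_gamma"),
                           interactions = NULL) {
  family <- match.arg(family)
  need <- if (max_lag >= 2) paste0("lag", seq_len(max_lag - 1)) else character()
  miss <- setdiff(need, names(effects))
  if (length(miss) > 0) {
    stop("effects must contain ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tt <- attr(panel, "n_visits")
  av <- analysis_view(panel)
  gap <- if (family == "linear") 0 else 1
  out <- list()
  for (j in seq_len(tt - gap)) {
    for (s in j:min(j + max_lag - 1 + gap, tt)) {
      if (s - j + 1 - gap < 1) next
      rows <- which(av$visit == s & av$observed == 1)
      d <- av[rows, c("id", "visit", "y_cont", "y_count")]
      adj <- numeric(nrow(d))
      # treatments after j that affect the outcome at s
      u_set <- seq(j + 1, s - gap, length.out = max(s - gap - j, 0))
      for (u in u_set) {
        lag_u <- s - u + 1 - gap
        x_u <- shift_col(av, rows, s - u, "x", 0)
        bl <- unname(effects[paste0("lag", lag_u)])
        if (!is.null(interactions)) {
          mod_u <- if (family == "linear")
            shift_col(av, rows, s - u + 1, "y_cont", NA)
          else shift_col(av, rows, s - u, "y_count", NA)
          bl <- bl + unname(interactions[paste0("lag", lag_u)]) * mod_u
        }
        adj <- adj + bl * x_u
      }
      h <- if (family == "linear") d$y_cont - adj
      else pmax(d$y_count, 0.5) * exp(-adj)
      out[[length(out) + 1]] <- data.frame(id = d$id, s = s, j = j, H = h)
    }
  }
  do.call(rbind, out)
}

#' G-estimation of a structural nested mean model by sequential regression
#'
#' Iterative algorithm: at iteration `m`, outcomes are blanked using the
#' current estimates for lags below `m`, all origin-outcome pairs at lags up
#' to `m` are pooled, and one propensity-adjusted regression with lag-specific
#' treatment coefficients re-estimates all lags `1..m` jointly. For the
#' continuous outcome the working model is linear (identity link); for the
#' count outcome it is a gamma regression with log link on the positive
#' blanked outcome, yielding a single rate ratio per lag (no separate
#' zero-count part). The fitted propensity score enters each regression as a
#' linear term, giving double robustness for the treatment coefficients.
#'
#' The lag-1 fit (horizon 1, linear family) is numerically identical to the
#' propensity-adjusted sequential conditional mean model.
#'
#' @param panel A `panel_df`.
#' @param family `"linear"` or `"count_gamma"`.
#' @param horizon Largest lag (default `T` for linear, `T - 1` for count).
#' @param propensity Optional [fit_propensity()] result to reuse.
#' @param interaction Estimate treatment-by-modifier interaction blips
#'   (modifier: previous continuous outcome / origin-visit count, raw scale);
#'   interactions enter both the blanking step and the regression design.
#' @param censoring Optional `weight_set`; pair rows are weighted by the
#'   stabilized probability of remaining observed between origin and outcome.
#' @param mode `"sequential"` (default) estimates lag `m` from the lag-`m`
#'   origin-outcome pairs only, with lag-specific nuisance coefficients and
#'   the lower lags fixed at their blanked values; `"pooled"` re-estimates all
#'   lags up to `m` jointly from the pooled pairs in one regression with
#'   shared nuisance coefficients. The sequential mode keeps the propensity
#'   residual of the origin treatment orthogonal to the (necessarily
#'   lag-varying) outcome-model part within each fit; the pooled single-model
#'   form is retained for comparison.
#' @return Effect table (part `"mean"` or `"rate"`); cluster-robust SEs. On
#'   failure the affected lags are flagged.
#' @export
g_estimate <- function(panel, family = c("linear", "count_gamma"),
                       horizon = NULL, propensity = NULL, interaction = FALSE,
                       censoring = NULL, mode = c("sequential", "pooled")) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  tt <- attr(panel, "n_visits")
  gap <- if (family == "linear") 0 else 1
  if (is.null(horizon)) horizon <- tt - gap
  if (is.null(propensity)) propensity <- fit_propensity(panel)
  part <- if (family == "linear") "mean" else "rate"

  av <- analysis_view(panel)
  pt <- rep(NA_real_, nrow(av))
  m <- match(paste(propensity$data$id, propensity$data$visit),
             paste(av$id, av$visit))
  pt[m] <- stats::predict(propensity$denominator$fit,
                          newdata = propensity$data, type = "response")
  av$pt <- pt
  ckey <- if (!is.null(censoring)) paste(censoring$id, censoring$visit)

  # static design pieces per (j, s) pair
  pair_data <- function(j, s) {
    rows <- which(av$visit == s & av$observed == 1)
    d <- av[rows, c("id", "y_cont", "y_count")]
    back <- s - j
    d$.rows <- rows
    d$x_j <- shift_col(av, rows, back, "x", 0)
    d$x_pre <- shift_col(av, rows, back + 1, "x", 0)
    d$f_pre <- shift_col(av, rows, back + 1, "y_cont", NA)
    d$v_j <- shift_col(av, rows, back, "y_count", NA)
    d$pt_j <- shift_col(av, rows, back, "pt", NA)
    d$age <- av$age[rows]
    d$mod <- if (family == "linear") d$f_pre else d$v_j
    d$j <- j; d$s <- s; d$lag <- s - j + 1 - gap
    if (!is.null(censoring)) {
      c_hi <- censoring$cw[match(paste(d$id, s), ckey)]
      c_lo <- censoring$cw[match(paste(d$id, j), ckey)]
      d$w <- c_hi / c_lo
    } else d$w <- 1
    rownames(d) <- NULL
    d
  }
  pairs <- list()
  for (j in seq_len(tt - gap)) {
    for (s in seq(j + gap, min(j + horizon - 1 + gap, tt))) {
      pairs[[length(pairs) + 1]] <- pair_data(j, s)
    }
  }
  all_pairs <- do.call(rbind, pairs)
  all_pairs <- all_pairs[stats::complete.cases(
    all_pairs[, c("x_j", "pt_j", "mod", "w")]), , drop = FALSE]

  est <- stats::setNames(numeric(0), character(0))
  ints <- stats::setNames(numeric(0), character(0))
  fam_lab <- if (family == "linear") "linear" else "count"
  ses <- list()
  lag_fits <- list()
  for (m_it in seq_len(horizon)) {
    d <- all_pairs[if (mode == "sequential") all_pairs$lag == m_it
                   else all_pairs$lag <= m_it, , drop = FALSE]
    # blank out the (already estimated) effects of treatments after the origin
    adj <- blank_adjust(av, d, est, ints, family, gap)
    d$H <- if (family == "linear") d$y_cont - adj
    else pmax(d$y_count, 0.5) * exp(-adj)
    lag_set <- if (mode == "sequential") m_it else seq_len(m_it)
    for (k in lag_set) {
      d[[paste0("xk", k)]] <- d$x_j * (d$lag == k)
      d[[paste0("ik", k)]] <- d$x_j * (d$lag == k) * d$mod
    }
    xk_terms <- paste0("xk", lag_set)
    terms <- c(xk_terms, "x_pre", "f_pre", "v_j", "age", "pt_j")
    terms <- terms[vapply(terms, function(v) !v %in% names(d) ||
                            stats::var(d[[v]]) > 0, logical(1))]
    if (length(unique(d$s)) > 1) terms <- c(terms, "factor(s)")
    if (interaction) terms <- c(terms, paste0("ik", lag_set))
    f <- stats::as.formula(paste("H ~", paste(terms, collapse = " + ")))
    wts <- if (all(d$w == 1)) NULL else d$w
    fit <- fit_glm(f, d, family = if (family == "linear") "linear"
                   else "gamma_log", weights = wts, cluster = d$id)
    if (!fit$converged) {
      out <- failed_effects("gest", fam_lab, part, horizon,
                            terms = if (interaction)
                              c("treat", "interaction") else "treat")
      attr(out, "failed_lag") <- m_it
      return(out)
    }
    for (k in lag_set) {
      est[paste0("lag", k)] <- unname(coef(fit)[paste0("xk", k)])
      if (interaction) {
        ints[paste0("lag", k)] <- unname(coef(fit)[paste0("ik", k)])
      }
      lag_fits[[k]] <- fit
    }
  }
  rows <- list()
  for (k in seq_len(horizon)) {
    fit <- lag_fits[[k]]
    vc <- fit$vcov_sandwich; vcm <- fit$vcov_model
    nm <- paste0("xk", k)
    se <- if (!is.null(vc) && nm %in% rownames(vc)) sqrt(vc[nm, nm]) else NA
    sem <- if (!is.null(vcm) && nm %in% rownames(vcm)) sqrt(vcm[nm, nm])
    else NA
    rows[[length(rows) + 1]] <- effect_row(
      "gest", fam_lab, part, k, "treat", unname(est[paste0("lag", k)]),
      se, sem)
    if (interaction) {
      nmi <- paste0("ik", k)
      sei <- if (!is.null(vc) && nmi %in% rownames(vc)) sqrt(vc[nmi, nmi])
      else NA
      rows[[length(rows) + 1]] <- effect_row(
        "gest", fam_lab, part, k, "interaction",
        unname(ints[paste0("lag", k)]), sei)
    }
  }
  do.call(rbind, rows)
}

# total blip adjustment for treatments strictly between origin j and the
# outcome visit (count family: up to s - 1)
#' @keywords internal
blank_adjust <- function(av, d, est, ints, family, gap) {
  adj <- numeric(nrow(d))
  if (length(est) == 0) return(adj)
  smax <- max(d$s)
  # treatment at visit u = s - u_back affects the outcome at s with lag
  # s - u + 1 (continuous) or s - u (count); only treatments after j count
  for (u_back in seq(gap, smax - 1)) {
    lag_u <- u_back + 1 - gap
    nm <- paste0("lag", lag_u)
    if (!nm %in% names(est)) next
    active <- d$s - u_back > d$j & d$s - u_back >= 1
    if (!any(active)) next
    x_u <- shift_col(av, d$.rows, u_back, "x", 0)
    bl <- rep(unname(est[nm]), nrow(d))
    if (length(ints) > 0 && nm %in% names(ints)) {
      mod_u <- if (family == "linear")
        shift_col(av, d$.rows, u_back + 1, "y_cont", NA)
      else shift_col(av, d$.rows, u_back, "y_count", NA)
      bl <- bl + unname(ints[nm]) * mod_u
    }
    adj <- adj + ifelse(active, bl * x_u, 0)
  }
  adj
}
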