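#' History-adjusted marginal structural model
#'
#' Estimates lag-specific treatment effects by re-anchoring the weighting at
#' each origin visit `t`: the weight for the pair (origin `t`, outcome visit
#' `s`) multiplies the stabilized per-visit ratios for visits `t..s` only, and
#' covariates measured before `t` (previous treatment, previous continuous
#' outcome, the count at `t`, baseline covariates) enter the outcome model
#' directly, which also permits treatment-by-covariate interaction terms.
#'
#' Estimation is per lag: the lag-`k` fit pools all origin-outcome pairs at
#' that lag with origin-specific intercepts, includes treatment terms for
#' every visit from the origin to the outcome, and reports the coefficient
#' (and optionally the interaction slope) of the origin treatment.
#' Restricting `origins` fits single origins instead.
#'
#' @param panel A `panel_df`.
#' @param weights A `weight_set` from [stabilized_weights()] (untruncated;
#'   pair weights are formed from its per-visit factors, then truncated here
#'   if requested).
#' @param family `"linear"` or `"zinb"`.
#' @param horizon Largest lag.
#' @param interaction Add treatment-by-modifier interactions (modifier:
#'   pre-origin continuous outcome for `linear`, pre-origin count for
#'   `zinb`; raw, uncentred scale).
#' @param trunc Optional percentile bounds `c(lo, hi)` applied to the pooled
#'   pair weights within each lag fit.
#' @param censoring Optional `weight_set`; pair rows are weighted by the
#'   stabilized probability of remaining observed between origin and outcome.
#' @param origins Optional restriction of origin visits (e.g. `1`); default
#'   all origins compatible with the lag.
#' @param include_history Include the pre-origin covariates (disable only for
#'   equivalence checks against the ordinary MSM).
#' @param warm,warm_key Optional environment (and key) holding warm-start
#'   values for repeated zero-inflated fits across simulation replicates.
#' @return Effect table with one row per lag (plus interaction rows). The
#'   `se` column is cluster-robust; `se_model` is the model-based SE.
#' @export
fit_hamsm <- function(panel, weights, family = c("linear", "zinb"),
                      horizon = NULL, interaction = FALSE, trunc = NULL,
                      censoring = NULL, origins = NULL,
                      include_history = TRUE, warm = NULL,
                      warm_key = "hamsm") {
  family <- match.arg(family)
  tt <- attr(panel, "n_visits")
  if (is.null(horizon)) horizon <- if (family == "linear") tt else tt - 1
  av <- analysis_view(panel)
  wkey <- paste(weights$id, weights$visit)
  ckey <- if (!is.null(censoring)) paste(censoring$id, censoring$visit)
  out <- list()
  # count outcome at s responds to treatments up to s-1
  out_gap <- if (family == "linear") 0 else 1

  for (k in seq_len(horizon)) {
    pieces <- list()
    t_max <- tt - out_gap - k + 1
    t_set <- seq_len(max(t_max, 0))
    if (!is.null(origins)) t_set <- intersect(t_set, origins)
    if (length(t_set) == 0) {
      out[[k]] <- failed_effects("hamsm", family,
                                 if (family == "linear") "mean"
                                 else c("zero", "rate"), 1)
      next
    }
    for (t0 in t_set) {
      s <- t0 + k - 1 + out_gap
      rows_s <- which(av$visit == s & av$observed == 1)
      d <- av[rows_s, , drop = FALSE]
      # treatment terms for visits t0..(s - out_gap): zj = x at s - out_gap - j + 1
      for (j in seq_len(k)) {
        shift <- out_gap + j - 1
        d[[paste0("z", j)]] <- if (shift == 0) d$x
        else d[[paste0("x_lag", shift)]]
      }
      # pre-origin covariates, measured at/before the origin visit t0
      back <- s - t0  # visits between origin and outcome
      d$x_pre <- shift_col(av, rows_s, back + 1, "x", 0)
      d$f_pre <- shift_col(av, rows_s, back + 1, "y_cont", NA)
      d$v_origin <- shift_col(av, rows_s, back, "y_count", NA)
      d$mod <- if (family == "linear") d$f_pre else d$v_origin
      # pair weight: stabilized ratios for visits t0..(s - out_gap)
      m_hi <- match(paste(d$id, s - out_gap), wkey)
      m_lo <- match(paste(d$id, t0 - 1), wkey)
      d$w <- weights$sw[m_hi] / weights$sw[m_lo]
      if (!is.null(censoring)) {
        c_hi <- censoring$cw[match(paste(d$id, s), ckey)]
        c_lo <- censoring$cw[match(paste(d$id, t0), ckey)]
        d$w <- d$w * c_hi / c_lo
      }
      d$origin <- t0
      rownames(d) <- NULL
      pieces[[length(pieces) + 1]] <- d
    }
    dat <- do.call(rbind, pieces)
    dat <- dat[stats::complete.cases(dat[, c("w", "mod")]), , drop = FALSE]
    if (!is.null(trunc)) {
      q <- stats::quantile(dat$w, probs = trunc / 100, names = FALSE)
      dat$w <- pmin(pmax(dat$w, q[1]), q[2])
    }
    lag_terms <- paste0("z", seq_len(k))
    terms <- lag_terms
    if (include_history) {
      hist_terms <- c("x_pre", "f_pre", "v_origin", "age")
      # drop constant columns (x_pre is structurally 0 when origin is 1 only)
      hist_terms <- hist_terms[vapply(hist_terms,
                                      function(v) stats::var(dat[[v]]) > 0,
                                      logical(1))]
      terms <- c(terms, hist_terms)
    }
    if (length(unique(dat$origin)) > 1) terms <- c(terms, "factor(origin)")
    if (interaction) terms <- c(terms, paste0(lag_terms, ":mod"))
    rhs <- paste(terms, collapse = " + ")
    if (family == "linear") {
      f <- stats::as.formula(paste("y_cont ~", rhs))
      fit <- fit_glm(f, dat, family = "linear", weights = dat$w,
                     cluster = dat$id)
      out[[k]] <- if (!fit$converged) {
        failed_effects("hamsm", "linear", "mean", 1,
                       terms = if (interaction) c("treat", "interaction")
                       else "treat")
      } else {
        r <- extract_lags("hamsm", "linear", "mean", coef(fit),
                          fit$vcov_sandwich, fit$vcov_model, k, interaction,
                          prefix = "z")
        r[r$lag == k, , drop = FALSE]
      }
    } else {
      f <- stats::as.formula(paste("y_count ~", rhs))
      zf <- stats::as.formula(paste("~", rhs))
      wk <- paste0(warm_key, "_lag", k)
      fit <- fit_zinb(f, zf, dat, weights = dat$w, cluster = dat$id,
                      start = warm_get(warm, wk))
      warm_set(warm, wk, fit)
      out[[k]] <- if (!fit$converged) {
        failed_effects("hamsm", "count", c("zero", "rate"), 1,
                       terms = if (interaction) c("treat", "interaction")
                       else "treat")
      } else {
        r <- zinb_effect_rows("hamsm", fit, k, interaction)
        r[r$lag == k, , drop = FALSE]
      }
    }
    out[[k]]$lag <- k
  }
  do.call(rbind, out)
}

# value of `col` shifted `back` visits before each row (same person), using
# the analysis view's direct-index person-visit lookup
#' @keywords internal
shift_col <- function(av, rows, back, col, fill) {
  visit <- av$visit[rows] - back
  key <- av$.id_ix[rows] * 64L + visit
  j <- attr(av, "lookup")[pmax(key, 1L)]
  val <- av[[col]][j]
  val[visit < 0] <- fill
  val
}
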