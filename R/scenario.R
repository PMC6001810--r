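#' Scenario configurations for the synthetic cohort generator
#'
#' Six data-generating scenarios sharing one causal skeleton: annual visits
#' `t = 0..5`, a continuous lung-function outcome `F` (percent units), a
#' zero-inflated negative binomial count outcome `V` (annual IV-antibiotic
#' days, 0--365) that also confounds treatment, a binary treatment `X` with
#' `X0 = 0`, and a beta-distributed baseline age. Per visit `t >= 1` the
#' generation order is `V_t`, then `X_t` (given `V_t`, `F_{t-1}`, `X_{t-1}`,
#' age), then `F_t` (given `X_t`, `V_t`, `F_{t-1}`, age); the `reversed`
#' scenario swaps the first two steps so that `X_t` causes `V_t`.
#'
#' Scenarios:
#' * `standard`: a one-year treatment effect on each outcome; longer-term
#'   effects arise only through mediation by the time-varying covariates.
#' * `null`: all treatment coefficients zero.
#' * `longterm`: adds direct long-term treatment effects that are negative,
#'   partially counteracting the beneficial one-year effect.
#' * `effectmod`: adds treatment-by-covariate interactions (treatment with the
#'   previous continuous outcome, and with the previous count).
#' * `reversed`: within-visit treatment-to-count direction flipped.
#' * `censoring`: adds a missing-at-random dropout hazard that is higher for
#'   unhealthy histories (low lung function, many IV days).
#'
#' Continuous-outcome covariates enter centred at 85 percent (`f_ref`) and age
#' at 16 years (`age_ref`); coefficients are per unit.
#'
#' @param name Scenario name.
#' @param overrides Optional named list of coefficient blocks replacing the
#'   defaults (replacement is per block element, e.g.
#'   `list(f_model = list(x = 0.5))`).
#' @return A `scenario_config` list with blocks `age`, `f0`, `v0`, `v_model`,
#'   `x_model`, `f_model`, `cens` (or `NULL`), flags, and a `ground_truth`
#'   summary of the direct treatment coefficients.
#' @export
make_scenario <- function(name = c("standard", "null", "longterm",
                                   "effectmod", "reversed", "censoring"),
                          overrides = NULL) {
  name <- match.arg(name)
  cfg <- list(
    name = name,
    n_visits = 5L,
    f_ref = 85, age_ref = 16,
    # age ~ scale * Beta(a, b): mean ~16 y, SD ~12 y
    age = list(shape1 = 1.2, shape2 = 4, scale = 70),
    # baseline lung function
    f0 = list(int = 95, age = -0.55, sd = 12),
    # baseline count: zero-inflation and NB rate parts
    v0 = list(zero = c(int = 0.35, f = -0.03, age = 0.012),
              rate = c(int = 2.9, f = -0.012, age = 0.01),
              theta = 1.3),
    # count model at t >= 1; x is the treatment term (X_{t-1}, or X_t when
    # reversed), x2 a direct effect of X_{t-2} (longterm scenario), ix the
    # treatment-by-previous-count interaction (effectmod scenario)
    v_model = list(zero = c(int = 0.45, x = 0.35, f = 0.025, v = -0.05,
                            age = -0.012),
                   rate = c(int = 2.55, x = -0.25, f = -0.012, v = 0.010,
                            age = 0.008),
                   x2_zero = 0, x2_rate = 0, ix_zero = 0, ix_rate = 0,
                   theta = 1.3),
    # treatment assignment: v is V_t (standard) or V_{t-1} (reversed)
    # treatment logit uses log1p of the count so its influence is bounded
    # and positivity holds across the count's full range
    x_model = c(int = -1.9, xprev = 2.6, f = -0.02, v = 0.35, age = 0.012),
    # continuous outcome: x = X_t (the one-year effect), xprev a direct
    # long-term effect of X_{t-1}, ix the X_t-by-previous-F interaction
    f_model = list(coef = c(int = 85, f = 0.80, x = 2.0, xprev = 0,
                            v = -0.06, age = -0.03),
                   ix = 0, sd = 7),
    cens = NULL,
    reversed = FALSE)

  if (name == "null") {
    cfg$v_model$zero["x"] <- 0
    cfg$v_model$rate["x"] <- 0
    cfg$f_model$coef["x"] <- 0
  } else if (name == "longterm") {
    cfg$f_model$coef["xprev"] <- -0.5
    cfg$v_model$x2_zero <- -0.12
    cfg$v_model$x2_rate <- 0.10
  } else if (name == "effectmod") {
    cfg$f_model$ix <- -0.05
    cfg$v_model$ix_zero <- 0.015
    cfg$v_model$ix_rate <- -0.004
  } else if (name == "reversed") {
    cfg$reversed <- TRUE
    cfg$v_model$zero["x"] <- 0.9
    cfg$v_model$rate["x"] <- -0.7
  } else if (name == "censoring") {
    cfg$cens <- c(int = -2.6, f = -0.05, v = 0.45, age = 0.01)
  }

  if (!is.null(overrides)) {
    for (block in names(overrides)) {
      if (!block %in% names(cfg)) {
        stop("unknown config block: ", block, call. = FALSE)
      }
      if (is.list(cfg[[block]]) && is.list(overrides[[block]])) {
        for (el in names(overrides[[block]])) {
          cur <- cfg[[block]][[el]]
          new <- overrides[[block]][[el]]
          if (!is.null(names(new)) && !is.null(names(cur))) {
            cur[names(new)] <- new
            cfg[[block]][[el]] <- cur
          } else {
            cfg[[block]][[el]] <- new
          }
        }
      } else if (!is.null(names(overrides[[block]])) &&
                 !is.null(names(cfg[[block]]))) {
        cur <- cfg[[block]]
        cur[names(overrides[[block]])] <- overrides[[block]]
        cfg[[block]] <- cur
      } else {
        cfg[[block]] <- overrides[[block]]
      }
    }
  }

  cfg$ground_truth <- scenario_ground_truth(cfg)
  structure(cfg, class = "scenario_config")
}

# direct (non-mediated) treatment coefficients implied by a config; the full
# population-average lag effects come from true_effects()
#' @keywords internal
scenario_ground_truth <- function(cfg) {
  k <- cfg$n_visits
  direct <- numeric(k)
  direct[1] <- unname(cfg$f_model$coef["x"])
  if (k >= 2) direct[2] <- unname(cfg$f_model$coef["xprev"])
  names(direct) <- paste0("lag", seq_len(k))
  null <- cfg$v_model$zero[["x"]] == 0 && cfg$v_model$rate[["x"]] == 0 &&
    cfg$f_model$coef[["x"]] == 0 && cfg$f_model$coef[["xprev"]] == 0 &&
    cfg$f_model$ix == 0 && cfg$v_model$ix_zero == 0 &&
    cfg$v_model$ix_rate == 0 && cfg$v_model$x2_zero == 0 &&
    cfg$v_model$x2_rate == 0
  list(direct_cont = direct,
       interaction_cont = cfg$f_model$ix,
       interaction_count = c(zero = cfg$v_model$ix_zero,
                             rate = cfg$v_model$ix_rate),
       null = null)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s': visits 0..%d%s%s\n", x$name, x$n_visits,
              if (x$reversed) ", reversed X<->V ordering" else "",
              if (!is.null(x$cens)) ", MAR censoring" else ""))
  cat("direct continuous-treatment coefficients:\n")
  print(x$ground_truth$direct_cont)
  invisible(x)
}
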