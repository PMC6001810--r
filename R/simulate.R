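#' Simulate a synthetic cohort
#'
#' Generates `n` persons over visits `0..T` from a [make_scenario()]
#' configuration. All randomness is drawn up front as uniform/normal noise
#' keyed by `(person, visit)` and the trajectory recursion is deterministic
#' given that noise, so identical `(config, n, seed)` give bit-identical
#' panels, and counterfactual regimes can share noise (common random numbers).
#'
#' Count draws use the quantile transform of the zero-inflated negative
#' binomial and are truncated at 365 days. Censored person-visits are emitted
#' with `observed = 0` and `NA` treatment/outcomes.
#'
#' @param config A `scenario_config`.
#' @param n Number of persons (>= 1).
#' @param seed Integer seed.
#' @return A [as_panel()] object with `n * (T + 1)` rows.
#' @export
simulate_cohort <- function(config, n, seed) {
  stopifnot(n >= 1)
  noise <- sim_noise(config, n, seed)
  sim_path(config, noise)
}

# pre-draw all noise used by the recursion
#' @keywords internal
sim_noise <- function(config, n, seed) {
  set.seed(seed)
  tt <- config$n_visits
  list(n = n,
       u_age = stats::runif(n),
       z_f0 = stats::rnorm(n),
       u_v_zero = matrix(stats::runif(n * (tt + 1)), n, tt + 1),
       u_v_count = matrix(stats::runif(n * (tt + 1)), n, tt + 1),
       u_x = matrix(stats::runif(n * tt), n, tt),
       z_f = matrix(stats::rnorm(n * tt), n, tt),
       u_cens = matrix(stats::runif(n * tt), n, tt))
}

# zero-inflated NB quantile draw from two uniforms
#' @keywords internal
qzinb <- function(u_zero, u_count, pi_, mu, theta, cap = 365) {
  out <- ifelse(u_zero < pi_, 0,
                stats::qnbinom(u_count, size = theta, mu = mu))
  pmin(out, cap)
}

# deterministic trajectory recursion given pre-drawn noise; `regime`, if
# given, is a fixed treatment vector (length T) applied to everyone
#' @keywords internal
sim_path <- function(config, noise, regime = NULL) {
  n <- noise$n
  tt <- config$n_visits
  age <- config$age$scale *
    stats::qbeta(noise$u_age, config$age$shape1, config$age$shape2)
  ac <- age - config$age_ref

  f0c <- config$f0$int + config$f0$age * age +
    config$f0$sd * noise$z_f0 - config$f_ref
  pz0 <- stats::plogis(config$v0$zero["int"] + config$v0$zero["f"] * f0c +
                         config$v0$zero["age"] * ac)
  mu0 <- exp(config$v0$rate["int"] + config$v0$rate["f"] * f0c +
               config$v0$rate["age"] * ac)
  v0 <- qzinb(noise$u_v_zero[, 1], noise$u_v_count[, 1], pz0, mu0,
              config$v0$theta)

  Fm <- matrix(NA_real_, n, tt + 1); Fm[, 1] <- f0c + config$f_ref
  Vm <- matrix(NA_real_, n, tt + 1); Vm[, 1] <- v0
  Xm <- matrix(0L, n, tt + 1)
  Om <- matrix(1L, n, tt + 1)

  vm <- config$v_model; xm <- config$x_model; fm <- config$f_model
  for (t in seq_len(tt)) {
    fc_prev <- Fm[, t] - config$f_ref
    v_prev <- Vm[, t]
    x_prev <- Xm[, t]
    x_prev2 <- if (t >= 2) Xm[, t - 1] else rep(0L, n)

    draw_v <- function(x_term) {
      eta_z <- vm$zero["int"] + vm$zero["x"] * x_term +
        vm$zero["f"] * fc_prev + vm$zero["v"] * v_prev +
        vm$zero["age"] * ac + vm$x2_zero * x_prev2 +
        vm$ix_zero * x_term * v_prev
      eta_c <- vm$rate["int"] + vm$rate["x"] * x_term +
        vm$rate["f"] * fc_prev + vm$rate["v"] * v_prev +
        vm$rate["age"] * ac + vm$x2_rate * x_prev2 +
        vm$ix_rate * x_term * v_prev
      qzinb(noise$u_v_zero[, t + 1], noise$u_v_count[, t + 1],
            stats::plogis(eta_z), exp(eta_c), vm$theta)
    }
    draw_x <- function(v_term) {
      eta_x <- xm["int"] + xm["xprev"] * x_prev + xm["f"] * fc_prev +
        xm["v"] * log1p(v_term) + xm["age"] * ac
      if (is.null(regime)) as.integer(noise$u_x[, t] < stats::plogis(eta_x))
      else rep(as.integer(regime[t]), n)
    }

    if (config$reversed) {
      x_t <- draw_x(v_prev)
      v_t <- draw_v(x_t)
    } else {
      v_t <- draw_v(x_prev)
      x_t <- draw_x(v_t)
    }
    f_t <- fm$coef["int"] + fm$coef["f"] * fc_prev + fm$coef["x"] * x_t +
      fm$coef["xprev"] * x_prev + fm$coef["v"] * v_t + fm$coef["age"] * ac +
      fm$ix * x_t * fc_prev + fm$sd * noise$z_f[, t]

    Vm[, t + 1] <- v_t
    Xm[, t + 1] <- x_t
    Fm[, t + 1] <- f_t

    if (!is.null(config$cens) && is.null(regime)) {
      p_c <- stats::plogis(config$cens["int"] + config$cens["f"] * fc_prev +
                             config$cens["v"] * log1p(v_prev) +
                             config$cens["age"] * ac)
      Om[, t + 1] <- Om[, t] * as.integer(noise$u_cens[, t] >= p_c)
    } else {
      Om[, t + 1] <- Om[, t]
    }
  }

  obs <- as.vector(t(Om)) == 1L
  out <- data.frame(
    id = rep(seq_len(n), each = tt + 1),
    visit = rep(0:tt, n),
    x = ifelse(obs, as.vector(t(Xm)), NA_integer_),
    y_cont = ifelse(obs, as.vector(t(Fm)), NA_real_),
    y_count = ifelse(obs, as.vector(t(Vm)), NA_real_),
    age = rep(age, each = tt + 1),
    observed = as.integer(obs))
  as_panel(out)
}

#' True population-average lag effects for the continuous outcome
#'
#' The lag-`k` effect is defined as the population mean contrast
#' `E[F_T | treat only at visit T-k+1] - E[F_T | never treat]`, i.e. the
#' effect of a single year of treatment `k` years before the final outcome
#' with all other treatments withheld. It is computed by counterfactual
#' simulation with common random numbers: both regimes reuse the same noise,
#' so the Monte-Carlo error affects only variability genuinely induced by
#' mediation through the count pathway. Under a `null` configuration the
#' result is exactly zero without simulation.
#'
#' @param config A `scenario_config`.
#' @param horizon Largest lag (<= number of visits).
#' @param n Number of simulated persons per regime.
#' @param seed Integer seed for the shared noise.
#' @return Data frame with columns `lag` and `truth`.
#' @export
true_effects <- function(config, horizon = config$n_visits, n = 200000,
                         seed = 1) {
  stopifnot(horizon <= config$n_visits)
  if (config$ground_truth$null) {
    return(data.frame(lag = seq_len(horizon), truth = 0))
  }
  tt <- config$n_visits
  cfg <- config
  cfg$cens <- NULL  # counterfactual follow-up is uncensored
  noise <- sim_noise(cfg, n, seed)
  mean_final <- function(regime) {
    p <- sim_path(cfg, noise, regime = regime)
    mean(p$y_cont[p$visit == tt])
  }
  never <- mean_final(rep(0L, tt))
  truth <- vapply(seq_len(horizon), function(k) {
    regime <- rep(0L, tt)
    regime[tt - k + 1] <- 1L
    mean_final(regime) - never
  }, numeric(1))
  data.frame(lag = seq_len(horizon), truth = truth)
}
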