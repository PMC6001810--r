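test_that("the saturated regime set at horizon 2 has four regimes", {
  rs <- make_regimes(2)
  expect_length(rs, 4)
  expect_setequal(vapply(rs, paste, collapse = "", character(1)),
                  c("00", "01", "10", "11"))
})

test_that("regime means match the exact g-formula recursion", {
  # hand-specified short-term models: the count depends only on the previous
  # treatment, the continuous outcome is linear in its parents, so the
  # regime means have a closed form that the Monte-Carlo draws must match
  pi0 <- 0.4; pi1 <- 0.6
  mu0 <- 4; mu1 <- 2.5
  v_model <- hand_zinb(
    zero_coef = c(`(Intercept)` = qlogis(pi0),
                  x_lag1 = qlogis(pi1) - qlogis(pi0)),
    count_coef = c(`(Intercept)` = log(mu0), x_lag1 = log(mu1) - log(mu0)),
    theta = 2, formula_rhs = "x_lag1")
  # exact linear continuous model fitted on noise-free data
  tr <- expand.grid(x = 0:1, y_cont_lag1 = c(70, 80, 90), y_count = c(0, 5, 9))
  tr$y_cont <- 20 + 1.5 * tr$x + 0.75 * tr$y_cont_lag1 - 0.2 * tr$y_count
  f_model <- fit_glm(y_cont ~ x + y_cont_lag1 + y_count, tr,
                     family = "linear")
  expect_lt(f_model$rmse, 1e-10)

  baseline <- data.frame(id = 1, y_cont = 80, y_count = 5, age = 20)
  n_mc <- 40000
  cf <- simulate_regimes(list(f_model = f_model, v_model = v_model),
                         baseline, make_regimes(2), n_mc = n_mc, seed = 99)

  ev <- function(x_prev) (1 - c(pi0, pi1)[x_prev + 1]) *
    c(mu0, mu1)[x_prev + 1]
  ef1 <- function(x1) 20 + 1.5 * x1 + 0.75 * 80 - 0.2 * ev(0)
  ef2 <- function(x1, x2) 20 + 1.5 * x2 + 0.75 * ef1(x1) - 0.2 * ev(x1)
  regimes <- attr(cf, "regimes")
  for (r in seq_along(regimes)) {
    x <- regimes[[r]]
    m1 <- mean(cf$y_cont[cf$regime == r & cf$visit == 1])
    m2 <- mean(cf$y_cont[cf$regime == r & cf$visit == 2])
    expect_equal(m1, ef1(x[1]), tolerance = 0.06)
    expect_equal(m2, ef2(x[1], x[2]), tolerance = 0.06)
  }
})

test_that("null treatment models give equal regime means", {
  pi_ <- 0.5; mu <- 3
  v_model <- hand_zinb(c(`(Intercept)` = qlogis(pi_)),
                       c(`(Intercept)` = log(mu)), theta = 2,
                       formula_rhs = "1")
  tr <- expand.grid(y_cont_lag1 = c(70, 80, 90), y_count = c(0, 4, 8))
  tr$y_cont <- 10 + 0.8 * tr$y_cont_lag1 - 0.1 * tr$y_count
  f_model <- fit_glm(y_cont ~ y_cont_lag1 + y_count, tr, family = "linear")
  baseline <- data.frame(id = 1:50, y_cont = rnorm(50, 80, 5),
                         y_count = rpois(50, 4), age = 20)
  cf <- simulate_regimes(list(f_model = f_model, v_model = v_model),
                         baseline, make_regimes(2), n_mc = 400, seed = 3)
  always <- mean(cf$y_cont[cf$regime == 4 & cf$visit == 2])
  never <- mean(cf$y_cont[cf$regime == 1 & cf$visit == 2])
  expect_equal(always, never, tolerance = 0.05)
  eff <- gformula_effects(cf, "linear", horizon = 2)
  expect_true(all(abs(eff$estimate) < 0.05))
})

test_that("the full pipeline tracks the simulated truth at moderate n", {
  p <- simulate_cohort(make_scenario("standard"), 4000, 47)
  est <- fit_gformula(p, "linear", seed = 8)
  truth <- true_effects(make_scenario("standard"), 5, n = 100000, seed = 9)
  expect_true(all(abs(est$estimate - truth$truth) < 0.35))
  expect_error(
    simulate_regimes(fit_nuisance_models(p),
                     p[p$visit == 0, c("id", "y_cont", "y_count", "age")],
                     structure(list(c(0L, 1L)), class = "regime_set",
                               horizon = 2), 1, 1),
    NA)
})
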