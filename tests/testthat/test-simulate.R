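test_that("scenario constructors encode the six designs", {
  null <- make_scenario("null")
  expect_true(null$ground_truth$null)
  expect_true(all(null$ground_truth$direct_cont == 0))
  expect_equal(true_effects(null, 5)$truth, rep(0, 5))

  lt <- make_scenario("longterm")
  expect_gt(lt$ground_truth$direct_cont["lag1"], 0)
  expect_lt(lt$ground_truth$direct_cont["lag2"], 0)

  std <- make_scenario("standard")
  rev <- make_scenario("reversed")
  expect_false(std$reversed); expect_true(rev$reversed)
  # apart from the ordering switch, only the within-visit treatment-count
  # coefficients change
  expect_equal(std$f_model, rev$f_model)
  expect_equal(std$x_model, rev$x_model)
  expect_equal(std$v_model$rate[c("int", "f", "v", "age")],
               rev$v_model$rate[c("int", "f", "v", "age")])

  expect_error(make_scenario("bogus"))
  over <- make_scenario("standard", overrides = list(f_model = list(
    coef = c(x = 3))))
  expect_equal(unname(over$f_model$coef["x"]), 3)
})

test_that("identical (config, n, seed) give bit-identical panels", {
  cfg <- make_scenario("censoring")
  p1 <- simulate_cohort(cfg, 400, 123)
  p2 <- simulate_cohort(cfg, 400, 123)
  expect_identical(p1, p2)
  p3 <- simulate_cohort(cfg, 400, 124)
  expect_false(identical(p1$y_cont, p3$y_cont))
})

test_that("default cohorts match the registry calibration bands", {
  p <- simulate_cohort(make_scenario("standard"), 7500, 42)
  b <- p[p$visit == 0, ]
  expect_gt(mean(b$y_cont), 75); expect_lt(mean(b$y_cont), 90)
  expect_gt(mean(b$y_count), 4); expect_lt(mean(b$y_count), 13)
  expect_true(all(b$x == 0))
  expect_true(all(p$y_count[p$observed == 1] >= 0 &
                    p$y_count[p$observed == 1] <= 365))
  # treatment uptake rises over visits with both starts and stops
  uptake <- tapply(p$x, p$visit, mean)
  expect_true(all(diff(uptake) > 0))
  w <- matrix(p$x, nrow = 6)
  expect_gt(mean(apply(w, 2, function(r) any(diff(r) == -1))), 0.05)
})

test_that("fitted treatment probabilities respect positivity bounds", {
  for (s in 1:3) {
    p <- simulate_cohort(make_scenario("standard"), 7500, 100 + s)
    prop <- fit_propensity(p)
    pr <- predict(prop$denominator$fit, type = "response")
    expect_gt(min(pr), 0.005)
    expect_lt(max(pr), 0.995)
  }
})

test_that("confounding is present: both outcomes predict treatment", {
  p <- simulate_cohort(make_scenario("standard"), 20000, 77)
  prop <- fit_propensity(p)
  cf <- coef(prop$denominator)
  se <- sqrt(diag(prop$denominator$vcov_model))
  expect_lt(cf["y_cont_lag1"] / se["y_cont_lag1"], -3)  # negative, strong
  expect_gt(cf["log1p(y_count)"] / se["log1p(y_count)"], 3)
})

test_that("null scenario: adjusted treatment coefficient is null", {
  p <- simulate_cohort(make_scenario("null"), 5000, 88)
  av <- tdcausal:::analysis_view(p)
  dat <- av[av$visit >= 1, ]
  fit <- fit_glm(y_cont ~ x + x_lag1 + y_cont_lag1 + y_count + age,
                 dat, family = "linear", cluster = dat$id)
  se <- sqrt(diag(fit$vcov_sandwich))
  expect_lt(abs(coef(fit)["x"]) / se["x"], 3)
})

test_that("path tracing and counterfactual simulation agree", {
  # with the treatment-to-count and lung-function-to-count pathways switched
  # off, mediation runs only through the continuous outcome itself and the
  # lag effects have the closed form b_x * d_f^(k-1); common random numbers
  # make the contrast deterministic
  cfg <- make_scenario("standard",
                       overrides = list(v_model = list(
                         zero = c(x = 0, f = 0), rate = c(x = 0, f = 0))))
  te <- true_effects(cfg, 3, n = 4000, seed = 3)
  b_x <- cfg$f_model$coef[["x"]]
  d_f <- cfg$f_model$coef[["f"]]
  expect_equal(te$truth, b_x * d_f^(0:2), tolerance = 1e-9)

  # in the full standard scenario the lag-1 contrast is exactly the direct
  # coefficient (the current visit's count precedes treatment)
  std <- make_scenario("standard")
  te1 <- true_effects(std, 1, n = 4000, seed = 4)
  expect_equal(te1$truth, std$f_model$coef[["x"]], tolerance = 1e-12)
})

test_that("effect modification changes the population-average lag-1 effect", {
  em <- make_scenario("effectmod")
  te <- true_effects(em, 1, n = 150000, seed = 5)
  # population-average effect = b_x + ix * E[centred F among the population],
  # which differs from the value at the centre
  expect_gt(abs(te$truth[1] - em$f_model$coef[["x"]]), 0.02)
})

test_that("censoring scenario produces monotone MAR dropout", {
  p <- simulate_cohort(make_scenario("censoring"), 5000, 9)
  obs <- tapply(p$observed, p$visit, mean)
  expect_true(all(diff(obs) < 0))
  expect_gt(obs[6], 0.4); expect_lt(obs[6], 0.9)
  # dropout is predicted by the previous visit's health state
  cwfit <- censoring_weights(p)
  expect_true(all(cwfit$cw[!is.na(cwfit$cw)] > 0))
})
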