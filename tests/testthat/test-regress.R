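test_that("linear fit reproduces the normal-equations solution", {
  d <- data.frame(y = c(3.2, 1.1, 4.8, 2.0, 5.5),
                  a = c(1, 0, 1, 0, 1), b = c(0.2, 1.4, -0.7, 0.9, 0.0))
  fit <- fit_glm(y ~ a + b, d, family = "linear")
  X <- cbind(1, d$a, d$b)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-10)
  expect_true(is.numeric(fit$rmse))
})

test_that("rescaling all weights leaves coefficients unchanged", {
  set.seed(11)
  d <- data.frame(y = rnorm(200, 5), a = rbinom(200, 1, 0.5))
  d$cnt <- rpois(200, exp(0.5 + 0.3 * d$a))
  f1 <- fit_glm(y ~ a, d, family = "linear", weights = rep(7, 200))
  f2 <- fit_glm(y ~ a, d, family = "linear")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)

  g1 <- fit_glm(cnt ~ a, d, family = "negbin", weights = rep(7, 200))
  g2 <- fit_glm(cnt ~ a, d, family = "negbin")
  expect_equal(coef(g1), coef(g2), tolerance = 1e-6)

  d$z <- pmax(rpois(200, 4), 1)
  z1 <- fit_zinb(cnt ~ a, ~ a, d, weights = rep(7, 200))
  z2 <- fit_zinb(cnt ~ a, ~ a, d)
  expect_equal(z1$coefficients, z2$coefficients, tolerance = 1e-3)
})

test_that("rank deficiency and negative weights are handled as specified", {
  d <- data.frame(y = rnorm(20), a = 1)  # constant covariate
  fit <- fit_glm(y ~ a, d, family = "linear")
  expect_false(fit$converged)
  expect_null(fit$coefficients)
  expect_error(fit_glm(y ~ 1, d, family = "linear", weights = rep(-1, 20)),
               "strictly positive")
})

test_that("negative binomial refit recovers generating parameters", {
  set.seed(21)
  n <- 20000
  a <- rbinom(n, 1, 0.5)
  mu <- exp(1.0 + 0.6 * a)
  y <- rnbinom(n, size = 1.5, mu = mu)
  fit <- fit_glm(y ~ a, data.frame(y = y, a = a), family = "negbin")
  se <- sqrt(diag(fit$vcov_model))
  expect_lt(abs(coef(fit)["a"] - 0.6) / se["a"], 3)
  expect_lt(abs(coef(fit)["(Intercept)"] - 1.0) / se["(Intercept)"], 3)
})

test_that("zinb refit recovers generating parameters within 3 SEs", {
  set.seed(31)
  n <- 20000
  a <- rbinom(n, 1, 0.5)
  b <- rnorm(n)
  pi_ <- plogis(-0.4 + 0.5 * a - 0.3 * b)
  mu <- exp(1.6 - 0.4 * a + 0.25 * b)
  y <- ifelse(runif(n) < pi_, 0L, rnbinom(n, size = 1.4, mu = mu))
  fit <- fit_zinb(y ~ a + b, ~ a + b, data.frame(y = y, a = a, b = b))
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov_model))
  truth <- c(-0.4, 0.5, -0.3, 1.6, -0.4, 0.25, log(1.4))
  est <- fit$par
  expect_true(all(abs(est - truth) / se < 3.5))
})

test_that("zinb degenerate cases are flagged", {
  set.seed(41)
  d <- data.frame(y = rpois(300, 5) + 1L, a = rbinom(300, 1, 0.5))
  fit <- fit_zinb(y ~ a, ~ a, d)  # no zeros at all
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "no zero-inflation")

  # zero-inflation probability 0: count part matches a plain NB fit and the
  # zero-part intercept drifts to the boundary
  n <- 8000
  a <- rbinom(n, 1, 0.5)
  y <- rnbinom(n, size = 2, mu = exp(1.2 + 0.4 * a))
  d2 <- data.frame(y = y, a = a)
  z <- fit_zinb(y ~ a, ~ 1, d2)
  nb <- fit_glm(y ~ a, d2, family = "negbin")
  se_nb <- sqrt(diag(nb$vcov_model))
  expect_lt(abs(z$coefficients["a"] - coef(nb)["a"]) / se_nb["a"], 2)
  expect_true(z$boundary || plogis(z$zero$coefficients[1]) < 0.02)
})

test_that("sample_outcome draws from the fitted conditional distribution", {
  set.seed(51)
  d <- data.frame(y = 1 + 2 * (1:40) / 40, a = (1:40) / 40)
  exact <- fit_glm(y ~ a, d, family = "linear")
  expect_lt(exact$rmse, 1e-10)
  draw <- sample_outcome(exact, data.frame(a = 0.5))
  expect_equal(draw, unname(predict(exact$fit, data.frame(a = 0.5))),
               tolerance = 1e-8)

  # structural-zero probability 1 gives all-zero counts
  m <- hand_zinb(zero_coef = c(`(Intercept)` = 50),
                 count_coef = c(`(Intercept)` = 2), theta = 1.5,
                 formula_rhs = "1")
  expect_true(all(sample_outcome(m, data.frame(.dummy = 1:200)) == 0))

  bad <- tdcausal:::new_fitted_model("linear", NULL, converged = FALSE)
  expect_error(sample_outcome(bad, d), "non-converged")
})

test_that("mean and SD of repeated linear draws match the fitted model", {
  set.seed(61)
  d <- data.frame(y = rnorm(500, 10, 2), a = rnorm(500))
  fit <- fit_glm(y ~ a, d, family = "linear")
  nd <- data.frame(a = rep(0.3, 100000))
  draws <- sample_outcome(fit, nd)
  mu <- unname(predict(fit$fit, data.frame(a = 0.3)))
  se_mean <- fit$rmse / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu) / se_mean, 4)
  expect_equal(sd(draws), fit$rmse, tolerance = 0.02)
})

test_that("sandwich and model-based SEs agree on a correct unweighted fit", {
  set.seed(71)
  n <- 10000
  d <- data.frame(a = rnorm(n))
  d$y <- 1 + 0.5 * d$a + rnorm(n)
  fit <- fit_glm(y ~ a, d, family = "linear")
  r <- sqrt(diag(fit$vcov_sandwich)) / sqrt(diag(fit$vcov_model))
  expect_true(all(abs(r - 1) < 0.1))
})
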