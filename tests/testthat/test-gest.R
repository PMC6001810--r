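test_that("blanking at the same visit returns the outcome unchanged", {
  p <- simulate_cohort(make_scenario("standard"), 100, 53)
  b <- blank_outcomes(p, effects = numeric(0), max_lag = 1, family = "linear")
  same <- b[b$s == b$j, ]
  m <- match(paste(same$id, same$s), paste(p$id, p$visit))
  expect_equal(same$H, p$y_cont[m], tolerance = 1e-12)
})

test_that("blanking removes the stated effects on both scales", {
  pd <- data.frame(id = 1, visit = 0:2, x = c(0L, 0L, 1L),
                   y_cont = c(9, 9, 10), y_count = c(4L, 4L, 10L),
                   age = 20, observed = 1L)
  p <- as_panel(pd)
  bl <- blank_outcomes(p, effects = c(lag1 = 2), max_lag = 2,
                       family = "linear")
  expect_equal(bl$H[bl$j == 1 & bl$s == 2], 10 - 2 * 1)

  # multiplicative scale: treated the year before the count, log effect ln 2
  pd2 <- data.frame(id = 1, visit = 0:3, x = c(0L, 0L, 1L, 0L),
                    y_cont = 85, y_count = c(0L, 2L, 3L, 10L),
                    age = 20, observed = 1L)
  p2 <- as_panel(pd2)
  bl2 <- blank_outcomes(p2, effects = c(lag1 = log(2)), max_lag = 2,
                        family = "count_gamma")
  expect_equal(bl2$H[bl2$j == 1 & bl2$s == 3], 10 * exp(-log(2)))
  expect_error(blank_outcomes(p2, effects = numeric(0), max_lag = 3,
                              family = "linear"), "must contain")
})

test_that("horizon-1 g-estimation equals the propensity-adjusted SCMM", {
  p <- simulate_cohort(make_scenario("standard"), 1200, 59)
  prop <- fit_propensity(p)
  ge <- g_estimate(p, "linear", horizon = 1, propensity = prop)
  sc <- fit_scmm(p, "linear", propensity = prop)
  expect_equal(ge$estimate, sc$estimate[sc$term == "treat"],
               tolerance = 1e-10)
})

test_that("blip recovery when direct long-term effects are present", {
  cfg <- make_scenario("longterm")
  p <- simulate_cohort(cfg, 5000, 61)
  ge <- g_estimate(p, "linear", horizon = 2)
  truth <- true_effects(cfg, 2, n = 100000, seed = 7)
  expect_lt(abs(ge$estimate[1] - truth$truth[1]), 4 * ge$se[1])
  expect_lt(abs(ge$estimate[2] - truth$truth[2]), 4 * ge$se[2])
  # the lag-2 blip is negative here: direct effects counteract the benefit
  expect_lt(ge$estimate[2], ge$estimate[1])
})

test_that("the count family yields a single rate ratio per lag", {
  p <- simulate_cohort(make_scenario("standard"), 1500, 67)
  ge <- g_estimate(p, "count_gamma", horizon = 2)
  expect_equal(unique(ge$part), "rate")
  expect_equal(ge$lag, 1:2)
  # treated years reduce the subsequent rate of treatment days
  expect_lt(ge$estimate[1], 0)
})

test_that("pooled and sequential modes agree at horizon one", {
  p <- simulate_cohort(make_scenario("standard"), 800, 71)
  prop <- fit_propensity(p)
  a <- g_estimate(p, "linear", horizon = 1, propensity = prop,
                  mode = "sequential")
  b <- g_estimate(p, "linear", horizon = 1, propensity = prop,
                  mode = "pooled")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
})
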