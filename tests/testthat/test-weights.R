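test_that("numerator terms are restricted to history and baseline", {
  p <- simulate_cohort(make_scenario("standard"), 200, 1)
  expect_silent(fit_propensity(p, numerator = x ~ x_lag1))
  expect_error(fit_propensity(p, numerator = x ~ y_count),
               "treatment history")
  expect_error(fit_propensity(p, numerator = x ~ y_cont_lag1),
               "treatment history")
})

test_that("identical numerator and denominator give unit weights", {
  p <- simulate_cohort(make_scenario("standard"), 300, 2)
  f <- x ~ x_lag1 + factor(visit)
  prop <- fit_propensity(p, denominator = f, numerator = f)
  ws <- stabilized_weights(p, prop)
  expect_equal(ws$sw[!is.na(ws$sw)], rep(1, sum(!is.na(ws$sw))),
               tolerance = 1e-12)
})

test_that("stabilized weights are running products of per-visit ratios", {
  p <- simulate_cohort(make_scenario("standard"), 400, 3)
  prop <- fit_propensity(p)
  ws <- stabilized_weights(p, prop)
  # cumulative-product consistency on every row
  for (t in 1:5) {
    now <- ws[ws$visit == t, ]
    prev <- ws[ws$visit == t - 1, ]
    expect_equal(now$sw, prev$sw * now$fac, tolerance = 1e-12)
  }
  # hand recomputation for one treated person-visit from the fitted models
  dat <- prop$data
  i <- which(dat$visit == 2)[1]
  p_den <- predict(prop$denominator$fit, newdata = dat[dat$id == dat$id[i] &
                                                         dat$visit <= 2, ],
                   type = "response")
  p_num <- predict(prop$numerator$fit, newdata = dat[dat$id == dat$id[i] &
                                                       dat$visit <= 2, ],
                   type = "response")
  xi <- dat$x[dat$id == dat$id[i] & dat$visit <= 2]
  fac <- ifelse(xi == 1, p_num, 1 - p_num) / ifelse(xi == 1, p_den, 1 - p_den)
  expect_equal(ws$sw[ws$id == dat$id[i] & ws$visit == 2], prod(fac),
               tolerance = 1e-10)
  # stabilization: mean weight near one at every visit
  mw <- tapply(ws$sw, ws$visit, mean, na.rm = TRUE)
  expect_true(all(abs(mw - 1) < 0.1))
})

test_that("origin-indexed weights reduce to the ordinary stabilized weight", {
  p <- simulate_cohort(make_scenario("standard"), 300, 4)
  ws <- stabilized_weights(p, fit_propensity(p))
  h1 <- ha_weights(ws, origin = 1)
  m <- match(paste(h1$id, h1$visit), paste(ws$id, ws$visit))
  expect_equal(h1$w, ws$sw[m], tolerance = 1e-12)
  # single-factor weight when origin equals the outcome visit
  h3 <- ha_weights(ws, origin = 3)
  m3 <- match(paste(h3$id[h3$visit == 3], 3), paste(ws$id, ws$visit))
  expect_equal(h3$w[h3$visit == 3], ws$fac[m3], tolerance = 1e-12)
  # origin 2 on a three-visit window multiplies factors for visits 2 and 3
  h2 <- ha_weights(ws, origin = 2)
  m2a <- match(paste(h2$id[h2$visit == 3], 2), paste(ws$id, ws$visit))
  m2b <- match(paste(h2$id[h2$visit == 3], 3), paste(ws$id, ws$visit))
  expect_equal(h2$w[h2$visit == 3], ws$fac[m2a] * ws$fac[m2b],
               tolerance = 1e-12)
  expect_error(ha_weights(ws, 0), "origin")
})

test_that("censoring weights are unit without censoring, stabilized with", {
  p <- simulate_cohort(make_scenario("standard"), 200, 5)
  cw <- censoring_weights(p)
  expect_true(all(cw$cw == 1))

  pc <- simulate_cohort(make_scenario("censoring"), 3000, 6)
  cwc <- censoring_weights(pc)
  obs_rows <- !is.na(cwc$cw)
  expect_true(all(cwc$cw[obs_rows] > 0))
  expect_true(all(abs(tapply(cwc$cw, cwc$visit, mean, na.rm = TRUE) - 1)
                  < 0.25))
  # censored person-visits carry no weight
  m <- match(paste(pc$id, pc$visit), paste(cwc$id, cwc$visit))
  expect_true(all(is.na(cwc$cw[m][pc$observed == 0])))
})

test_that("truncation clamps at empirical percentiles and is idempotent", {
  ws <- structure(data.frame(id = 1:100, visit = 1, p = 0.5, fac = 1,
                             sw = as.numeric(1:100)),
                  class = c("weight_set", "data.frame"))
  none <- truncate_weights(ws, 0, 100)
  expect_equal(none$sw, ws$sw)
  tr <- truncate_weights(ws, 1, 99)
  q <- quantile(as.numeric(1:100), c(0.01, 0.99), names = FALSE)
  expect_equal(min(tr$sw), q[1])
  expect_equal(max(tr$sw), q[2])
  tr2 <- truncate_weights(tr, 1, 99)
  expect_equal(tr2$sw, tr$sw)
  expect_error(truncate_weights(ws, 99, 1), "lo < hi")
})

test_that("weighting balances the confounder between treatment groups", {
  p <- simulate_cohort(make_scenario("standard"), 20000, 7)
  ws <- stabilized_weights(p, fit_propensity(p))
  av <- tdcausal:::analysis_view(p)
  dat <- av[av$visit >= 1, ]
  dat$w <- ws$sw[match(paste(dat$id, dat$visit), paste(ws$id, ws$visit))]
  raw <- fit_glm(x ~ log1p(y_count) + factor(visit), dat, family = "linear")
  wtd <- fit_glm(x ~ log1p(y_count) + factor(visit), dat, family = "linear",
                 weights = dat$w)
  expect_lt(abs(coef(wtd)["log1p(y_count)"]),
            abs(coef(raw)["log1p(y_count)"]) / 2)
})
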