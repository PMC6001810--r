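test_that("a well-formed panel validates and round-trips through CSV", {
  panel <- toy_panel()
  expect_s3_class(panel, "panel_df")
  expect_equal(nrow(panel), 6)

  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  for (col in c("id", "visit", "x", "y_count", "observed")) {
    expect_identical(as.numeric(back[[col]]), as.numeric(panel[[col]]))
  }
  expect_equal(back$y_cont, panel$y_cont, tolerance = 1e-12)
  expect_equal(back$age, panel$age, tolerance = 1e-12)
})

test_that("simulator output survives a write/read round-trip", {
  panel <- simulate_cohort(make_scenario("standard"), 60, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(as.numeric(back$y_count), as.numeric(panel$y_count))
  expect_identical(as.numeric(back$x), as.numeric(panel$x))
  expect_equal(back$y_cont, panel$y_cont, tolerance = 1e-12)
})

test_that("schema renaming maps file columns onto panel columns", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  d <- as.data.frame(panel)
  names(d)[names(d) == "x"] <- "treated"
  utils::write.csv(d, path, row.names = FALSE)
  back <- read_panel(path, schema = c(x = "treated"))
  expect_equal(back$x, panel$x)
  expect_error(read_panel(path, schema = c(x = "nope")), "absent file columns")
})

test_that("structural violations are rejected with person and visit named", {
  base <- as.data.frame(toy_panel())
  gap <- base[base$id != 1 | base$visit != 1, ]  # person 1: visits 0, 2
  expect_error(as_panel(gap), "gap in visit sequence for person 1")

  treated0 <- base
  treated0$x[treated0$id == 2 & treated0$visit == 0] <- 1
  expect_error(as_panel(treated0), "treated at visit 0")

  big <- base
  big$y_count[3] <- 400
  expect_error(as_panel(big), "outside \\[0, 365\\]")

  revive <- base
  revive$observed[revive$id == 1] <- c(1, 0, 1)
  expect_error(as_panel(revive), "observed again after censoring")
})

test_that("lagged_view shifts within persons and marks pre-baseline as NA", {
  panel <- toy_panel()
  lv <- lagged_view(panel, lags = c(1, 2))
  expect_equal(nrow(lv), nrow(panel))
  expect_equal(lv$x_lag1[lv$id == 1], c(NA, 0, 1))
  expect_equal(lv$y_cont_lag1[lv$id == 2], c(NA, 90, 88))
  # lag beyond the panel depth is all-missing
  lv3 <- lagged_view(panel, lags = 3)
  expect_true(all(is.na(lv3$x_lag3)))
  expect_error(lagged_view(panel, lags = 0), "positive integers")
})

test_that("a lag-2 view equals two composed lag-1 views", {
  panel <- simulate_cohort(make_scenario("standard"), 30, 9)
  lv2 <- lagged_view(panel, lags = 2)
  once <- lagged_view(panel, lags = 1)
  # shift the lag-1 column by one more visit within person
  twice <- tdcausal:::lag_within(once$x_lag1, once$id, 1)
  expect_identical(lv2$x_lag2, twice)
})
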