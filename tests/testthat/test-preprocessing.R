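test_that("concatenation preserves order and inserts spacers under mask policy", {
  m1 <- cbind(happy = c(1, 2, 3), sad = c(4, 5, 6))
  m2 <- cbind(happy = c(7, 6, 5), sad = c(3, 2, 1))
  panel <- make_tiny_panel(list(`1` = m1, `2` = m2))

  naive <- concatenate_series(panel, c("happy", "sad"),
                              boundary_policy = "naive")
  expect_equal(nrow(naive$values), 6)
  expect_equal(naive$boundary_index, c(1, 4))
  expect_equal(naive$values[, "happy"], c(1, 2, 3, 7, 6, 5))

  masked <- concatenate_series(panel, c("happy", "sad"),
                               boundary_policy = "mask", tau_max = 2)
  expect_equal(nrow(masked$values), 8)
  expect_true(all(is.na(masked$values[4:5, ])))
  expect_equal(masked$boundary_index, c(1, 6))
  expect_equal(masked$values[6:8, "happy"], c(7, 6, 5))

  single <- make_tiny_panel(list(`1` = m1))
  s_naive <- concatenate_series(single, boundary_policy = "naive")
  s_mask <- concatenate_series(single, boundary_policy = "mask", tau_max = 5)
  expect_equal(s_naive$values, s_mask$values)

  expect_error(concatenate_series(panel, "nope"), "Available")
})

test_that("mask policy keeps lagged pairs within subjects (boundary safety)", {
  spec <- make_group_preset("HC_like")
  panel <- simulate_panel(spec, 6, seed = 31)
  tau <- 4
  s <- concatenate_series(panel, boundary_policy = "mask", tau_max = tau)
  subj_of <- rep(NA_integer_, nrow(s$values))
  for (i in seq_along(s$boundary_index)) {
    from <- s$boundary_index[i]
    to <- if (i < length(s$boundary_index)) {
      s$boundary_index[i + 1] - tau - 1
    } else nrow(s$values)
    subj_of[from:to] <- i
  }
  for (lag in seq_len(tau)) {
    t_idx <- (lag + 1):nrow(s$values)
    both_obs <- !is.na(s$values[t_idx, 1]) & !is.na(s$values[t_idx - lag, 1])
    cross <- subj_of[t_idx] != subj_of[t_idx - lag]
    expect_false(any(both_obs & cross, na.rm = TRUE))
  }
})

test_that("midscale imputation fills missing Likert cells with 4, idempotently", {
  m <- cbind(happy = c(1, NA, 3, NA, NA), at_home = c(0, 15, NA, 45, 60))
  panel <- make_tiny_panel(list(`1` = m))
  attr(panel, "scales") <- c(happy = "likert_1_7",
                             at_home = "minutes_0_60_step15")
  s <- concatenate_series(panel, boundary_policy = "naive")

  imp <- impute_midscale(s, "happy")
  expect_equal(imp$values[, "happy"], c(1, 4, 3, 4, 4))
  expect_false(any(imp$missing_mask[, "happy"]))
  # untouched other variable
  expect_true(is.na(imp$values[3, "at_home"]))
  # idempotent
  expect_identical(impute_midscale(imp, "happy"), imp)
  # empty list is a no-op; fully observed variable unchanged
  expect_identical(impute_midscale(s, character(0)), s)
  expect_error(impute_midscale(s, "at_home"), "Likert")
})

test_that("spacer rows are never imputed", {
  m1 <- cbind(happy = c(1, NA)); m2 <- cbind(happy = c(7, 7))
  panel <- make_tiny_panel(list(`1` = m1, `2` = m2))
  s <- concatenate_series(panel, boundary_policy = "mask", tau_max = 3)
  imp <- impute_midscale(s, "happy")
  expect_equal(imp$values[, "happy"], c(1, 4, NA, NA, NA, 7, 7))
})

test_that("blank counts are interpreted as zero", {
  m <- cbind(friends = c(NA, 1, NA, 0), happy = c(NA, 2, 3, 4))
  panel <- make_tiny_panel(list(`1` = m))
  attr(panel, "scales") <- c(friends = "indicator", happy = "likert_1_7")
  s <- concatenate_series(panel, boundary_policy = "naive")
  z <- blank_counts_to_zero(s, "friends")
  expect_equal(z$values[, "friends"], c(0, 1, 0, 0))
  expect_false(any(z$missing_mask[, "friends"]))
  expect_true(is.na(z$values[1, "happy"]))
  # no blanks: unchanged
  expect_identical(blank_counts_to_zero(z, "friends"), z)
  expect_error(blank_counts_to_zero(s, "happy"), "count/indicator")
  expect_error(blank_counts_to_zero(s, "nope"), "Available")
})

test_that("ADF rejects for stationary AR(1) and not for a random walk", {
  ar <- withr::with_seed(101, as.numeric(arima.sim(list(ar = 0.4), 2000)))
  res_ar <- adf_test(ar)
  expect_lt(res_ar$p_value, 0.01)
  expect_true(res_ar$stationary)

  rw <- withr::with_seed(202, cumsum(rnorm(2000)))
  res_rw <- adf_test(rw)
  expect_gt(res_rw$p_value, 0.10)

  expect_error(adf_test(rep(3, 100)), "constant")
  expect_error(adf_test(rnorm(10)), "25")
})

test_that("ADF statistic matches the reference implementation on a frozen series", {
  # expected values computed with statsmodels adfuller(regression='c',
  # autolag='AIC') on this exact seed-42 AR(1) draw
  y <- withr::with_seed(42, as.numeric(arima.sim(list(ar = 0.4), 500)))
  res <- adf_test(y)
  expect_equal(res$statistic, -15.183083456916751, tolerance = 1e-9)
  expect_equal(res$lag_order, 0L)
  expect_equal(res$p_value, 6.158315481084252e-28, tolerance = 1e-6)
})

test_that("preprocessing report summarizes missingness and stationarity", {
  spec <- make_group_preset("HC_like")
  panel <- apply_missingness(simulate_panel(spec, 12, seed = 3), 0.1, seed = 4)
  s <- concatenate_series(panel, c("happy", "sad"), tau_max = 3)
  rep <- preprocessing_report(s)
  expect_equal(rep$variable, c("happy", "sad"))
  expect_true(all(rep$missing_fraction > 0.05 & rep$missing_fraction < 0.2))
  expect_true(all(rep$stationary))
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocessing_report(rep, path, "mask")
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$policy, "mask")
  expect_equal(nrow(parsed$variables), 2)
})
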