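test_that("condition selection keeps roughly alpha-level false candidates under the null", {
  vars <- c("a", "b", "c")
  counts <- integer(0)
  for (seed in 1:50) {
    s <- make_noise_series(5000, vars, seed = seed)
    sel <- pc_condition_selection(s, "a", tau_max = 3, pc_alpha = 0.05)
    counts <- c(counts, nrow(sel))
  }
  expected <- 0.05 * length(vars) * 3
  # iterated re-testing prunes some borderline candidates, so the mean sits
  # at or somewhat below the one-pass binomial expectation
  upper <- expected + 3 * sqrt(expected * 0.95 / 50)
  expect_lte(mean(counts), upper)
  expect_gt(mean(counts), 0)
})

test_that("condition selection retains a planted parent with high probability", {
  b1 <- matrix(0, 2, 2); b1[2, 1] <- 0.5
  hits <- 0
  for (seed in 1:50) {
    s <- make_noise_series(5000, c("x", "y"), seed = 100 + seed, b1 = b1)
    sel <- pc_condition_selection(s, "y", tau_max = 3, pc_alpha = 0.05)
    if (any(sel$var == "x" & sel$lag == 1)) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% of 50 seeds
})

test_that("single-variable pure noise yields at most a rare self-lag candidate", {
  hits <- integer(0)
  for (seed in 1:30) {
    s <- make_noise_series(2000, "x", seed = 300 + seed)
    sel <- pc_condition_selection(s, "x", tau_max = 1, pc_alpha = 0.05)
    hits <- c(hits, nrow(sel))
  }
  expect_lte(mean(hits), 0.2)  # ~ pc_alpha
  s <- make_noise_series(2000, "x", seed = 1)
  expect_error(pc_condition_selection(s, "x", tau_max = 0), "tau_max")
})

test_that("MCI link test is calibrated under the null and finds planted links", {
  # type-I: two independent AR(1) variables, test cross-links at lags 1..5
  b1 <- diag(0.4, 2)
  p_values <- c()
  for (seed in 1:20) {
    s <- make_noise_series(5000, c("x", "y"), seed = 400 + seed, b1 = b1)
    px <- pc_condition_selection(s, "x", tau_max = 5, pc_alpha = 0.05)
    py <- pc_condition_selection(s, "y", tau_max = 5, pc_alpha = 0.05)
    for (lag in 1:5) {
      p_values <- c(
        p_values,
        mci_link_test(s, "x", lag, "y", py, px)$p_value,
        mci_link_test(s, "y", lag, "x", px, py)$p_value
      )
    }
  }
  rate <- mean(p_values < 0.01)  # 200 simulated links
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.03)

  # planted lag-1 link: estimated weight near the closed-form partial
  # correlation of the generating model, with the right sign
  b1 <- matrix(c(0.4, 0, 0.3, 0.4), 2, 2, byrow = TRUE)
  spec <- svar_spec(c("x", "y"), blags = list(b1))
  nodes <- data.frame(var = c("y", "x", "y", "x"), lag = c(0, 1, 1, 2))
  truth <- oracle_pcor_from_cov(oracle_joint_cov(spec, nodes))
  s <- make_noise_series(5000, c("x", "y"), seed = 990, b1 = b1)
  res <- mci_link_test(s, "x", 1, "y",
                       parents_target = tibble::tibble(var = c("y", "x"),
                                                       lag = c(1L, 1L)),
                       parents_source = tibble::tibble(var = "x", lag = 1L))
  expect_gt(res$weight, 0)
  expect_lt(abs(res$weight - truth), 0.1)

  # autoregression is recovered as a positive self-link
  auto <- mci_link_test(s, "x", 1, "x",
                        parents_target = tibble::tibble(var = character(),
                                                        lag = integer()),
                        parents_source = tibble::tibble(var = character(),
                                                        lag = integer()))
  expect_gt(auto$weight, 0.2)
  expect_lt(auto$p_value, 1e-10)
})

test_that("a single AR(1) variable yields only its self-lag link", {
  spec <- svar_spec("x", blags = list(matrix(0.4, 1, 1)))
  panel <- simulate_panel(spec, 60, seed = 17)
  s <- concatenate_series(panel, tau_max = 5)
  net <- estimate_network(s, tau_max = 5)
  expect_true(all(net$links$source == "x" & net$links$target == "x"))
  expect_true(any(net$links$lag == 1))
  expect_gt(net$links$weight[net$links$lag == 1], 0)
})

test_that("estimation is deterministic and invariant to variable order", {
  spec <- make_group_preset("HC_like")
  panel <- apply_missingness(simulate_panel(spec, 20, seed = 5), 0.05, seed = 6)
  vars <- c("happy", "sad", "relax")
  s1 <- concatenate_series(panel, vars, tau_max = 3)
  s2 <- concatenate_series(panel, rev(vars), tau_max = 3)
  n1 <- estimate_network(s1, tau_max = 3)
  n2 <- estimate_network(s2, tau_max = 3)
  expect_identical(n1$links, estimate_network(s1, tau_max = 3)$links)
  l1 <- dplyr::arrange(n1$links, .data$lag, .data$target, .data$source)
  l2 <- dplyr::arrange(n2$links, .data$lag, .data$target, .data$source)
  expect_equal(l1$source, l2$source)
  expect_equal(l1$weight, l2$weight, tolerance = 1e-12)
})

test_that("contemporaneous links are stored once per unordered pair", {
  spec <- make_group_preset("HC_like")
  panel <- simulate_panel(spec, 40, seed = 8)
  s <- concatenate_series(panel, c("happy", "relax", "sad"), tau_max = 3)
  net <- estimate_network(s, tau_max = 3)
  con <- net$links[net$links$lag == 0, ]
  expect_true(all(con$source < con$target))
  expect_true(!any(duplicated(paste(con$source, con$target))))
  # the planted happy-relax contemporaneous association is found, positive
  expect_true(any(con$source == "happy" & con$target == "relax" &
                    con$weight > 0))
})

test_that("more than ten variables triggers a warning but the run completes", {
  vars <- paste0("v", sprintf("%02d", 1:12))
  spec <- svar_spec(vars, blags = list(diag(0.3, 12)))
  panel <- simulate_panel(spec, 12, seed = 2)
  s <- concatenate_series(panel, tau_max = 2)
  expect_warning(net <- estimate_network(s, tau_max = 2), "10 variables")
  expect_s3_class(net, "ema_network")
})
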