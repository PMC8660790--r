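#' @noRd
new_ema_network <- function(links, variable_names, alpha, tau_max,
                            pc_alpha = NA_real_, parents = NULL) {
  structure(
    list(
      links = links, variable_names = variable_names,
      alpha = alpha, tau_max = tau_max, pc_alpha = pc_alpha,
      parents = parents
    ),
    class = "ema_network"
  )
}

#' PC-style selection of a variable's lagged parents
#'
#' Iterative partial-correlation screening of all `(variable, lag)` candidate
#' parents of `target` for lags `1..tau_max`. At iteration `k` every
#' surviving candidate is tested conditional on its `k` strongest surviving
#' co-candidates (by absolute partial correlation from the previous
#' iteration); candidates with `p >= pc_alpha` are removed after the full
#' pass, and iterations continue with growing `k` until no candidate has `k`
#' co-candidates left. This is the condition-selection stage that screens
#' parents before the momentary-conditional-independence tests.
#'
#' @param series An `ema_series`.
#' @param target Target variable name.
#' @param tau_max Maximum lag (>= 1), in survey steps.
#' @param pc_alpha Screening significance level.
#' @param max_conds Cap on the conditioning-set size (default unlimited).
#' @return A tibble of surviving candidates, strongest first: `var`, `lag`,
#'   `r`, `p_value`.
#' @export
pc_condition_selection <- function(series, target, tau_max = 14,
                                   pc_alpha = 0.05, max_conds = Inf) {
  stopifnot(inherits(series, "ema_series"))
  if (tau_max < 1) abort("tau_max must be >= 1.")
  check_variables(target, series$variable_names, "series")
  emb <- build_lag_matrix(series$values, tau_max)
  .pc_select(emb, target, series$variable_names, tau_max, pc_alpha, max_conds)
}

#' @noRd
.pc_select <- function(emb, target, variables, tau_max, pc_alpha, max_conds) {
  cand <- tidyr::expand_grid(var = variables, lag = seq_len(tau_max))
  cand$col <- lag_col(cand$var, cand$lag)
  cand$absr <- Inf  # untested candidates sort first within ties
  cand$r_signed <- NA_real_
  cand$p <- NA_real_
  ycol <- lag_col(target, 0)
  k <- 0
  repeat {
    if (nrow(cand) == 0) break
    if (k > min(max_conds, nrow(cand) - 1)) break
    ord <- order(-cand$absr, cand$var, cand$lag)
    cand <- cand[ord, ]
    keep <- logical(nrow(cand))
    newr <- numeric(nrow(cand))
    newp <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      others <- setdiff(seq_len(nrow(cand)), i)
      conds <- head(others, k)  # k strongest co-candidates
      m <- emb[, c(ycol, cand$col[i], cand$col[conds]), drop = FALSE]
      res <- tryCatch(.pcor_core(m), error = function(e) NULL)
      if (is.null(res)) {
        keep[i] <- FALSE
        newr[i] <- 0; newp[i] <- 1
      } else {
        keep[i] <- res$p < pc_alpha
        newr[i] <- res$r; newp[i] <- res$p
      }
    }
    cand$r_signed <- newr
    cand$absr <- abs(newr)
    cand$p <- newp
    removed <- !all(keep)
    cand <- cand[keep, , drop = FALSE]
    k <- k + 1
    if (!removed && k > min(max_conds, max(0, nrow(cand) - 1))) break
  }
  ord <- order(-cand$absr, cand$var, cand$lag)
  cand <- cand[ord, , drop = FALSE]
  tibble::tibble(
    var = cand$var, lag = as.integer(cand$lag),
    r = cand$r_signed, p_value = cand$p
  )
}

#' Momentary-conditional-independence test of one lagged link
#'
#' Tests `source` at `t - lag` against `target` at `t`, conditioning on the
#' selected lagged parents of the target (minus the tested link) and on the
#' time-shifted lagged parents of the source. Conditioning on both parent
#' sets controls false positives from autocorrelation and common drivers.
#'
#' @param series An `ema_series`.
#' @param source,target Variable names.
#' @param lag Positive lag in survey steps.
#' @param parents_target,parents_source Tibbles with columns `var`, `lag`
#'   (as returned by [pc_condition_selection()]).
#' @return A one-row tibble link: `source`, `target`, `lag`, `weight`,
#'   `p_value`, `n_eff`.
#' @export
mci_link_test <- function(series, source, lag, target,
                          parents_target, parents_source) {
  stopifnot(inherits(series, "ema_series"), lag >= 1)
  check_variables(c(source, target), series$variable_names, "series")
  depth <- max(lag + max_mci_lag(parents_source),
               max_mci_lag(parents_target), lag)
  emb <- build_lag_matrix(series$values, depth)
  .mci_test(emb, source, lag, target, parents_target, parents_source)
}

#' @noRd
max_mci_lag <- function(parents) {
  if (is.null(parents) || nrow(parents) == 0) 0L else max(parents$lag)
}

#' @noRd
.mci_test <- function(emb, source, lag, target, parents_target,
                      parents_source) {
  zt <- parents_target[!(parents_target$var == source &
                           parents_target$lag == lag), , drop = FALSE]
  zs <- parents_source
  cols <- character(0)
  if (nrow(zt) > 0) cols <- lag_col(zt$var, zt$lag)
  if (!is.null(zs) && nrow(zs) > 0) {
    cols <- c(cols, lag_col(zs$var, zs$lag + lag))
  }
  cols <- setdiff(unique(cols), c(lag_col(target, 0), lag_col(source, lag)))
  m <- emb[, c(lag_col(target, 0), lag_col(source, lag), cols),
           drop = FALSE]
  res <- .pcor_core(m)
  tibble::tibble(
    source = source, target = target, lag = as.integer(lag),
    weight = res$r, p_value = res$p, n_eff = res$n
  )
}

#' Estimate a contemporaneous + lagged partial-correlation network
#'
#' The estimation engine: for each variable, candidate lagged parents are
#' screened with [pc_condition_selection()]; every ordered pair and lag
#' `1..tau_max` (including self-lags) is then tested with the
#' momentary-conditional-independence test, and links significant at `alpha`
#' are kept as signed directed lagged links. Contemporaneous (lag-0) links
#' are the correlations of same-time residuals — each variable regressed on
#' its selected lagged parents — kept at `alpha` and stored once per
#' unordered pair (undirected; degrees of freedom are charged for both
#' parent sets). Rows enter a test only when the target, the lagged source,
#' and every conditioned value are non-missing.
#'
#' @param series An `ema_series`.
#' @param tau_max Maximum lag in survey steps (default 14 = two days at
#'   seven surveys/day).
#' @param alpha Reporting significance level for links (default 0.01).
#' @param pc_alpha Screening level for condition selection.
#' @param max_conds Cap on conditioning-set size during screening.
#' @return An `ema_network`: `links` tibble (`source`, `target`, `lag`,
#'   `weight`, `p_value`, `n_eff`; lag 0 = contemporaneous, undirected,
#'   stored with `source < target`), variable names, thresholds and the
#'   selected parent sets.
#' @export
#' @examples
#' panel <- simulate_panel(make_group_preset("HC_like"), 30, seed = 1)
#' series <- concatenate_series(panel, c("happy", "relax"), tau_max = 3)
#' net <- estimate_network(series, tau_max = 3)
#' tidy(net)
estimate_network <- function(series, tau_max = 14, alpha = 0.01,
                             pc_alpha = 0.05, max_conds = Inf) {
  stopifnot(inherits(series, "ema_series"))
  vars <- series$variable_names
  if (length(vars) < 1) abort("estimate_network needs at least 1 variable.")
  if (length(vars) > 10) {
    warn(sprintf(
      "Network over %d variables; interpretability and power degrade beyond 10 variables.",
      length(vars)
    ))
  }
  if (tau_max < 1) abort("tau_max must be >= 1.")
  if (series$policy == "mask" && !is.na(series$tau_max) &&
      series$tau_max < tau_max) {
    warn("Series spacer width is smaller than tau_max; lagged samples may span subjects.")
  }
  # embedding large enough for MCI source-parent shifts (lag + parent lag)
  emb <- build_lag_matrix(series$values, 2L * tau_max)

  parents <- purrr::map(
    stats::setNames(vars, vars),
    function(v) .pc_select(emb, v, vars, tau_max, pc_alpha, max_conds)
  )

  lagged <- purrr::map(vars, function(target) {
    purrr::map(vars, function(source) {
      purrr::map(seq_len(tau_max), function(lag) {
        tryCatch(
          .mci_test(emb, source, lag, target,
                    parents[[target]], parents[[source]]),
          error = function(e) NULL
        )
      }) |> purrr::compact() |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  lagged <- dplyr::filter(lagged, .data$p_value < alpha)

  contemp <- .contemporaneous_links(series$values, parents, alpha)

  links <- dplyr::bind_rows(lagged, contemp) |>
    dplyr::arrange(.data$lag, .data$target, .data$source)
  new_ema_network(links, vars, alpha, as.integer(tau_max),
                  pc_alpha = pc_alpha, parents = parents)
}

# Residuals of each variable on its selected lagged parents (with intercept),
# NA wherever the variable or any parent value is missing; pairwise
# correlation of residuals with df charged for both parent sets.
#' @noRd
.contemporaneous_links <- function(values, parents, alpha) {
  vars <- colnames(values)
  if (length(vars) < 2) return(NULL)
  tau_need <- max(c(1L, purrr::map_int(parents, max_mci_lag)))
  emb <- build_lag_matrix(values, tau_need)
  resid_mat <- matrix(NA_real_, nrow(values), length(vars))
  colnames(resid_mat) <- vars
  n_par <- integer(length(vars))
  names(n_par) <- vars
  for (v in vars) {
    pv <- parents[[v]]
    n_par[v] <- nrow(pv)
    y <- values[, v]
    if (nrow(pv) == 0) {
      resid_mat[, v] <- y - mean(y, na.rm = TRUE)
      resid_mat[is.na(y), v] <- NA
      next
    }
    x <- emb[, lag_col(pv$var, pv$lag), drop = FALSE]
    ok <- !is.na(y) & complete.cases(x)
    fit <- stats::lm.fit(cbind(1, x[ok, , drop = FALSE]), y[ok])
    resid_mat[ok, v] <- fit$residuals
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    a <- resid_mat[, pr[1]]
    b <- resid_mat[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    extra_df <- unname(n_par[pr[1]] + n_par[pr[2]])
    if (n <= extra_df + 4) return(NULL)
    r <- suppressWarnings(cor(a[ok], b[ok]))
    if (is.na(r)) return(NULL)
    df <- n - 2 - extra_df
    tstat <- if (abs(r) >= 1) Inf else r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
    if (p >= alpha) return(NULL)
    tibble::tibble(
      source = min(pr), target = max(pr), lag = 0L,
      weight = r, p_value = p, n_eff = n
    )
  }) |> purrr::compact() |> purrr::list_rbind()
}

#' @export
print.ema_network <- function(x, ...) {
  nl <- x$links
  cat(sprintf(
    "<ema_network> %d variables, %d links (%d contemporaneous, %d lagged) at alpha = %s, tau_max = %d\n",
    length(x$variable_names), nrow(nl), sum(nl$lag == 0), sum(nl$lag > 0),
    format(x$alpha), x$tau_max
  ))
  invisible(x)
}

#' @describeIn estimate_network Tidy the significant links of a network.
#' @param x An `ema_network`.
#' @param ... Unused.
#' @export
tidy.ema_network <- function(x, ...) {
  x$links
}

#' @describeIn estimate_network One-row network summary (node/link counts
#'   and densities).
#' @export
glance.ema_network <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variable_names),
    n_links = nrow(x$links),
    n_contemporaneous = sum(x$links$lag == 0),
    n_lagged = sum(x$links$lag > 0),
    density_count = network_density(x, "count"),
    density_weight = network_density(x, "weight"),
    alpha = x$alpha,
    tau_max = x$tau_max
  )
}
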