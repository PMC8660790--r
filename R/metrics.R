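# Expand a network to a named weight vector over (pair, channel) slots.
# Lagged channel: one slot per ordered pair, the signed weight of the
# strongest-|weight| significant link across lags (or the sum over lags);
# contemporaneous channel: one slot per unordered pair. Absent links are 0.
#' @noRd
edge_vector <- function(net, lag_aggregate = c("max", "sum"),
                        include_self = FALSE) {
  lag_aggregate <- match.arg(lag_aggregate)
  vars <- sort(net$variable_names)
  ordered <- expand.grid(source = vars, target = vars,
                         stringsAsFactors = FALSE)
  if (!include_self) ordered <- ordered[ordered$source != ordered$target, ]
  lag_slots <- paste0("lagged:", ordered$source, "->", ordered$target)
  un <- utils::combn(vars, 2)
  con_slots <- paste0("contemporaneous:", un[1, ], "--", un[2, ])
  w <- stats::setNames(rep(0, length(lag_slots) + length(con_slots)),
                       c(lag_slots, con_slots))

  links <- net$links
  lag_links <- links[links$lag > 0, , drop = FALSE]
  if (!include_self) {
    lag_links <- lag_links[lag_links$source != lag_links$target, , drop = FALSE]
  }
  if (nrow(lag_links) > 0) {
    key <- paste0("lagged:", lag_links$source, "->", lag_links$target)
    for (k in unique(key)) {
      ws <- lag_links$weight[key == k]
      w[k] <- if (lag_aggregate == "max") ws[which.max(abs(ws))] else sum(ws)
    }
  }
  con_links <- links[links$lag == 0, , drop = FALSE]
  if (nrow(con_links) > 0) {
    a <- pmin(con_links$source, con_links$target)
    b <- pmax(con_links$source, con_links$target)
    w[paste0("contemporaneous:", a, "--", b)] <- con_links$weight
  }
  w
}

#' Network goodness-of-fit R-squared between two estimated networks
#'
#' A similarity statistic: both networks are expanded over the same
#' (pair, channel) slots — one lagged slot per ordered variable pair (the
#' signed weight of the strongest-magnitude significant link across lags)
#' and one contemporaneous slot per unordered pair — with absent links
#' contributing exactly 0, and the statistic is
#' `1 - sum((w_A - w_B)^2)`. Identical networks give 1; the value can be
#' negative and is not clamped. This is a similarity measure over edge
#' weights, not a regression fit.
#'
#' @param net_a,net_b `ema_network` objects over the same variable set.
#' @param lag_aggregate How multiple lags per ordered pair enter the slot:
#'   `"max"` (strongest |weight|, default) or `"sum"`.
#' @param include_self Include autoregressive self-links (default FALSE:
#'   between-variable structure only).
#' @return A single number.
#' @export
#' @examples
#' hc <- network_from_spec(make_group_preset("HC_like"))
#' network_r2(hc, hc)
network_r2 <- function(net_a, net_b, lag_aggregate = c("max", "sum"),
                       include_self = FALSE) {
  stopifnot(inherits(net_a, "ema_network"), inherits(net_b, "ema_network"))
  if (!setequal(net_a$variable_names, net_b$variable_names)) {
    abort("Networks must be defined over identical variable sets.")
  }
  wa <- edge_vector(net_a, lag_aggregate, include_self)
  wb <- edge_vector(net_b, lag_aggregate, include_self)
  1 - sum((wa - wb)^2)
}

#' Network density
#'
#' The degree of connectivity: the number of significant links (mode
#' `"count"`, default) or the sum of absolute link weights (mode
#' `"weight"`), divided by the `N(N-1)/2` possible undirected pairs. Each
#' (pair, lag) link counts once and a contemporaneous link once per
#' unordered pair, so a pair linked at several lags contributes several
#' times and densities above 1 are legal. Autoregressive self-links are
#' excluded by default.
#'
#' @param net An `ema_network` with at least 2 variables.
#' @param mode `"count"` or `"weight"`.
#' @param include_self Include self-links in the numerator.
#' @return A single non-negative number.
#' @export
network_density <- function(net, mode = c("count", "weight"),
                            include_self = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ema_network"))
  n <- length(net$variable_names)
  if (n < 2) abort("Density needs at least 2 variables.")
  links <- net$links
  if (!include_self) {
    links <- links[links$source != links$target | links$lag == 0, , drop = FALSE]
  }
  num <- if (mode == "count") nrow(links) else sum(abs(links$weight))
  num / (n * (n - 1) / 2)
}

#' Pairwise network comparison report
#'
#' Bundles the two-group comparison statistics: per-network densities in
#' both modes and the between-network R-squared, plus a slot-level
#' difference table for inspection.
#'
#' @param nets Named list of `ema_network` objects (>= 2, same variables).
#' @param lag_aggregate Passed to [network_r2()].
#' @return A list with `density` (tibble), `r2` (tibble of pairs), and
#'   `differences` (tibble of per-slot weights for the first pair).
#' @export
network_metrics_report <- function(nets, lag_aggregate = "max") {
  stopifnot(is.list(nets), length(nets) >= 2, !is.null(names(nets)))
  density_tbl <- purrr::imap(nets, function(n, nm) {
    tibble::tibble(
      network = nm,
      density_count = network_density(n, "count"),
      density_weight = network_density(n, "weight")
    )
  }) |> purrr::list_rbind()
  pairs <- utils::combn(names(nets), 2, simplify = FALSE)
  r2_tbl <- purrr::map(pairs, function(pr) {
    tibble::tibble(
      network_a = pr[1], network_b = pr[2],
      r2 = network_r2(nets[[pr[1]]], nets[[pr[2]]],
                      lag_aggregate = lag_aggregate)
    )
  }) |> purrr::list_rbind()
  wa <- edge_vector(nets[[1]], lag_aggregate)
  wb <- edge_vector(nets[[2]], lag_aggregate)
  differences <- tibble::tibble(
    slot = names(wa),
    weight_a = unname(wa), weight_b = unname(wb),
    difference = unname(wa - wb)
  )
  differences <- differences[differences$weight_a != 0 |
                               differences$weight_b != 0, ]
  list(density = density_tbl, r2 = r2_tbl, differences = differences)
}

#' @rdname network_metrics_report
#' @param report Output of `network_metrics_report()`.
#' @param path Output JSON path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
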