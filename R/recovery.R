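#' Reduced-form lagged dependencies implied by an SVAR specification
#'
#' A lagged partial-correlation network estimated from observed series
#' targets the reduced form of the generative model: with contemporaneous
#' mixing `B0`, the lag-`tau` dependency matrix seen by a lagged regression
#' is `(I - B0)^{-1} B_tau`, which can contain entries absent from the
#' structural `B_tau` (a lagged parent acting through a contemporaneous
#' partner). Contemporaneous dependencies are the nonzero off-diagonals of
#' the reduced-form innovation covariance.
#'
#' @param spec An [svar_spec()].
#' @return A tibble: `source`, `target`, `lag` (0 = contemporaneous,
#'   `source < target`), `coefficient` (for lag 0, the innovation
#'   covariance).
#' @export
reduced_form_links <- function(spec) {
  stopifnot(inherits(spec, "ema_svar_spec"))
  v <- length(spec$variables)
  m <- solve(diag(v) - spec$b0)
  lag_rows <- purrr::imap(spec$blags, function(b, tau) {
    a <- m %*% b
    idx <- which(abs(a) > 1e-12, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(
      source = spec$variables[idx[, "col"]],
      target = spec$variables[idx[, "row"]],
      lag = as.integer(tau), coefficient = a[idx]
    )
  })
  innov <- m %*% diag(spec$noise_sd^2, v) %*% t(m)
  idx <- which(abs(innov) > 1e-12 & upper.tri(innov), arr.ind = TRUE)
  con <- if (nrow(idx) > 0) {
    tibble::tibble(
      source = pmin(spec$variables[idx[, "row"]], spec$variables[idx[, "col"]]),
      target = pmax(spec$variables[idx[, "row"]], spec$variables[idx[, "col"]]),
      lag = 0L, coefficient = innov[idx]
    )
  } else NULL
  dplyr::bind_rows(con, purrr::list_rbind(purrr::compact(lag_rows))) |>
    dplyr::arrange(.data$lag, .data$target, .data$source)
}

# collapse links to directed-pair edges: lagged pairs keep the signed weight
# of the strongest-|weight| lag; contemporaneous pairs stored source < target
#' @noRd
collapse_pairs <- function(links) {
  lag_part <- links[links$lag > 0, , drop = FALSE]
  con_part <- links[links$lag == 0, , drop = FALSE]
  out <- NULL
  if (nrow(lag_part) > 0) {
    out <- lag_part |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::summarise(weight = .data$weight[which.max(abs(.data$weight))],
                       .groups = "drop") |>
      dplyr::mutate(channel = "lagged")
  }
  if (nrow(con_part) > 0) {
    con <- tibble::tibble(
      source = pmin(con_part$source, con_part$target),
      target = pmax(con_part$source, con_part$target),
      weight = con_part$weight, channel = "contemporaneous"
    )
    out <- dplyr::bind_rows(out, con)
  }
  out %||% tibble::tibble(source = character(), target = character(),
                          weight = numeric(), channel = character())
}

#' Score an estimated network against the generating model
#'
#' Edge-level recovery at the directed-pair level (the edge concept of the
#' lag-collapsed network figures and of the R-squared edge expansion):
#'
#' * precision — the fraction of estimated edges (lagged: ordered pair;
#'   contemporaneous: unordered pair) present among the generating model's
#'   reduced-form dependencies ([reduced_form_links()]);
#' * recall — the fraction of planted structural links (pairs from the
#'   spec's nonzero coefficients) recovered by the estimate;
#' * sign agreement — among recovered structural pairs, the fraction whose
#'   aggregated estimated sign (strongest-|weight| lag) matches the planted
#'   sign.
#'
#' @param net An `ema_network` estimate.
#' @param spec The generating [svar_spec()].
#' @return One-row tibble: `n_true`, `n_est`, `precision`, `recall`,
#'   `sign_agreement`.
#' @export
score_recovery <- function(net, spec) {
  stopifnot(inherits(net, "ema_network"), inherits(spec, "ema_svar_spec"))
  truth_struct <- tidy(network_from_spec(spec)) |> collapse_pairs()
  truth_reduced <- reduced_form_links(spec) |>
    dplyr::rename(weight = "coefficient") |> collapse_pairs()
  est <- collapse_pairs(net$links)
  key <- function(d) paste(d$channel, d$source, d$target)
  precision <- if (nrow(est) > 0) mean(key(est) %in% key(truth_reduced)) else NA_real_
  hit <- key(truth_struct) %in% key(est)
  recall <- mean(hit)
  matched <- dplyr::inner_join(
    truth_struct, est, by = c("source", "target", "channel"),
    suffix = c("_true", "_est")
  )
  sign_agreement <- if (nrow(matched) > 0) {
    mean(sign(matched$weight_true) == sign(matched$weight_est))
  } else NA_real_
  tibble::tibble(
    n_true = nrow(truth_struct), n_est = nrow(est),
    precision = precision, recall = recall,
    sign_agreement = sign_agreement
  )
}

#' Check that the planted feedback loops are recovered
#'
#' Enumerates loops in the estimated network's summary graph and reports,
#' for each loop of the ground-truth network, whether a loop with the same
#' node cycle, feedback type, adaptivity and context flag is present.
#'
#' @param net An `ema_network` estimate.
#' @param spec The generating [svar_spec()].
#' @param valence_map,context_set Passed to [collapse_to_summary()]; default
#'   to the spec's own tags.
#' @return Tibble with one row per planted loop: `cycle`, `feedback`,
#'   `adaptivity`, `includes_context`, `recovered`.
#' @export
loop_recovery <- function(net, spec, valence_map = NULL, context_set = NULL) {
  valence_map <- valence_map %||% spec$valence
  context_set <- context_set %||% spec$variables[spec$is_context]
  truth_loops <- enumerate_loops(
    collapse_to_summary(network_from_spec(spec), valence_map, context_set)
  )
  est_loops <- enumerate_loops(
    collapse_to_summary(net, valence_map, context_set)
  )
  est_key <- paste(est_loops$cycle, est_loops$feedback, est_loops$adaptivity,
                   est_loops$includes_context)
  tibble::tibble(
    cycle = truth_loops$cycle,
    feedback = truth_loops$feedback,
    adaptivity = truth_loops$adaptivity,
    includes_context = truth_loops$includes_context,
    recovered = paste(truth_loops$cycle, truth_loops$feedback,
                      truth_loops$adaptivity,
                      truth_loops$includes_context) %in% est_key
  )
}
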