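#' Pool per-subject EMA records into one analysis-ready series
#'
#' Concatenates subjects' records (ordered by subject, day, beep) into a
#' single T x V series, the within-subject relative order preserved. Under
#' `boundary_policy = "mask"` (default), `tau_max` all-missing spacer rows
#' are inserted between consecutive subjects so that no lagged sample spans
#' two subjects; `"naive"` concatenates directly, in which case lagged pairs
#' can cross subject boundaries.
#'
#' @param panel An `ema_panel` tibble.
#' @param variables Variables to retain (default: all measured variables).
#' @param boundary_policy `"mask"` or `"naive"`.
#' @param tau_max Number of spacer rows under `"mask"`; use the maximum lag
#'   of the downstream analysis.
#' @return An object of class `ema_series`: a list with `values` (T x V
#'   matrix), `missing_mask`, `boundary_index` (1-based first row of each
#'   subject), `variable_names`, `scales`, and `policy`.
#' @export
#' @examples
#' panel <- simulate_panel(make_group_preset("HC_like"), 2, seed = 1)
#' s <- concatenate_series(panel, boundary_policy = "naive")
#' s$boundary_index
concatenate_series <- function(panel, variables = NULL,
                               boundary_policy = c("mask", "naive"),
                               tau_max = 14) {
  boundary_policy <- match.arg(boundary_policy)
  available <- panel_variables(panel)
  variables <- variables %||% available
  check_variables(variables, available)

  panel <- dplyr::arrange(panel, .data$subject_id, .data$day, .data$beep)
  subjects <- unique(panel$subject_id)
  n_spacer <- if (boundary_policy == "mask") as.integer(tau_max) else 0L

  blocks <- vector("list", length(subjects))
  boundary <- integer(length(subjects))
  at <- 0L
  for (i in seq_along(subjects)) {
    rows <- panel[panel$subject_id == subjects[i], variables, drop = FALSE]
    m <- as.matrix(rows)
    if (i > 1 && n_spacer > 0) {
      m <- rbind(matrix(NA_real_, n_spacer, length(variables)), m)
    }
    boundary[i] <- at + (if (i > 1) n_spacer else 0L) + 1L
    at <- at + nrow(m)
    blocks[[i]] <- m
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- variables
  scales <- attr(panel, "scales")
  structure(
    list(
      values = values,
      missing_mask = is.na(values),
      boundary_index = boundary,
      variable_names = variables,
      scales = if (!is.null(scales)) scales[variables] else NULL,
      policy = boundary_policy,
      tau_max = if (boundary_policy == "mask") as.integer(tau_max) else NA_integer_
    ),
    class = "ema_series"
  )
}

#' @export
print.ema_series <- function(x, ...) {
  cat(sprintf(
    "<ema_series> %d rows x %d variables, %d subjects, policy = %s, %.1f%% missing\n",
    nrow(x$values), ncol(x$values), length(x$boundary_index), x$policy,
    100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' @export
tidy.ema_series <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1)
}

#' Assign the scale midpoint to missing values of sparse Likert items
#'
#' Items answered very sparsely break the continuity of a pooled time series;
#' this sets their missing cells to the 1–7 scale midpoint (4) and clears the
#' missing flag, so the item can still enter lagged analyses. Only 1–7 Likert
#' variables are eligible. Applying the operation twice is a no-op.
#'
#' @param series An `ema_series`.
#' @param sparse_variables Character vector of Likert variables to impute.
#' @return The modified `ema_series`.
#' @export
impute_midscale <- function(series, sparse_variables) {
  stopifnot(inherits(series, "ema_series"))
  if (length(sparse_variables) == 0) return(series)
  check_variables(sparse_variables, series$variable_names, "series")
  for (v in sparse_variables) {
    vals <- series$values[, v]
    obs <- vals[!is.na(vals)]
    not_likert <- (!is.null(series$scales) &&
                     series$scales[[v]] != "likert_1_7") ||
      (length(obs) > 0 && (min(obs) < 1 || max(obs) > 7))
    if (not_likert) {
      abort(sprintf("'%s' is not a 1-7 Likert variable; cannot impute midscale.", v))
    }
    # midscale imputation only applies to real survey gaps, never to
    # between-subject spacer rows
    idx <- is.na(vals) & !all_spacer_rows(series)
    series$values[idx, v] <- 4
    series$missing_mask[idx, v] <- FALSE
  }
  series
}

# rows inserted purely as boundary spacers (every variable missing AND not a
# subject row); identified as rows before each boundary start under "mask"
#' @noRd
all_spacer_rows <- function(series) {
  out <- rep(FALSE, nrow(series$values))
  if (series$policy != "mask" || is.na(series$tau_max) || series$tau_max == 0) {
    return(out)
  }
  starts <- series$boundary_index[-1]
  for (s in starts) out[(s - series$tau_max):(s - 1)] <- TRUE
  out
}

#' Interpret blank count/indicator responses as zero
#'
#' Interaction-partner counts left blank are, by survey design, zeros (no
#' interaction of that type): this sets missing cells of the listed count or
#' indicator variables to 0 and clears their missing flag.
#'
#' @param series An `ema_series`.
#' @param count_variables Count/indicator variables to zero-fill.
#' @return The modified `ema_series`.
#' @export
blank_counts_to_zero <- function(series, count_variables) {
  stopifnot(inherits(series, "ema_series"))
  if (length(count_variables) == 0) return(series)
  check_variables(count_variables, series$variable_names, "series")
  spacer <- all_spacer_rows(series)
  for (v in count_variables) {
    if (!is.null(series$scales) &&
        !series$scales[[v]] %in% c("count_0_6", "indicator")) {
      abort(sprintf("'%s' is not a count/indicator variable.", v))
    }
    idx <- is.na(series$values[, v]) & !spacer
    series$values[idx, v] <- 0
    series$missing_mask[idx, v] <- FALSE
  }
  series
}

#' Preprocessing report
#'
#' Summarizes an analysis-ready series: rows, per-variable missing fraction,
#' and the augmented Dickey-Fuller stationarity check per variable.
#'
#' @param series An `ema_series`.
#' @param adf_max_lag Passed to [adf_test()].
#' @return A tibble with one row per variable; also suitable for JSON export
#'   via [write_preprocessing_report()].
#' @export
preprocessing_report <- function(series, adf_max_lag = NULL) {
  stopifnot(inherits(series, "ema_series"))
  spacer <- all_spacer_rows(series)
  purrr::map(series$variable_names, function(v) {
    x <- series$values[!spacer, v]
    adf <- tryCatch(adf_test(x, max_lag = adf_max_lag),
                    error = function(e) NULL)
    tibble::tibble(
      variable = v,
      n_rows = length(x),
      missing_fraction = mean(is.na(x)),
      adf_statistic = if (is.null(adf)) NA_real_ else adf$statistic,
      adf_p_value = if (is.null(adf)) NA_real_ else adf$p_value,
      stationary = if (is.null(adf)) NA else adf$p_value < 0.01
    )
  }) |> purrr::list_rbind()
}

#' @rdname preprocessing_report
#' @param report A tibble from `preprocessing_report()`.
#' @param series_policy Boundary policy string recorded in the JSON.
#' @param path Output path.
#' @export
write_preprocessing_report <- function(report, path, series_policy = NA) {
  jsonlite::write_json(
    list(policy = series_policy, variables = report),
    path, digits = NA, auto_unbox = TRUE, na = "null"
  )
  invisible(path)
}
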