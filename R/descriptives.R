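#' Cohen's d from group summary statistics
#'
#' Standardized mean difference using the pooled standard deviation:
#' `(mean1 - mean2) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A single number.
#' @export
#' @examples
#' cohens_d(1, 1, 10, 0, 1, 10)
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("cohens_d needs n >= 2 per group.")
  pooled_var <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (pooled_var <= 0) abort("Pooled variance is zero; d undefined.")
  (mean1 - mean2) / sqrt(pooled_var)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with 1 degree
#' of freedom.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(5, 71, 3, 100), 2, byrow = TRUE))
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2.")
  if (any(table < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All margins must be positive.")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic), df = 1L,
                 p_value = unname(res$p.value))
}

#' Percentages of interaction records per partner type
#'
#' @param counts Named numeric vector of record counts per type.
#' @return Tibble with `type`, `n`, `pct` (percentage of all typed records,
#'   one decimal place).
#' @export
type_percentages <- function(counts) {
  if (sum(counts) <= 0) abort("Counts must sum to a positive total.")
  tibble::tibble(
    type = names(counts) %||% as.character(seq_along(counts)),
    n = unname(as.numeric(counts)),
    pct = unname(round(100 * counts / sum(counts), 1))
  )
}

#' Tabulate interaction-partner types per group
#'
#' Counts EMA records containing each partner type (indicator > 0) and the
#' percentage each type contributes to all typed records within a group.
#'
#' @param panel An `ema_panel`.
#' @param type_cols Partner-indicator columns; defaults to the partner-type
#'   vocabulary intersected with the panel's columns.
#' @return Tibble with `group`, `type`, `n`, `pct`.
#' @export
tabulate_interaction_types <- function(panel, type_cols = NULL) {
  vocab <- c("alone", "roommate", "family", "treatment_provider", "friends",
             "coworker", "staff", "other")
  type_cols <- type_cols %||% intersect(vocab, names(panel))
  if (length(type_cols) == 0) abort("No partner-type indicator columns found.")
  check_variables(type_cols, names(panel))
  purrr::map(split(panel, panel$group), function(g) {
    counts <- vapply(type_cols, function(v) {
      sum(!is.na(g[[v]]) & g[[v]] > 0)
    }, numeric(1))
    dplyr::mutate(type_percentages(counts), group = g$group[1], .before = 1)
  }) |> purrr::list_rbind()
}

#' Percentage of sampled time spent at home
#'
#' Converts a mean at-home minutes-per-hour value (0-60) to a percentage of
#' sampled time, one decimal place.
#'
#' @param mean_minutes_per_hour Mean minutes at home per sampled hour.
#' @return A single number in `[0, 100]`.
#' @export
#' @examples
#' percent_time_at_home(32.8)
percent_time_at_home <- function(mean_minutes_per_hour) {
  if (!is.numeric(mean_minutes_per_hour) ||
      any(mean_minutes_per_hour < 0 | mean_minutes_per_hour > 60)) {
    abort("mean_minutes_per_hour must lie in [0, 60].")
  }
  round(mean_minutes_per_hour / 60 * 100, 1)
}

#' Group comparison table for EMA variables
#'
#' Per-variable group means, SDs and record counts, with Cohen's d (pooled)
#' and a two-sample Student t test at the EMA record level — repeated
#' observations per subject pooled, which is how per-beep variables are
#' conventionally summarized in these tables.
#'
#' @param panel An `ema_panel` containing exactly two groups.
#' @param variables Variables to compare (default all measured variables).
#' @param var_equal Use the pooled-variance Student t (default TRUE).
#' @return A tibble with one row per variable: per-group `n`, `mean`, `sd`,
#'   `cohens_d`, `t`, `df`, `p_value`.
#' @export
group_summary <- function(panel, variables = NULL, var_equal = TRUE) {
  variables <- variables %||% panel_variables(panel)
  check_variables(variables, names(panel))
  groups <- sort(unique(panel$group))
  if (length(groups) != 2) abort("group_summary expects exactly two groups.")
  purrr::map(variables, function(v) {
    x1 <- panel[[v]][panel$group == groups[1]]
    x2 <- panel[[v]][panel$group == groups[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    tt <- stats::t.test(x1, x2, var.equal = var_equal)
    tibble::tibble(
      variable = v,
      group1 = groups[1], n1 = length(x1), mean1 = mean(x1), sd1 = sd(x1),
      group2 = groups[2], n2 = length(x2), mean2 = mean(x2), sd2 = sd(x2),
      cohens_d = cohens_d(mean(x1), sd(x1), length(x1),
                          mean(x2), sd(x2), length(x2)),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }) |> purrr::list_rbind()
}
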