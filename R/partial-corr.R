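#' Partial correlation with a t-test
#'
#' Correlation between the residuals of `x` and `y` after linear regression
#' (with intercept) on the conditioning set `Z`; equivalently computed from
#' the inverse covariance of `(x, y, Z)`. Rows with a missing value in `x`,
#' `y`, or any column of `Z` are dropped listwise. The two-sided p-value uses
#' the t distribution with `n_effective - |Z| - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param z Optional conditioning set: a numeric vector, matrix, or list of
#'   vectors. `NULL` gives the plain product-moment correlation.
#' @return A one-row tibble: `r`, `p_value`, `n_effective`, `df`.
#' @export
#' @examples
#' partial_corr(mtcars$mpg, mtcars$hp, mtcars$wt)
partial_corr <- function(x, y, z = NULL) {
  if (is.list(z) && !is.data.frame(z)) z <- do.call(cbind, z)
  if (!is.null(z)) z <- as.matrix(z)
  m <- cbind(x, y, z)
  res <- .pcor_core(m)
  tibble::tibble(r = res$r, p_value = res$p, n_effective = res$n,
                 df = res$df)
}

# Core partial-correlation computation on a numeric matrix whose first two
# columns are the tested pair and remaining columns the conditioning set.
# Listwise deletion; errors on insufficient sample or degenerate residuals.
#' @noRd
.pcor_core <- function(m) {
  ok <- complete.cases(m)
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  nz <- ncol(m) - 2L
  if (n <= nz + 3) {
    abort(sprintf(
      "Insufficient effective samples for partial correlation (n_effective = %d, |Z| = %d).",
      n, nz
    ), class = "emanet_insufficient_samples", n_effective = n)
  }
  cc <- stats::cov(m)
  if (any(diag(cc) == 0)) {
    abort("Zero-variance column in partial correlation.",
          class = "emanet_zero_variance")
  }
  prec <- tryCatch(chol2inv(chol(cc)), error = function(e) NULL)
  if (!is.null(prec)) {
    denom <- prec[1, 1] * prec[2, 2]
    if (denom <= 0 || !is.finite(denom)) {
      abort("Zero-variance residuals in partial correlation.",
            class = "emanet_zero_variance")
    }
    r <- -prec[1, 2] / sqrt(denom)
  } else {
    # covariance is rank-deficient (e.g. a conditioning column collinear
    # with the tested pair): fall back to explicit residualization, which
    # only needs the conditioning block to be well-behaved
    z1 <- cbind(1, m[, -(1:2), drop = FALSE])
    rx <- stats::lm.fit(z1, m[, 1])$residuals
    ry <- stats::lm.fit(z1, m[, 2])$residuals
    if (stats::var(rx) < 1e-12 * cc[1, 1] ||
        stats::var(ry) < 1e-12 * cc[2, 2]) {
      abort("Zero-variance residuals in partial correlation.",
            class = "emanet_zero_variance")
    }
    r <- stats::cor(rx, ry)
  }
  r <- unname(max(-1, min(1, r)))
  df <- n - nz - 2L
  tstat <- if (1 - r^2 <= 0) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = unname(p), n = n, df = df)
}

# Lagged design matrix: column (v, tau) holds variable v shifted down by tau
# rows, i.e. row t contains v at time t - tau. Column name "v@tau".
#' @noRd
build_lag_matrix <- function(values, tau_max) {
  t_n <- nrow(values)
  v_n <- ncol(values)
  out <- matrix(NA_real_, t_n, v_n * (tau_max + 1))
  cn <- character(v_n * (tau_max + 1))
  k <- 0L
  for (tau in 0:tau_max) {
    for (j in seq_len(v_n)) {
      k <- k + 1L
      if (tau == 0) {
        out[, k] <- values[, j]
      } else if (tau < t_n) {
        out[(tau + 1):t_n, k] <- values[seq_len(t_n - tau), j]
      }
      cn[k] <- paste0(colnames(values)[j], "@", tau)
    }
  }
  colnames(out) <- cn
  out
}

#' @noRd
lag_col <- function(var, lag) paste0(var, "@", lag)
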