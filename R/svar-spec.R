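#' Structural VAR specification for EMA simulation
#'
#' An `ema_svar_spec` is the ground-truth generative model behind a synthetic
#' EMA panel: a structural vector autoregression with contemporaneous signed
#' coefficients `b0` (strictly lower-triangular under the declared causal
#' order, so no contemporaneous cycles) and lagged coefficient matrices
#' `blags`. Each variable carries a valence tag (`"positive"`, `"negative"`,
#' `"neutral"`), a context flag, an innovation SD, and an output scale
#' descriptor used to discretize the latent Gaussian trajectory.
#'
#' Coefficient convention: `b0[i, j]` (and `blags[[tau]][i, j]`) is the effect
#' of variable `j` on variable `i`; row = target, column = source.
#'
#' @param variables Character vector of variable names, in causal order.
#' @param b0 V x V contemporaneous coefficient matrix (default all zero).
#'   Must be strictly lower triangular in the given variable order.
#' @param blags List of V x V lagged coefficient matrices; element `tau` holds
#'   the lag-`tau` coefficients.
#' @param valence Named character vector mapping variables to
#'   `"positive"`, `"negative"` or `"neutral"`; unnamed scalar recycles.
#' @param is_context Named logical vector flagging context variables;
#'   unnamed scalar recycles.
#' @param noise_sd Innovation standard deviations (scalar or named vector).
#' @param scales Output scale descriptor per variable: one of
#'   `"likert_1_7"`, `"minutes_0_60_step15"`, `"count_0_6"`, `"indicator"`.
#' @param group Optional group label carried into simulated panels.
#'
#' @return An object of class `ema_svar_spec`.
#' @seealso [make_group_preset()], [simulate_panel()], [network_from_spec()]
#' @export
#' @examples
#' spec <- svar_spec(
#'   c("x", "y"),
#'   blags = list(matrix(c(0.4, 0.3, 0, 0.4), 2, 2, byrow = TRUE,
#'                       dimnames = list(c("x", "y"), c("x", "y"))))
#' )
#' spec$stationary
svar_spec <- function(variables,
                      b0 = NULL,
                      blags = list(),
                      valence = "neutral",
                      is_context = FALSE,
                      noise_sd = 1,
                      scales = "likert_1_7",
                      group = NULL) {
  stopifnot(is.character(variables), length(variables) >= 1,
            !anyDuplicated(variables))
  v <- length(variables)

  expand_named <- function(x, what, default, allowed = NULL) {
    if (is.null(names(x))) {
      if (length(x) == 1) x <- rep(x, v)
      if (length(x) != v) {
        abort(sprintf("%s must be a scalar, length-%d, or named vector.", what, v))
      }
      x <- stats::setNames(x, variables)
    } else {
      check_variables(names(x), variables, "spec variables")
      full <- stats::setNames(rep(default, v), variables)
      full[names(x)] <- x
      x <- full
    }
    if (!is.null(allowed) && !all(x %in% allowed)) {
      abort(sprintf("%s must be one of: %s.", what,
                    paste(allowed, collapse = ", ")))
    }
    x[variables]
  }

  valence <- expand_named(valence, "valence", "neutral",
                          c("positive", "negative", "neutral"))
  is_context <- expand_named(is_context, "is_context", FALSE)
  noise_sd <- expand_named(noise_sd, "noise_sd", 1)
  if (any(noise_sd <= 0)) abort("noise_sd must be positive.")
  scales <- expand_named(
    scales, "scales", "likert_1_7",
    c("likert_1_7", "minutes_0_60_step15", "count_0_6", "indicator")
  )

  mk <- function(m) {
    if (is.null(m)) m <- matrix(0, v, v)
    stopifnot(is.matrix(m), nrow(m) == v, ncol(m) == v)
    dimnames(m) <- list(variables, variables)
    m
  }
  b0 <- mk(b0)
  if (any(b0[upper.tri(b0, diag = TRUE)] != 0)) {
    abort(paste0(
      "b0 must be strictly lower triangular under the declared causal ",
      "order (no contemporaneous cycles)."
    ))
  }
  blags <- lapply(blags, mk)

  spec <- structure(
    list(
      variables = variables, b0 = b0, blags = blags,
      valence = valence,
      is_context = stats::setNames(as.logical(is_context), variables),
      noise_sd = noise_sd, scales = scales, group = group
    ),
    class = "ema_svar_spec"
  )
  spec$stationary <- svar_is_stationary(spec)
  spec$latent_sd <- svar_latent_sd(spec)
  spec
}

#' @noRd
svar_reduced_lags <- function(spec) {
  v <- length(spec$variables)
  m <- solve(diag(v) - spec$b0)
  lapply(spec$blags, function(b) m %*% b)
}

#' @noRd
svar_companion <- function(spec) {
  a <- svar_reduced_lags(spec)
  p <- length(a)
  v <- length(spec$variables)
  if (p == 0) return(matrix(0, v, v))
  comp <- matrix(0, v * p, v * p)
  for (tau in seq_len(p)) comp[seq_len(v), (tau - 1) * v + seq_len(v)] <- a[[tau]]
  if (p > 1) comp[(v + 1):(v * p), seq_len(v * (p - 1))] <- diag(v * (p - 1))
  comp
}

#' @noRd
svar_is_stationary <- function(spec) {
  spectral_radius(svar_companion(spec)) < 1
}

# Stationary SD of each latent variable, from the discrete Lyapunov equation
# of the companion form. Used to standardize latents before discretization.
#' @noRd
svar_latent_sd <- function(spec) {
  v <- length(spec$variables)
  comp <- svar_companion(spec)
  p <- max(1L, length(spec$blags))
  m <- solve(diag(v) - spec$b0)
  innov <- m %*% diag(spec$noise_sd^2, v) %*% t(m)
  q <- matrix(0, v * p, v * p)
  q[seq_len(v), seq_len(v)] <- innov
  if (!svar_is_stationary(spec)) {
    return(stats::setNames(rep(NA_real_, v), spec$variables))
  }
  # vec(Sigma) = (I - A (x) A)^{-1} vec(Q)
  n <- nrow(comp)
  sig <- matrix(solve(diag(n * n) - kronecker(comp, comp), as.vector(q)), n, n)
  stats::setNames(sqrt(diag(sig)[seq_len(v)]), spec$variables)
}

#' @export
print.ema_svar_spec <- function(x, ...) {
  n_lag <- sum(vapply(x$blags, function(b) sum(b != 0), integer(1)))
  cat(sprintf(
    "<ema_svar_spec> %d variables, %d contemporaneous + %d lagged coefficients (max lag %d)\n",
    length(x$variables), sum(x$b0 != 0), n_lag, length(x$blags)
  ))
  if (!is.null(x$group)) cat("  group label:", x$group, "\n")
  cat("  stationary:", x$stationary, "\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the nonzero coefficients of an SVAR specification
#'
#' @param x An `ema_svar_spec`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero coefficient: `source`, `target`,
#'   `lag` (0 = contemporaneous) and `coefficient`.
#' @export
tidy.ema_svar_spec <- function(x, ...) {
  one <- function(m, lag) {
    idx <- which(m != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(
      source = x$variables[idx[, "col"]],
      target = x$variables[idx[, "row"]],
      lag = lag,
      coefficient = m[idx]
    )
  }
  out <- dplyr::bind_rows(
    one(x$b0, 0L),
    purrr::imap(x$blags, function(b, tau) one(b, as.integer(tau)))
  )
  dplyr::arrange(out, .data$lag, .data$target, .data$source)
}

#' Write / read an SVAR specification as JSON
#'
#' The JSON sidecar records variables, coefficient matrices, valence tags,
#' context flags, noise SDs and scale descriptors, so that ground truth can be
#' stored next to a simulated panel for later recovery scoring.
#'
#' @param spec An `ema_svar_spec`.
#' @param path File path.
#' @return `write_spec_json()` returns `path` invisibly; `read_spec_json()`
#'   returns an `ema_svar_spec`.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "ema_svar_spec"))
  payload <- list(
    variables = spec$variables,
    b0 = spec$b0,
    blags = spec$blags,
    valence = as.list(spec$valence),
    is_context = as.list(spec$is_context),
    noise_sd = as.list(spec$noise_sd),
    scales = as.list(spec$scales),
    group = spec$group
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- p$variables
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(vars, vars)
    m
  }
  blags <- p$blags
  if (is.array(blags) && length(dim(blags)) == 3) {
    blags <- lapply(seq_len(dim(blags)[1]), function(i) blags[i, , ])
  }
  svar_spec(
    variables = vars,
    b0 = fix(p$b0),
    blags = lapply(blags, fix),
    valence = unlist(p$valence)[vars],
    is_context = unlist(p$is_context)[vars],
    noise_sd = unlist(p$noise_sd)[vars],
    scales = unlist(p$scales)[vars],
    group = p$group
  )
}
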