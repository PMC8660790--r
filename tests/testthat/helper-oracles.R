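# Independent oracles used across the suite. These deliberately take naive
# routes (iterative sums, explicit regressions, permutation search) so they
# share no code path with the package implementation.

# Stationary covariance of the latent SVAR across lags 0..max_lag, via the
# companion form and an iterative sum Sigma = sum_k A^k Q (A^k)'.
oracle_svar_cross_cov <- function(spec, max_lag = 2, iters = 400) {
  v <- length(spec$variables)
  p <- max(1L, length(spec$blags))
  m <- solve(diag(v) - spec$b0)
  a_list <- lapply(spec$blags, function(b) m %*% b)
  dim_c <- v * p
  a <- matrix(0, dim_c, dim_c)
  for (tau in seq_along(a_list)) {
    a[seq_len(v), (tau - 1) * v + seq_len(v)] <- a_list[[tau]]
  }
  if (p > 1) a[(v + 1):dim_c, seq_len(v * (p - 1))] <- diag(v * (p - 1))
  q <- matrix(0, dim_c, dim_c)
  q[seq_len(v), seq_len(v)] <- m %*% diag(spec$noise_sd^2, v) %*% t(m)
  sig <- q
  ak <- a
  for (k in seq_len(iters)) {
    sig <- sig + ak %*% q %*% t(ak)
    ak <- ak %*% a
    if (max(abs(ak)) < 1e-14) break
  }
  # companion stationary covariance holds Cov(X_t, X_{t-j}) blocks for j < p;
  # recurse for larger lags: Gamma_j = sum_tau A_tau Gamma_{j-tau}
  gam <- list()
  gam[["0"]] <- sig[seq_len(v), seq_len(v)]
  for (j in seq_len(max(max_lag, p - 1))) {
    if (j < p) {
      gam[[as.character(j)]] <- sig[seq_len(v), j * v + seq_len(v)]
    } else {
      acc <- matrix(0, v, v)
      for (tau in seq_along(a_list)) {
        g_prev <- gam[[as.character(j - tau)]]
        if (is.null(g_prev)) {
          g_prev <- t(gam[[as.character(tau - j)]])
        }
        acc <- acc + a_list[[tau]] %*% g_prev
      }
      gam[[as.character(j)]] <- acc
    }
  }
  lapply(gam, function(g) {
    dimnames(g) <- list(spec$variables, spec$variables)
    g
  })
}

# Joint covariance matrix of (var@lag) nodes from the oracle cross-covariance;
# nodes is a data.frame with columns var, lag. Cov(X_i@a, X_j@b) = Gamma_{a-b}[j,i]
# with Gamma_j = Cov(X_t, X_{t-j}).
oracle_joint_cov <- function(spec, nodes) {
  max_l <- max(nodes$lag)
  gam <- oracle_svar_cross_cov(spec, max_lag = max_l + 1)
  n <- nrow(nodes)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- nodes$lag[i] - nodes$lag[j]
    g <- if (d >= 0) gam[[as.character(d)]] else t(gam[[as.character(-d)]])
    # g[r, c] = Cov(X_r at t, X_c at t - d); X_i@lag_i vs X_j@lag_j with
    # lag_i - lag_j = d means X_j is d steps more recent
    out[i, j] <- g[nodes$var[j], nodes$var[i]]
  }
  out
}

# Population partial correlation of nodes 1 and 2 given the rest, from a
# covariance matrix, via explicit residual regression algebra.
oracle_pcor_from_cov <- function(cov_mat) {
  k <- nrow(cov_mat)
  if (k == 2) {
    return(cov_mat[1, 2] / sqrt(cov_mat[1, 1] * cov_mat[2, 2]))
  }
  zz <- cov_mat[3:k, 3:k, drop = FALSE]
  zx <- cov_mat[3:k, 1, drop = FALSE]
  zy <- cov_mat[3:k, 2, drop = FALSE]
  bx <- solve(zz, zx)
  by <- solve(zz, zy)
  rxy <- cov_mat[1, 2] - t(zx) %*% by
  rxx <- cov_mat[1, 1] - t(zx) %*% bx
  ryy <- cov_mat[2, 2] - t(zy) %*% by
  as.numeric(rxy / sqrt(rxx * ryy))
}

# Two-stage residual-regression partial correlation with its t-test p-value.
oracle_partial_corr <- function(x, y, z = NULL) {
  if (is.null(z)) {
    m <- cbind(x, y)
  } else {
    if (is.list(z)) z <- do.call(cbind, z)
    m <- cbind(x, y, z)
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  nz <- ncol(m) - 2
  if (nz == 0) {
    r <- stats::cor(m[, 1], m[, 2])
  } else {
    rx <- stats::lm(m[, 1] ~ m[, -(1:2)])$residuals
    ry <- stats::lm(m[, 2] ~ m[, -(1:2)])$residuals
    r <- stats::cor(rx, ry)
  }
  df <- n - nz - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

# Brute-force simple-cycle enumerator: tries every ordered arrangement of
# every node subset and keeps arrangements whose consecutive (and closing)
# edges all exist; canonicalized to start at the smallest node.
oracle_enumerate_cycles <- function(edges, max_length = 4) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  has_edge <- function(a, b) any(edges$source == a & edges$target == b)
  found <- character(0)
  for (len in 2:max_length) {
    if (length(nodes) < len) break
    subsets <- utils::combn(nodes, len, simplify = FALSE)
    for (sub in subsets) {
      perms <- all_permutations(sub[-1])
      for (pp in perms) {
        cyc <- c(sub[1], pp)
        ok <- TRUE
        for (i in seq_along(cyc)) {
          nxt <- cyc[if (i == length(cyc)) 1 else i + 1]
          if (!has_edge(cyc[i], nxt)) { ok <- FALSE; break }
        }
        if (ok) found <- c(found, paste(cyc, collapse = " -> "))
      }
    }
  }
  sort(unique(found))
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# Simple iid-noise multivariate series with optional lag-1 effects, as a
# plain ema_series (single pseudo-subject), for calibration tests.
make_noise_series <- function(n, vars, seed, b1 = NULL) {
  withr::with_seed(seed, {
    v <- length(vars)
    x <- matrix(rnorm(n * v), n, v)
    if (!is.null(b1)) {
      for (t in 2:n) x[t, ] <- x[t, ] + as.vector(b1 %*% x[t - 1, ])
    }
    colnames(x) <- vars
    structure(
      list(values = x, missing_mask = is.na(x), boundary_index = 1L,
           variable_names = vars, scales = NULL, policy = "naive",
           tau_max = NA_integer_),
      class = "ema_series"
    )
  })
}

# Tiny deterministic panel builder for preprocessing tests.
make_tiny_panel <- function(values_by_subject, variables = colnames(values_by_subject[[1]])) {
  rows <- purrr::imap(values_by_subject, function(m, i) {
    m <- as.matrix(m)
    tibble::tibble(
      subject_id = sprintf("S%02d", as.integer(i)),
      group = "G",
      day = rep(1, nrow(m)),
      beep = seq_len(nrow(m))
    ) |> dplyr::bind_cols(tibble::as_tibble(m))
  })
  panel <- purrr::list_rbind(rows)
  class(panel) <- c("ema_panel", class(panel))
  panel
}
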