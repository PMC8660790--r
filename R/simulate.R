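#' Simulate a latent SVAR trajectory
#'
#' Draws one realization of the latent Gaussian structural VAR defined by
#' `spec`, after discarding `burn_in` initial steps. Values are standardized
#' by each variable's stationary SD (computed from the model's Lyapunov
#' equation), so columns are approximately N(0, 1) and discretization keeps
#' latent correlations roughly intact.
#'
#' @param spec An [svar_spec()].
#' @param n_steps Number of retained time steps.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param burn_in Initialization steps discarded before recording.
#' @return A numeric `n_steps` x V matrix with variable names as columns.
#' @export
simulate_svar <- function(spec, n_steps, seed = NULL, burn_in = 50) {
  stopifnot(inherits(spec, "ema_svar_spec"), n_steps >= 1)
  if (!spec$stationary) {
    abort("spec is non-stationary (companion spectral radius >= 1); refusing to simulate.")
  }
  run <- function() .simulate_svar_core(spec, n_steps, burn_in)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @noRd
.simulate_svar_core <- function(spec, n_steps, burn_in) {
  v <- length(spec$variables)
  p <- length(spec$blags)
  m <- solve(diag(v) - spec$b0)
  total <- n_steps + burn_in
  eps <- matrix(rnorm(total * v, sd = rep(spec$noise_sd, each = total)),
                total, v)
  x <- matrix(0, total, v)
  for (t in seq_len(total)) {
    drive <- eps[t, ]
    if (p > 0) {
      for (tau in seq_len(min(p, t - 1))) {
        drive <- drive + spec$blags[[tau]] %*% x[t - tau, ]
      }
    }
    x[t, ] <- m %*% drive
  }
  x <- x[(burn_in + 1):total, , drop = FALSE]
  x <- sweep(x, 2, spec$latent_sd, "/")
  colnames(x) <- spec$variables
  x
}

# Map a standardized latent column to its observation scale.
#' @noRd
map_scale <- function(x, scale) {
  switch(scale,
    likert_1_7 = pmin(7, pmax(1, round(x * 1.5 + 4))),
    minutes_0_60_step15 = pmin(60, pmax(0, round((x * 15 + 30) / 15) * 15)),
    count_0_6 = pmin(6, pmax(0, round(x * 1.5 + 2))),
    indicator = as.numeric(x > 0),
    abort(sprintf("Unknown scale descriptor '%s'.", scale))
  )
}

#' Simulate an EMA panel from an SVAR specification
#'
#' Simulates independent latent trajectories per subject (each with burn-in
#' discarded), maps them onto each variable's observation scale — 1–7 Likert
#' items, at-home minutes in 15-minute steps, 0–6 counts, or 0/1 indicators —
#' and assembles a long-format beep-level panel: one row per subject x day x
#' beep.
#'
#' @param spec An [svar_spec()]; must be stationary.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_days,beeps_per_day Sampling design; defaults are the 7 x 7 EMA
#'   protocol (49 surveys per subject).
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @param group Group label column value; defaults to the spec's label.
#' @return A tibble of class `ema_panel` with columns `subject_id`, `group`,
#'   `day`, `beep`, then one column per variable. The scale map is attached
#'   as attribute `"scales"`.
#' @export
#' @examples
#' panel <- simulate_panel(make_group_preset("HC_like"), n_subjects = 3, seed = 1)
#' dplyr::count(panel, subject_id)
simulate_panel <- function(spec, n_subjects, n_days = 7, beeps_per_day = 7,
                           seed = NULL, group = NULL) {
  stopifnot(inherits(spec, "ema_svar_spec"))
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("n_subjects must be a positive integer.")
  }
  if (!spec$stationary) {
    abort("spec is non-stationary (companion spectral radius >= 1).")
  }
  n_subjects <- as.integer(n_subjects)
  n_beeps <- n_days * beeps_per_day
  group <- group %||% spec$group %||% "group1"

  build <- function() {
    purrr::map(seq_len(n_subjects), function(s) {
      lat <- .simulate_svar_core(spec, n_beeps, burn_in = 50)
      obs <- purrr::imap(spec$scales, function(sc, v) map_scale(lat[, v], sc))
      tibble::tibble(
        subject_id = sprintf("S%03d", s),
        group = group,
        day = rep(seq_len(n_days), each = beeps_per_day),
        beep = rep(seq_len(beeps_per_day), times = n_days),
        !!!obs
      )
    }) |> purrr::list_rbind()
  }
  panel <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  attr(panel, "scales") <- spec$scales
  class(panel) <- c("ema_panel", class(panel))
  panel
}

#' Mask panel cells completely at random
#'
#' Applies MCAR missingness: every measured cell (identifier columns are
#' never masked) is independently set to `NA` with probability `rate`. The
#' default rate matches the overall missing fraction reported for the study
#' protocol this generator emulates (9.16%).
#'
#' @param panel An `ema_panel` (or any tibble with the panel id columns).
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed for a reproducible mask.
#' @return The panel with masked cells set to `NA`.
#' @export
apply_missingness <- function(panel, rate = 0.0916, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    abort("rate must be a single number in [0, 1).")
  }
  if (rate == 0) return(panel)
  vars <- panel_variables(panel)
  mask_fun <- function() {
    for (v in vars) {
      hit <- runif(nrow(panel)) < rate
      panel[[v]][hit] <- NA
    }
    panel
  }
  if (is.null(seed)) mask_fun() else withr::with_seed(seed, mask_fun())
}

#' Write / read an EMA panel as long-format CSV
#'
#' One row per subject-beep; missing values are written as empty fields.
#' Header names are fixed: `subject_id, group, day, beep`, then variables.
#'
#' @param panel An `ema_panel`.
#' @param path File path.
#' @param scales Optional named scale map to re-attach on read.
#' @return `write_panel_csv()` returns `path` invisibly; `read_panel_csv()`
#'   returns an `ema_panel` tibble.
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path, scales = NULL) {
  panel <- readr::read_csv(path, na = "", show_col_types = FALSE,
                           progress = FALSE)
  if (!all(.panel_id_cols %in% names(panel))) {
    abort(sprintf("Panel CSV must contain columns: %s.",
                  paste(.panel_id_cols, collapse = ", ")))
  }
  if (!is.null(scales)) attr(panel, "scales") <- scales
  class(panel) <- c("ema_panel", class(panel))
  panel
}
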