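#' Variable clusters for incremental network building
#'
#' Networks are built incrementally over nested variable sets: affect and
#' motivation first, then context (location, being alone, interaction
#' count), then interaction partners. Clusters above 10 variables trigger a
#' warning during estimation, as power and interpretability degrade.
#'
#' @return Named list of character vectors.
#' @export
ema_variable_clusters <- function() {
  affect <- c("happy", "sad", "anxious", "relax")
  partners <- c("alone", "roommate", "family", "treatment_provider",
                "friends", "coworker", "staff", "other")
  list(
    affect_motivation = c(affect, "social_motivation"),
    affect_context = c(affect, "at_home", "alone", "interaction_count"),
    affect_context_motivation = c(affect, "at_home", "alone",
                                  "interaction_count", "social_motivation"),
    partners_affect = c(partners, affect),
    partners_affect_motivation = c(partners, affect, "social_motivation")
  )
}

#' Configure an end-to-end pipeline run
#'
#' Bundles every tunable of a two-group analysis: the input (a panel CSV
#' per group, or synthetic presets), the variable cluster, estimation
#' thresholds, boundary policy, density mode and group-specific valence
#' overrides for loop classification.
#'
#' @param input Either `"synthetic"` (default) or a named character vector
#'   of CSV paths, one per group.
#' @param presets Named character vector mapping group name to preset label
#'   (used when `input = "synthetic"`).
#' @param n_subjects Named integer vector of subjects per group; the
#'   defaults are the case-control sample sizes of the emulated study
#'   design (76 comparison, 105 case subjects).
#' @param cluster A cluster name from [ema_variable_clusters()], or a
#'   character vector of variable names.
#' @param missing_rate MCAR masking rate applied to synthetic panels.
#' @param tau_max,alpha,pc_alpha,max_conds Estimation settings, see
#'   [estimate_network()].
#' @param boundary_policy Subject-boundary handling, see
#'   [concatenate_series()].
#' @param density_mode `"count"` or `"weight"`.
#' @param valence_overrides Named list: per group, a named character vector
#'   of valence overrides for loop classification (e.g. giving being alone
#'   and being at home negative valence in the case group).
#' @param seed Integer seed for all randomness.
#' @return A `ema_run_config` list.
#' @export
run_config <- function(input = "synthetic",
                       presets = c(HC = "HC_like", SZ = "SZ_like"),
                       n_subjects = c(HC = 76, SZ = 105),
                       cluster = NULL,
                       missing_rate = 0.0916,
                       tau_max = 14, alpha = 0.01, pc_alpha = 0.05,
                       max_conds = Inf,
                       boundary_policy = "mask",
                       density_mode = "count",
                       valence_overrides = list(
                         SZ = c(alone = "negative", at_home = "negative")
                       ),
                       seed = 20211209) {
  clusters <- ema_variable_clusters()
  if (is.character(cluster) && length(cluster) == 1 &&
      cluster %in% names(clusters)) {
    cluster_vars <- clusters[[cluster]]
    cluster_name <- cluster
  } else if (is.character(cluster) && length(cluster) > 1) {
    cluster_vars <- cluster
    cluster_name <- "custom"
  } else if (is.null(cluster)) {
    cluster_vars <- NULL
    cluster_name <- "all"
  } else {
    abort(sprintf("Unknown cluster. Valid names: %s.",
                  paste(names(clusters), collapse = ", ")))
  }
  structure(
    list(
      input = input, presets = presets, n_subjects = n_subjects,
      cluster = cluster_name, cluster_vars = cluster_vars,
      missing_rate = missing_rate, tau_max = tau_max, alpha = alpha,
      pc_alpha = pc_alpha, max_conds = max_conds,
      boundary_policy = boundary_policy, density_mode = density_mode,
      valence_overrides = valence_overrides, seed = seed
    ),
    class = "ema_run_config"
  )
}

#' Run the full case-control network pipeline
#'
#' Simulates (or reads) one EMA panel per group, pools each into an
#' analysis-ready series, estimates the contemporaneous + lagged network
#' per group, compares the groups with the network R-squared and densities,
#' enumerates and classifies feedback loops per group, and computes
#' Table-1-style descriptives. Deterministic given the configuration.
#'
#' @param config An [run_config()] object.
#' @return An `ema_run_report` list: `networks`, `metrics`, `loops`,
#'   `descriptives`, `series_reports`, `warnings`, `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(n_subjects = c(HC = 20, SZ = 20), tau_max = 3,
#'                   cluster = "affect_motivation")
#' rep <- run_pipeline(cfg)
#' rep$metrics$r2
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ema_run_config"))
  collected_warnings <- character(0)
  note <- function(w) {
    collected_warnings <<- c(collected_warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # --- input stage -----------------------------------------------------
  panels <- list()
  if (identical(config$input, "synthetic")) {
    specs <- purrr::imap(config$presets, function(p, g) make_group_preset(p))
    for (g in names(specs)) {
      panel <- simulate_panel(
        specs[[g]], n_subjects = config$n_subjects[[g]],
        seed = config$seed + match(g, names(specs)), group = g
      )
      panels[[g]] <- apply_missingness(
        panel, rate = config$missing_rate,
        seed = config$seed + 1000 + match(g, names(specs))
      )
    }
  } else {
    if (is.null(names(config$input))) {
      abort("input must be 'synthetic' or a *named* vector of CSV paths.")
    }
    for (g in names(config$input)) {
      panels[[g]] <- read_panel_csv(config$input[[g]])
    }
    specs <- NULL
  }

  cluster_vars <- config$cluster_vars %||% panel_variables(panels[[1]])
  for (g in names(panels)) {
    check_variables(cluster_vars, panel_variables(panels[[g]]),
                    sprintf("panel '%s'", g))
  }

  # --- per-group estimation -------------------------------------------
  networks <- list()
  series_reports <- list()
  loops <- list()
  for (g in names(panels)) {
    series <- concatenate_series(panels[[g]], cluster_vars,
                                 boundary_policy = config$boundary_policy,
                                 tau_max = config$tau_max)
    series_reports[[g]] <- preprocessing_report(series)
    net <- withCallingHandlers(
      estimate_network(series, tau_max = config$tau_max,
                       alpha = config$alpha, pc_alpha = config$pc_alpha,
                       max_conds = config$max_conds),
      warning = note
    )
    networks[[g]] <- net
    vmap <- default_valence_map(
      override = config$valence_overrides[[g]]
    )
    # variables outside the standard vocabulary default to neutral
    unknown <- setdiff(cluster_vars, names(vmap$valence))
    if (length(unknown) > 0) {
      vmap$valence[unknown] <- "neutral"
    }
    loops[[g]] <- enumerate_loops(
      collapse_to_summary(net, vmap$valence, vmap$context)
    )
  }

  metrics <- network_metrics_report(networks)
  descriptives <- if (length(panels) == 2) {
    pooled <- dplyr::bind_rows(panels)
    group_summary(pooled, cluster_vars)
  } else NULL

  structure(
    list(
      networks = networks, metrics = metrics, loops = loops,
      descriptives = descriptives, series_reports = series_reports,
      warnings = collected_warnings,
      config = config,
      provenance = list(
        package_version = as.character(utils::packageVersion("emanet")),
        seed = config$seed
      )
    ),
    class = "ema_run_report"
  )
}

#' @export
print.ema_run_report <- function(x, ...) {
  cat("<ema_run_report>\n")
  for (g in names(x$networks)) {
    cat(sprintf("  %s: %d links, density %.2f, %d loops\n",
                g, nrow(x$networks[[g]]$links),
                network_density(x$networks[[g]], x$config$density_mode),
                nrow(x$loops[[g]])))
  }
  if (nrow(x$metrics$r2) > 0) {
    cat(sprintf("  R2(%s, %s) = %.3f\n", x$metrics$r2$network_a[1],
                x$metrics$r2$network_b[1], x$metrics$r2$r2[1]))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Edge-list CSV and GraphML per group, a JSON metrics report, loop CSVs, a
#' Table-1-style descriptives CSV and a preprocessing report per group.
#'
#' @param report An `ema_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "ema_run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(report$networks)) {
    write_network_csv(report$networks[[g]],
                      file.path(dir, paste0("network_", g, ".csv")))
    write_network_graphml(report$networks[[g]],
                          file.path(dir, paste0("network_", g, ".graphml")))
    write_loop_csv(report$loops[[g]],
                   file.path(dir, paste0("loops_", g, ".csv")))
    write_preprocessing_report(
      report$series_reports[[g]],
      file.path(dir, paste0("preprocessing_", g, ".json")),
      series_policy = report$config$boundary_policy
    )
  }
  write_metrics_report(report$metrics, file.path(dir, "metrics.json"))
  if (!is.null(report$descriptives)) {
    readr::write_csv(report$descriptives, file.path(dir, "descriptives.csv"))
  }
  writeLines(
    c(sprintf("emanet %s", report$provenance$package_version),
      sprintf("seed %d", report$provenance$seed),
      report$warnings),
    file.path(dir, "run.log")
  )
  invisible(dir)
}
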