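#' Write / read a network as an edge-list CSV
#'
#' Columns: `source`, `target`, `lag`, `weight`, `p_value`, `n_eff`; network
#' metadata (variables, alpha, tau_max) is stored in a `#`-prefixed header
#' comment so the file round-trips.
#'
#' @param net An `ema_network`.
#' @param path File path.
#' @return `write_network_csv()` returns `path` invisibly;
#'   `read_network_csv()` returns an `ema_network`.
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "ema_network"))
  meta <- sprintf(
    "# variables=%s alpha=%s tau_max=%d",
    paste(net$variable_names, collapse = ","),
    format(net$alpha, digits = 17), net$tau_max
  )
  writeLines(meta, path)
  readr::write_csv(net$links, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  meta <- readLines(path, n = 1)
  links <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  get_field <- function(name) {
    m <- regmatches(meta, regexpr(paste0(name, "=[^ ]+"), meta))
    sub(paste0(name, "="), "", m)
  }
  links$lag <- as.integer(links$lag)
  links$n_eff <- as.integer(links$n_eff)
  new_ema_network(
    links = tibble::as_tibble(links),
    variable_names = strsplit(get_field("variables"), ",")[[1]],
    alpha = as.numeric(get_field("alpha")),
    tau_max = as.integer(get_field("tau_max"))
  )
}

#' Export a network to GraphML
#'
#' Writes the significant links as a directed igraph with edge attributes
#' `lag`, `weight`, `p_value`, `sign` and `channel` (lag-0 links are stored
#' once, `source < target`, with channel `"contemporaneous"`).
#'
#' @param net An `ema_network`.
#' @param path File path.
#' @return `write_network_graphml()` returns `path` invisibly;
#'   `read_network_graphml()` reconstructs the `ema_network`.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "ema_network"))
  links <- net$links
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = links$source, to = links$target,
      lag = links$lag, weight = links$weight, p_value = links$p_value,
      n_eff = ifelse(is.na(links$n_eff), -1L, links$n_eff),
      sign = sign(links$weight),
      channel = ifelse(links$lag == 0, "contemporaneous", "lagged")
    ),
    directed = TRUE,
    vertices = data.frame(name = net$variable_names)
  )
  igraph::graph_attr(g, "alpha") <- net$alpha
  igraph::graph_attr(g, "tau_max") <- net$tau_max
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  links <- tibble::tibble(
    source = ed$from, target = ed$to, lag = as.integer(ed$lag),
    weight = ed$weight, p_value = ed$p_value,
    n_eff = ifelse(ed$n_eff < 0, NA_integer_, as.integer(ed$n_eff))
  ) |> dplyr::arrange(.data$lag, .data$target, .data$source)
  new_ema_network(
    links = links,
    variable_names = igraph::V(g)$name,
    alpha = igraph::graph_attr(g, "alpha"),
    tau_max = as.integer(igraph::graph_attr(g, "tau_max"))
  )
}
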