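#' Default valence map for the EMA variable vocabulary
#'
#' Positive valence: happiness, relaxation, social motivation (states whose
#' increase is desirable). Negative valence: sadness, anxiety. Context
#' variables (location, being alone, interaction partners, interaction
#' count) are neutral and flagged as context. Users can override any entry,
#' e.g. to give context states a group-specific valence.
#'
#' @param override Named character vector of valence overrides.
#' @param context Character vector of context variable names (replaces the
#'   default context set if given).
#' @return A list with `valence` (named character) and `context` (character).
#' @export
default_valence_map <- function(override = NULL, context = NULL) {
  valence <- c(
    happy = "positive", relax = "positive", social_motivation = "positive",
    sad = "negative", anxious = "negative",
    at_home = "neutral", alone = "neutral", friends = "neutral",
    family = "neutral", roommate = "neutral", coworker = "neutral",
    staff = "neutral", treatment_provider = "neutral", other = "neutral",
    interaction_count = "neutral"
  )
  ctx <- context %||% c(
    "at_home", "alone", "friends", "family", "roommate", "coworker",
    "staff", "treatment_provider", "other", "interaction_count"
  )
  if (!is.null(override)) {
    bad <- setdiff(override, c("positive", "negative", "neutral"))
    if (length(bad)) abort("Valence must be positive, negative or neutral.")
    valence[names(override)] <- override
  }
  list(valence = valence, context = ctx)
}

#' Collapse an estimated network to a signed summary digraph
#'
#' Lagged links become directed edges `source -> target` carrying the sign
#' of their weight; several lags with the same sign collapse to one edge,
#' while conflicting signs across lags yield two parallel edges flagged as
#' a conflict. A contemporaneous link contributes a sign-matched edge in
#' each direction (annotated `contemporaneous`); where a contemporaneous
#' edge duplicates an existing lagged edge with the same sign it is merged
#' into the lagged edge. Self-links are dropped: the summary graph carries
#' between-variable structure for cycle enumeration.
#'
#' @param net An `ema_network`.
#' @param valence_map Named character vector mapping every network variable
#'   to `"positive"`, `"negative"` or `"neutral"`; defaults to
#'   [default_valence_map()].
#' @param context_set Character vector of context variables.
#' @return An `ema_summary_graph`: list with `nodes` (tibble: `name`,
#'   `valence`, `is_context`) and `edges` (tibble: `source`, `target`,
#'   `sign`, `channel`, `conflict`).
#' @export
collapse_to_summary <- function(net, valence_map = NULL, context_set = NULL) {
  stopifnot(inherits(net, "ema_network"))
  defaults <- default_valence_map()
  valence_map <- valence_map %||% defaults$valence
  context_set <- context_set %||% defaults$context
  missing_val <- setdiff(net$variable_names, names(valence_map))
  if (length(missing_val) > 0) {
    abort(sprintf("No valence tag for variable(s): %s.",
                  paste(missing_val, collapse = ", ")))
  }
  nodes <- tibble::tibble(
    name = net$variable_names,
    valence = unname(valence_map[net$variable_names]),
    is_context = net$variable_names %in% context_set
  )

  links <- net$links[net$links$source != net$links$target, , drop = FALSE]
  lagged <- links[links$lag > 0, , drop = FALSE]
  lag_edges <- NULL
  if (nrow(lagged) > 0) {
    lag_edges <- lagged |>
      dplyr::mutate(sign = sign(.data$weight)) |>
      dplyr::distinct(.data$source, .data$target, .data$sign) |>
      dplyr::mutate(channel = "lagged")
    lag_edges <- lag_edges |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::mutate(conflict = dplyr::n() > 1) |>
      dplyr::ungroup()
  }
  con <- links[links$lag == 0, , drop = FALSE]
  con_edges <- NULL
  if (nrow(con) > 0) {
    con_edges <- dplyr::bind_rows(
      dplyr::transmute(con, source = .data$source, target = .data$target,
                       sign = sign(.data$weight)),
      dplyr::transmute(con, source = .data$target, target = .data$source,
                       sign = sign(.data$weight))
    ) |> dplyr::mutate(channel = "contemporaneous", conflict = FALSE)
  }
  edges <- dplyr::bind_rows(lag_edges, con_edges)
  if (nrow(edges) > 0) {
    # a contemporaneous edge duplicating a lagged edge of equal sign merges
    # into it; opposite signs stay as flagged parallel edges
    edges <- edges |>
      dplyr::group_by(.data$source, .data$target, .data$sign) |>
      dplyr::summarise(
        channel = if (any(.data$channel == "lagged")) "lagged" else "contemporaneous",
        .groups = "drop"
      )
    edges <- edges |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::mutate(conflict = dplyr::n() > 1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$source, .data$target, .data$sign)
  } else {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = numeric(), channel = character(),
                            conflict = logical())
  }
  structure(list(nodes = nodes, edges = edges), class = "ema_summary_graph")
}

#' @export
print.ema_summary_graph <- function(x, ...) {
  cat(sprintf("<ema_summary_graph> %d nodes, %d signed edges (%d contemporaneous-derived)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$channel == "contemporaneous")))
  invisible(x)
}

#' Construct a summary graph directly from edges
#'
#' Convenience constructor for small fixture graphs: supply signed edges and
#' node tags without estimating a network first.
#'
#' @param edges Tibble/data frame with columns `source`, `target`, `sign`
#'   and optionally `channel` (default `"lagged"`).
#' @param valence Named character vector of node valences (nodes default to
#'   `"neutral"`).
#' @param context Character vector of context node names.
#' @param nodes Optional explicit node name vector.
#' @return An `ema_summary_graph`.
#' @export
summary_graph <- function(edges, valence = NULL, context = character(),
                          nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"channel" %in% names(edges)) edges$channel <- "lagged"
  if (!"conflict" %in% names(edges)) {
    edges <- edges |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::mutate(conflict = length(unique(.data$sign)) > 1) |>
      dplyr::ungroup()
  }
  stopifnot(all(edges$sign %in% c(-1, 1)))
  node_names <- nodes %||% sort(unique(c(edges$source, edges$target)))
  val <- stats::setNames(rep("neutral", length(node_names)), node_names)
  if (!is.null(valence)) val[names(valence)] <- valence
  structure(
    list(
      nodes = tibble::tibble(
        name = node_names, valence = unname(val[node_names]),
        is_context = node_names %in% context
      ),
      edges = edges
    ),
    class = "ema_summary_graph"
  )
}

#' Enumerate feedback loops in a summary graph
#'
#' Finds all simple directed cycles of length `<= max_length`,
#' de-duplicated by canonical rotation (each cycle reported once, starting
#' at its lexicographically smallest node). When parallel edges of opposite
#' sign connect a pair, each sign combination is a distinct loop. With
#' `require_lagged = TRUE` (default), cycles composed solely of
#' contemporaneous-derived edges are discarded — a lag-0 association
#' trivially forms a 2-cycle that is not a temporal feedback loop.
#'
#' @param graph An `ema_summary_graph`.
#' @param max_length Maximum number of distinct nodes in a cycle (>= 2).
#' @param require_lagged Keep only cycles containing a lagged edge.
#' @param context_only_valence Passed to [classify_loop()]: how a loop made
#'   entirely of context nodes is judged (`"use_valence"` applies the
#'   context nodes' valence tags; `"mixed"` leaves it mixed).
#' @return An `ema_loops` tibble: one row per loop with the node cycle, the
#'   per-step edge signs, feedback type, adaptivity, context flag and
#'   lagged-edge flag.
#' @export
#' @examples
#' g <- summary_graph(
#'   tibble::tibble(source = c("sad", "happy"), target = c("happy", "sad"),
#'                  sign = c(-1, -1)),
#'   valence = c(sad = "negative", happy = "positive")
#' )
#' enumerate_loops(g)
enumerate_loops <- function(graph, max_length = 4, require_lagged = TRUE,
                            context_only_valence = "use_valence") {
  stopifnot(inherits(graph, "ema_summary_graph"))
  if (max_length < 2) abort("max_length must be >= 2.")
  edges <- graph$edges
  empty <- tibble::tibble(
    loop_id = integer(), cycle = character(), length = integer(),
    nodes = list(), edge_signs = list(), edge_channels = list(),
    feedback = character(), adaptivity = character(),
    includes_context = logical(), has_lagged_edge = logical()
  )
  if (nrow(edges) == 0) return(structure(empty, class = c("ema_loops", class(empty))))

  nodes <- sort(graph$nodes$name)
  out_edges <- split(edges, edges$source)
  found <- list()

  # DFS from each start node, visiting only nodes >= start so every cycle is
  # discovered exactly once, rooted at its smallest node
  walk <- function(start, path, sig, chan) {
    tail_node <- path[length(path)]
    oe <- out_edges[[tail_node]]
    if (is.null(oe)) return()
    for (i in seq_len(nrow(oe))) {
      nxt <- oe$target[i]
      if (nxt == start && length(path) >= 2) {
        found[[length(found) + 1]] <<- list(
          nodes = path, signs = c(sig, oe$sign[i]),
          channels = c(chan, oe$channel[i])
        )
      } else if (!(nxt %in% path) && nxt > start &&
                 length(path) < max_length) {
        walk(start, c(path, nxt), c(sig, oe$sign[i]), c(chan, oe$channel[i]))
      }
    }
  }
  for (s in nodes) walk(s, s, numeric(0), character(0))
  if (length(found) == 0) return(structure(empty, class = c("ema_loops", class(empty))))

  loops <- purrr::imap(found, function(l, i) {
    tibble::tibble(
      loop_id = i,
      cycle = paste(c(l$nodes, l$nodes[1]), collapse = " -> "),
      length = length(l$nodes),
      nodes = list(l$nodes),
      edge_signs = list(l$signs),
      edge_channels = list(l$channels),
      has_lagged_edge = any(l$channels == "lagged")
    )
  }) |> purrr::list_rbind()
  if (require_lagged) {
    loops <- loops[loops$has_lagged_edge, , drop = FALSE]
    loops$loop_id <- seq_len(nrow(loops))
  }
  if (nrow(loops) == 0) return(structure(empty, class = c("ema_loops", class(empty))))
  classified <- purrr::map(seq_len(nrow(loops)), function(i) {
    classify_loop(loops[i, ], graph,
                  context_only_valence = context_only_valence)
  }) |> purrr::list_rbind()
  classified <- classified[order(classified$length, classified$cycle), ]
  classified$loop_id <- seq_len(nrow(classified))
  structure(classified, class = c("ema_loops", class(empty)))
}

#' Classify a feedback loop
#'
#' Completes a loop record with its feedback type, adaptivity label and
#' context flag. Feedback is positive when the product of edge signs is +1
#' (a self-reinforcing loop) and negative when -1 (self-correcting). The
#' adaptivity judgement asks what states the loop regulates: a positive
#' (amplifying) loop sustains the intensity of its member states, so it is
#' likely maladaptive if any non-context member has negative valence
#' (negative affect can persist) and likely adaptive if its non-context
#' members are positive-valence states; a negative (dampening) loop erodes
#' its member states, so it is likely maladaptive if it dampens any
#' positive-valence member and likely adaptive if it dampens negative
#' affect. Context nodes set `includes_context` and stay out of the vote —
#' unless the loop consists of context nodes only, in which case (under
#' `context_only_valence = "use_valence"`) their assigned valences vote,
#' which lets a group-specific override label a context-only loop.
#'
#' @param loop A one-row loop tibble (as produced by [enumerate_loops()]),
#'   with `nodes` and `edge_signs` list columns.
#' @param graph The `ema_summary_graph` the loop came from.
#' @param context_only_valence `"use_valence"` or `"mixed"`.
#' @return The completed one-row loop record.
#' @export
classify_loop <- function(loop, graph, context_only_valence = "use_valence") {
  stopifnot(inherits(graph, "ema_summary_graph"))
  nodes <- loop$nodes[[1]]
  signs <- loop$edge_signs[[1]]
  if (!all(nodes %in% graph$nodes$name)) {
    abort("Loop nodes are not all present in the graph.")
  }
  info <- graph$nodes[match(nodes, graph$nodes$name), ]
  feedback <- if (prod(signs) > 0) "positive" else "negative"
  voters <- info[!info$is_context, , drop = FALSE]
  includes_context <- any(info$is_context)
  if (nrow(voters) == 0) {
    voters <- if (identical(context_only_valence, "use_valence")) info else info[0, ]
  }
  has_pos <- any(voters$valence == "positive")
  has_neg <- any(voters$valence == "negative")
  adaptivity <- if (feedback == "positive") {
    if (has_neg) "maladaptive" else if (has_pos) "adaptive" else "mixed"
  } else {
    if (has_pos) "maladaptive" else if (has_neg) "adaptive" else "mixed"
  }
  out <- loop
  out$feedback <- feedback
  out$adaptivity <- adaptivity
  out$includes_context <- includes_context
  out
}

#' Write a loop report as CSV
#'
#' One row per loop: the cycle, per-step signs, feedback type, adaptivity
#' and context flag.
#'
#' @param loops An `ema_loops` tibble.
#' @param path Output path.
#' @export
write_loop_csv <- function(loops, path) {
  flat <- dplyr::mutate(
    loops,
    edge_signs = purrr::map_chr(.data$edge_signs, paste, collapse = ","),
    edge_channels = purrr::map_chr(.data$edge_channels, paste, collapse = ","),
    nodes = NULL
  )
  readr::write_csv(flat, path)
  invisible(path)
}
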