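lk2 <- function(source, target, lag, weight) {
  tibble::tibble(source = source, target = target, lag = as.integer(lag),
                 weight = weight, p_value = 0.001, n_eff = 500L)
}
net_of <- function(vars, links) {
  emanet:::new_ema_network(links = links, variable_names = vars,
                           alpha = 0.01, tau_max = 14)
}

test_that("collapse_to_summary maps links to signed edges", {
  # single positive lagged link -> one directed edge
  n1 <- net_of(c("a", "b"), lk2("a", "b", 1, 0.4))
  g1 <- collapse_to_summary(n1, c(a = "neutral", b = "neutral"), character(0))
  expect_equal(nrow(g1$edges), 1)
  expect_equal(g1$edges$sign, 1)
  expect_equal(g1$edges$channel, "lagged")

  # negative contemporaneous link -> sign-matched edge pair
  n2 <- net_of(c("a", "b"), lk2("a", "b", 0, -0.3))
  g2 <- collapse_to_summary(n2, c(a = "neutral", b = "neutral"), character(0))
  expect_equal(nrow(g2$edges), 2)
  expect_true(all(g2$edges$sign == -1))
  expect_setequal(g2$edges$source, c("a", "b"))

  # conflicting signs across lags -> two parallel edges, conflict flagged
  n3 <- net_of(c("a", "b"),
               dplyr::bind_rows(lk2("a", "b", 1, 0.4), lk2("a", "b", 7, -0.2)))
  g3 <- collapse_to_summary(n3, c(a = "neutral", b = "neutral"), character(0))
  expect_equal(nrow(g3$edges), 2)
  expect_true(all(g3$edges$conflict))

  expect_error(collapse_to_summary(n1, c(a = "neutral"), character(0)),
               "valence")
})

test_that("two mutual lagged edges form exactly one 2-cycle; DAGs give none", {
  g <- summary_graph(tibble::tibble(
    source = c("a", "b"), target = c("b", "a"), sign = c(1, 1)
  ))
  loops <- enumerate_loops(g)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$cycle, "a -> b -> a")
  expect_equal(loops$feedback, "positive")

  dag <- summary_graph(tibble::tibble(
    source = c("a", "a", "b"), target = c("b", "c", "c"), sign = c(1, -1, 1)
  ))
  expect_equal(nrow(enumerate_loops(dag)), 0)
})

test_that("contemporaneous-only cycles are discarded unless requested", {
  g <- summary_graph(
    tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                   sign = c(1, 1), channel = "contemporaneous")
  )
  expect_equal(nrow(enumerate_loops(g, require_lagged = TRUE)), 0)
  expect_equal(nrow(enumerate_loops(g, require_lagged = FALSE)), 1)
})

test_that("cycle enumeration matches the brute-force oracle", {
  # exhaustive: all 64 digraphs on 3 labelled nodes (no self-loops)
  arcs <- expand.grid(source = c("a", "b", "c"), target = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  arcs <- arcs[arcs$source != arcs$target, ]
  for (mask in 0:63) {
    sel <- arcs[bitwAnd(mask, 2^(0:5)) > 0, ]
    if (nrow(sel) == 0) next
    sel$sign <- 1
    g <- summary_graph(sel, nodes = c("a", "b", "c"))
    got <- enumerate_loops(g, max_length = 3)$cycle
    want <- oracle_enumerate_cycles(sel, max_length = 3)
    want <- vapply(strsplit(want, " -> "), function(cc) {
      paste(c(cc, cc[1]), collapse = " -> ")
    }, character(1))
    expect_setequal(got, sort(want))
  }

  # random 4-6-node signed digraphs with <= 8 edges
  nodes6 <- letters[1:6]
  for (seed in 1:60) {
    sel <- withr::with_seed(seed, {
      n_nodes <- sample(4:6, 1)
      nd <- nodes6[seq_len(n_nodes)]
      all_arcs <- expand.grid(source = nd, target = nd,
                              stringsAsFactors = FALSE)
      all_arcs <- all_arcs[all_arcs$source != all_arcs$target, ]
      k <- sample(2:8, 1)
      out <- all_arcs[sample(nrow(all_arcs), k), ]
      out$sign <- sample(c(-1, 1), k, replace = TRUE)
      out
    })
    g <- summary_graph(sel, nodes = sort(unique(c(sel$source, sel$target))))
    got <- enumerate_loops(g, max_length = 4)$cycle
    want <- oracle_enumerate_cycles(sel, max_length = 4)
    want <- vapply(strsplit(want, " -> "), function(cc) {
      paste(c(cc, cc[1]), collapse = " -> ")
    }, character(1))
    expect_setequal(got, sort(want))
  }
})

test_that("feedback type follows the sign product, invariant to edge-sign bookkeeping", {
  for (signs in list(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))) {
    g <- summary_graph(tibble::tibble(
      source = c("a", "b"), target = c("b", "a"), sign = signs
    ))
    loops <- enumerate_loops(g)
    expect_equal(loops$feedback,
                 if (prod(signs) > 0) "positive" else "negative")
    # negating both signs leaves the product (hence the type) unchanged
    g_neg <- summary_graph(tibble::tibble(
      source = c("a", "b"), target = c("b", "a"), sign = -signs
    ))
    expect_equal(enumerate_loops(g_neg)$feedback, loops$feedback)
  }
})

# ---- the nine published loop fixtures -------------------------------------

published_loop_fixtures <- function() {
  vm <- default_valence_map()$valence
  list(
    relax_happy_motivation = list(edges = tibble::tibble(
      source = c("relax", "happy", "social_motivation"),
      target = c("happy", "social_motivation", "relax"), sign = 1),
      feedback = "positive", adaptivity = "adaptive", context = FALSE),
    happy_relax = list(edges = tibble::tibble(
      source = c("happy", "relax"), target = c("relax", "happy"), sign = 1),
      feedback = "positive", adaptivity = "adaptive", context = FALSE),
    motivation_happy = list(edges = tibble::tibble(
      source = c("social_motivation", "happy"),
      target = c("happy", "social_motivation"), sign = 1),
      feedback = "positive", adaptivity = "adaptive", context = FALSE),
    anxious_sad = list(edges = tibble::tibble(
      source = c("anxious", "sad"), target = c("sad", "anxious"),
      sign = c(1, -1)),
      feedback = "negative", adaptivity = "adaptive", context = FALSE),
    sad_happy = list(edges = tibble::tibble(
      source = c("sad", "happy"), target = c("happy", "sad"), sign = -1),
      feedback = "positive", adaptivity = "maladaptive", context = FALSE),
    relax_anxious_home = list(edges = tibble::tibble(
      source = c("relax", "anxious", "at_home"),
      target = c("anxious", "at_home", "relax"), sign = c(-1, -1, 1)),
      feedback = "positive", adaptivity = "maladaptive", context = TRUE),
    alone_at_home = list(edges = tibble::tibble(
      source = c("alone", "at_home"), target = c("at_home", "alone"),
      sign = 1),
      feedback = "positive", adaptivity = "maladaptive", context = TRUE,
      override = c(alone = "negative", at_home = "negative")),
    home_relax_anxious_coping = list(edges = tibble::tibble(
      source = c("at_home", "relax", "anxious"),
      target = c("relax", "anxious", "at_home"), sign = c(1, -1, -1)),
      feedback = "positive", adaptivity = NA, context = TRUE),
    friends_happy = list(edges = tibble::tibble(
      source = c("friends", "happy"), target = c("happy", "friends"),
      sign = c(1, -1)),
      feedback = "negative", adaptivity = "maladaptive", context = TRUE)
  )
}

test_that("the classifier reproduces the published loop taxonomy", {
  fixtures <- published_loop_fixtures()
  defaults <- default_valence_map()
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    vmap <- default_valence_map(override = fx$override)
    g <- summary_graph(fx$edges, valence = vmap$valence,
                       context = vmap$context)
    loops <- enumerate_loops(g)
    expect_equal(nrow(loops), 1, label = nm)
    expect_equal(loops$feedback, fx$feedback, label = nm)
    expect_equal(loops$includes_context, fx$context, label = nm)
    if (!is.na(fx$adaptivity)) {
      expect_equal(loops$adaptivity, fx$adaptivity, label = nm)
    }
  }
})

test_that("a context-only loop defaults to mixed without a valence override", {
  g <- summary_graph(
    tibble::tibble(source = c("alone", "at_home"),
                   target = c("at_home", "alone"), sign = 1),
    valence = c(alone = "neutral", at_home = "neutral"),
    context = c("alone", "at_home")
  )
  loops <- enumerate_loops(g)
  expect_equal(loops$adaptivity, "mixed")
  loops2 <- enumerate_loops(g, context_only_valence = "mixed")
  expect_equal(loops2$adaptivity, "mixed")
})

test_that("classify_loop validates loop-graph consistency", {
  g <- summary_graph(tibble::tibble(source = "a", target = "b", sign = 1))
  fake <- tibble::tibble(nodes = list(c("zz", "b")), edge_signs = list(c(1, 1)))
  expect_error(classify_loop(fake, g), "not all present")
})

test_that("loop CSV report writes one row per loop", {
  g <- summary_graph(tibble::tibble(
    source = c("sad", "happy"), target = c("happy", "sad"), sign = -1),
    valence = c(sad = "negative", happy = "positive"))
  loops <- enumerate_loops(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loop_csv(loops, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_equal(back$feedback, "positive")
  expect_equal(back$adaptivity, "maladaptive")
})
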