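test_that("hop-mode basics: diamond, self, unreachable", {
  g <- toy_graph()
  ps <- all_shortest_paths_pg(g, "A", "D")
  # two 2-edge routes A->B->D, A->C->D (A->ATP1->D also ties; ATP1 not excluded here)
  expect_equal(ps$mode, "hops")
  expect_true(all(ps$costs == 2))
  expect_setequal(path_key(ps$paths),
                  c("A>B>D", "A>C>D", "A>ATP1>D"))

  self <- all_shortest_paths_pg(g, "A", "A")
  expect_equal(self$paths, list("A"))
  expect_equal(self$costs, 0)

  un <- all_shortest_paths_pg(g, "D", "A")
  expect_equal(length(un$paths), 0)
  expect_equal(un$unreachable, list(c("D", "A")))

  expect_error(all_shortest_paths_pg(g, character(0), "D"),
               class = "kg_precondition_error")
})

test_that("truncation is flagged, never silent", {
  g <- toy_graph()
  ps <- all_shortest_paths_pg(g, "A", "D", max_paths = 2)
  expect_true(ps$truncated)
  expect_lte(length(ps$paths), 2)
})

test_that("influence weights follow the inverse-max formula", {
  g <- toy_graph()
  scores <- c(A = 0.2, B = 0.05, C = 0.3, D = 0, ATP1 = 0.45)
  r <- structure(list(direction = "forward", sources = "A", scores = scores,
                      converged = TRUE, iterations = 1L),
                 class = "radiate_result")
  w <- influence_weights(g, r, ppr_config(epsilon_floor = 1e-12))
  wAB <- w$weight[w$source == "A" & w$target == "B"]
  expect_equal(wAB, 1 / 0.2)  # max(0.2, 0.05)
  # zero-score on both endpoints floors at epsilon
  scores0 <- scores; scores0[] <- 0
  r0 <- r; r0$scores <- scores0
  w0 <- influence_weights(g, r0, ppr_config(epsilon_floor = 1e-12))
  expect_true(all(w0$weight == 1e12))
  expect_true(all(is.finite(w$weight)) && all(w$weight > 0))

  r_miss <- r; r_miss$scores <- scores[-1]
  expect_error(influence_weights(g, r_miss), class = "kg_inconsistency_error")
})

test_that("uniform scores reduce influence paths to hop paths", {
  g <- random_pg(9, p = 0.3, seed = 4)
  r <- structure(list(direction = "forward", sources = g$nodes$id[1],
                      scores = setNames(rep(1 / 9, 9), g$nodes$id),
                      converged = TRUE, iterations = 1L),
                 class = "radiate_result")
  w <- influence_weights(g, r)
  s <- g$nodes$id[1]; t <- g$nodes$id[9]
  hops <- all_shortest_paths_pg(g, s, t)
  infl <- highest_influence_paths(g, w, s, t)
  expect_equal(path_key(infl$paths), path_key(hops$paths))
})

test_that("high-influence detour beats shorter low-influence route", {
  # 2-edge route through a near-zero node vs 3-edge route through hot nodes
  nodes <- data.frame(id = c("S", "L", "H1", "H2", "T"),
                      labels = I(as.list(rep("Protein", 5))),
                      display_name = letters[1:5],
                      compartments = I(rep(list("cytosol"), 5)),
                      species = "", is_currency = FALSE)
  edges <- data.frame(source = c("S", "L", "S", "H1", "H2"),
                      target = c("L", "T", "H1", "H2", "T"),
                      type = "input")
  g <- property_graph(nodes, edges)
  scores <- c(S = 0.3, L = 0.001, H1 = 0.3, H2 = 0.3, T = 0.099)
  r <- structure(list(direction = "forward", sources = "S", scores = scores,
                      converged = TRUE, iterations = 1L),
                 class = "radiate_result")
  w <- influence_weights(g, r)
  infl <- highest_influence_paths(g, w, "S", "T")
  expect_equal(path_key(infl$paths), "S>H1>H2>T")
  # oracle agrees
  oracle <- enumerate_min_paths(g, "S", "T", weights = pair_weights(w))
  expect_equal(path_key(infl$paths), path_key(oracle))
  # hop mode prefers the short route
  expect_equal(path_key(all_shortest_paths_pg(g, "S", "T")$paths), "S>L>T")
})

test_that("exactly tied minimal routes are both returned", {
  nodes <- data.frame(id = c("S", "X", "Y", "T"),
                      labels = I(as.list(rep("Protein", 4))),
                      display_name = letters[1:4],
                      compartments = I(rep(list("cytosol"), 4)),
                      species = "", is_currency = FALSE)
  edges <- data.frame(source = c("S", "S", "X", "Y"),
                      target = c("X", "Y", "T", "T"), type = "input")
  g <- property_graph(nodes, edges)
  scores <- c(S = 0.4, X = 0.2, Y = 0.2, T = 0.2)
  r <- structure(list(direction = "forward", sources = "S", scores = scores,
                      converged = TRUE, iterations = 1L),
                 class = "radiate_result")
  infl <- highest_influence_paths(g, influence_weights(g, r), "S", "T")
  expect_setequal(path_key(infl$paths), c("S>X>T", "S>Y>T"))
})

test_that("both path finders match exhaustive enumeration on random graphs", {
  for (seed in 1:12) {
    g <- random_pg(sample(5:10, 1), p = 0.3, seed = 200 + seed)
    ids <- g$nodes$id
    s <- ids[1]; t <- ids[length(ids)]
    hops <- all_shortest_paths_pg(g, s, t)
    oracle_h <- enumerate_min_paths(g, s, t)
    expect_equal(path_key(hops$paths), path_key(oracle_h))
    if (!length(oracle_h)) {
      expect_equal(hops$unreachable, list(c(s, t)))
      next
    }
    pis <- abs(rnorm(length(ids))) + 1e-3
    r <- structure(list(direction = "forward", sources = s,
                        scores = setNames(pis / sum(pis), ids),
                        converged = TRUE, iterations = 1L),
                   class = "radiate_result")
    w <- influence_weights(g, r)
    infl <- highest_influence_paths(g, w, s, t)
    oracle_w <- enumerate_min_paths(g, s, t, weights = pair_weights(w))
    expect_equal(path_key(infl$paths), path_key(oracle_w))
    # costs: integers in hop mode; bounded below in influence mode
    expect_true(all(hops$costs == round(hops$costs)))
    expect_true(all(infl$costs >= (lengths(infl$paths) - 1) * min(w$weight) - 1e-9))
  }
})

test_that("scaling all scores leaves the minimal path set unchanged", {
  g <- random_pg(8, p = 0.35, seed = 55)
  ids <- g$nodes$id
  set.seed(56)
  pis <- abs(rnorm(8)) + 1e-3
  mk <- function(x) structure(list(direction = "forward", sources = ids[1],
                                   scores = setNames(x, ids),
                                   converged = TRUE, iterations = 1L),
                              class = "radiate_result")
  cfg <- ppr_config(epsilon_floor = 1e-300)  # floor off so scaling is exact
  w1 <- influence_weights(g, mk(pis), cfg)
  w2 <- influence_weights(g, mk(pis * 7.3), cfg)
  expect_equal(w2$weight, w1$weight / 7.3, tolerance = 1e-12)
  p1 <- highest_influence_paths(g, w1, ids[1], ids[8])
  p2 <- highest_influence_paths(g, w2, ids[1], ids[8])
  expect_equal(path_key(p1$paths), path_key(p2$paths))
})

test_that("trace graph assembly counts traversals and assigns roles", {
  ps <- structure(list(mode = "hops",
                       paths = list(c("S", "X", "T"), c("S", "Y", "T"),
                                    c("S2", "X", "T")),
                       costs = c(2, 2, 2),
                       sources = c("S", "S", "S2"), targets = c("T", "T", "T"),
                       unreachable = list(), truncated = FALSE,
                       graph = toy_graph()),
                  class = "path_set")
  tg <- build_trace_graph(ps)
  expect_setequal(tg$nodes$id, c("S", "S2", "X", "Y", "T"))
  expect_equal(tg$nodes$role[tg$nodes$id == "S"], "source")
  expect_equal(tg$nodes$role[tg$nodes$id == "T"], "target")
  expect_equal(tg$nodes$role[tg$nodes$id == "X"], "intermediate")
  expect_equal(tg$edges$traversal_count[tg$edges$source == "X" &
                                          tg$edges$target == "T"], 2L)
  # brute-force membership tally oracle
  for (i in seq_len(nrow(tg$edges))) {
    cnt <- sum(vapply(ps$paths, function(p) {
      any(p[-length(p)] == tg$edges$source[i] & p[-1] == tg$edges$target[i])
    }, logical(1)))
    expect_equal(tg$edges$traversal_count[i], cnt)
  }
  # conservation: paths leaving each source layer
  out_s <- sum(tg$edges$traversal_count[tg$edges$source == "S"])
  expect_equal(out_s, sum(ps$sources == "S"))
})

test_that("sankey export is index-correct, conservative and byte-stable", {
  g <- toy_graph()
  ps <- all_shortest_paths_pg(g, "A", "D")
  tg <- build_trace_graph(ps)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_sankey(tg, f1)
  export_sankey(tg, f2)
  expect_identical(readLines(f1), readLines(f2))
  sk <- jsonlite::fromJSON(f1, simplifyDataFrame = TRUE)
  expect_equal(nrow(sk$nodes), nrow(tg$nodes))
  expect_equal(sum(sk$links$value), sum(tg$edges$traversal_count))
  # indices reference the nodes array
  expect_true(all(sk$links$source_index >= 0 &
                    sk$links$source_index < nrow(sk$nodes)))
  expect_equal(sk$nodes$id[sk$links$source_index + 1],
               tg$edges$source)

  empty <- suppressWarnings(build_trace_graph(
    structure(list(mode = "hops", paths = list(), costs = numeric(0),
                   sources = character(0), targets = character(0),
                   unreachable = list(), truncated = FALSE, graph = g),
              class = "path_set")))
  f3 <- withr::local_tempfile(fileext = ".json")
  export_sankey(empty, f3)
  sk0 <- jsonlite::fromJSON(f3)
  expect_length(sk0$nodes, 0)
  expect_length(sk0$links, 0)
})
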