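test_that("construction enforces graph invariants", {
  g <- toy_graph()
  expect_s3_class(g, "property_graph")
  expect_equal(n_nodes(g), 5)
  expect_equal(n_edges(g), 6)

  expect_error(
    property_graph(g$nodes,
                   rbind(g$edges, data.frame(source = "A", target = "R-HSA-999",
                                             type = "input"))),
    class = "kg_referential_error")
  expect_error(
    property_graph(rbind(g$nodes, g$nodes[1, ]), g$edges),
    class = "kg_invalid_graph")
  expect_error(
    property_graph(g$nodes, rbind(g$edges, g$edges[1, ])),
    class = "kg_invalid_graph")
})

test_that("TSV and GraphML round trips are the identity", {
  g <- generate_pathway_graph(fixture_spec(seed = 7))$graph
  tsv_n <- withr::local_tempfile(fileext = ".tsv")
  tsv_e <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_graph(g, tsv_n, tsv_e)
  expect_equal(read_pathway_graph(tsv_n, tsv_e), g)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  g2 <- read_graphml(gml)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$nodes$labels, g$nodes$labels)
  expect_equal(g2$nodes$is_currency, g$nodes$is_currency)
})

test_that("readers name the missing column", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tlabels\tdisplay_name", bad)
  ok_e <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source\ttarget\ttype", ok_e)
  err <- tryCatch(read_pathway_graph(bad, ok_e), error = identity)
  expect_s3_class(err, "kg_format_error")
  expect_match(conditionMessage(err), "compartments")
})

test_that("preprocess removes decoys, filters species, reverses edges, is idempotent", {
  fx <- generate_pathway_graph(fixture_spec(seed = 3))
  cfg <- preprocess_config()
  pp <- preprocess_pathway_graph(fx$graph, cfg)
  # decoy Person/Affiliation/Taxon and the mouse protein are gone
  expect_false(any(fx$manifest$decoys %in% pp$nodes$id))
  expect_equal(n_nodes(pp), fx$manifest$human_node_count)
  # human-only graph with nothing to drop is unchanged (modulo currency flags)
  pp2 <- preprocess_pathway_graph(pp, cfg)
  expect_equal(pp2, pp)

  # edge reversal
  cfg_rev <- preprocess_config(reverse_edge_types = "output")
  ppr <- preprocess_pathway_graph(fx$graph, cfg_rev)
  orig <- pp$edges[pp$edges$type == "output", ]
  expect_true(all(paste(orig$target, orig$source) %in%
                    paste(ppr$edges$source[ppr$edges$type == "output"],
                          ppr$edges$target[ppr$edges$type == "output"])))
})

test_that("edge-addition rules add parallel typed edges", {
  g <- toy_graph()
  cfg <- preprocess_config(add_edge_rules = list(list(via = "output",
                                                      new_type = "produces")))
  pp <- preprocess_pathway_graph(g, cfg)
  added <- pp$edges[pp$edges$type == "produces", ]
  base <- g$edges[g$edges$type == "output", ]
  expect_equal(nrow(added), nrow(base))
  expect_setequal(paste(added$source, added$target),
                  paste(base$source, base$target))
})

test_that("currency labeling flags by display name, case-insensitively", {
  fx <- generate_pathway_graph(fixture_spec(seed = 5))
  g <- label_currency_nodes(fx$graph)
  flagged <- g$nodes$id[g$nodes$is_currency]
  expect_setequal(flagged, c(fx$manifest$hub_id, fx$manifest$ubiquitin_id))
  g0 <- label_currency_nodes(fx$graph, character(0))
  expect_equal(sum(g0$nodes$is_currency), 0)
  g_ci <- label_currency_nodes(fx$graph, c("atp", "UBIQUITIN"))
  expect_setequal(g_ci$nodes$id[g_ci$nodes$is_currency], flagged)
})

test_that("traversal_view filters edge types and currency nodes; oracle count", {
  fx <- generate_pathway_graph(fixture_spec(seed = 11))
  pp <- preprocess_pathway_graph(fx$graph)
  cfg <- preprocess_config(traversable_edge_types = c("input", "output"))
  v <- traversal_view(pp, cfg, exclude_currency = FALSE)
  expect_setequal(unique(v$edges$type), intersect(c("input", "output"),
                                                  pp$edges$type))
  # linear-scan oracle for the edge count
  expect_equal(n_edges(v), sum(pp$edges$type %in% c("input", "output")))
  expect_equal(n_nodes(v), n_nodes(pp))

  v2 <- traversal_view(pp, cfg, exclude_currency = TRUE)
  expect_false(any(v2$nodes$is_currency))
  expect_false(any(v2$edges$source %in% fx$manifest$hub_id |
                     v2$edges$target %in% fx$manifest$hub_id))
  # view never adds anything
  expect_true(all(v2$nodes$id %in% pp$nodes$id))
  expect_true(all(paste(v2$edges$source, v2$edges$target, v2$edges$type) %in%
                    paste(pp$edges$source, pp$edges$target, pp$edges$type)))
  # currency exclusion and type restriction commute
  a <- traversal_view(traversal_view(pp, cfg, exclude_currency = FALSE),
                      cfg, exclude_currency = TRUE)
  expect_equal(a, v2)
})

test_that("currency star graph loses center and spokes under exclusion", {
  n <- 6
  nodes <- data.frame(id = c("HUB", paste0("S", 1:n)),
                      labels = I(as.list(rep("SimpleEntity", n + 1))),
                      display_name = c("ATP", paste0("spoke", 1:n)),
                      compartments = I(rep(list("cytosol"), n + 1)),
                      species = "", is_currency = FALSE)
  edges <- data.frame(source = "HUB", target = paste0("S", 1:n), type = "input")
  g <- label_currency_nodes(property_graph(nodes, edges))
  v <- traversal_view(g, exclude_currency = TRUE)
  expect_equal(n_edges(v), 0)
  expect_false("HUB" %in% v$nodes$id)
})

test_that("find_nodes prefers the requested compartment", {
  nodes <- data.frame(
    id = c("M1.cytosol", "M1.extracellular", "M2.cytosol"),
    labels = I(as.list(rep("SimpleEntity", 3))),
    display_name = c("met1", "met1", "met2"),
    compartments = I(list("cytosol", "extracellular region", "cytosol")),
    species = "", is_currency = FALSE)
  g <- property_graph(nodes, data.frame(source = character(0),
                                        target = character(0),
                                        type = character(0)))
  expect_equal(find_nodes(g, "M1"), "M1.extracellular")
  expect_warning(res <- find_nodes(g, "M2"), class = "kg_compartment_mismatch")
  expect_equal(res, "M2.cytosol")
  expect_warning(expect_error(find_nodes(g, "M9"), class = "kg_empty_source_error"),
                 class = "kg_unresolved_ids")
  expect_error(find_nodes(g, character(0)), class = "kg_precondition_error")
})
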