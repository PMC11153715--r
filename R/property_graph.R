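#' Construct a pathway property graph
#'
#' A `property_graph` is a directed multigraph of typed nodes (entities,
#' reactions, pathways) and typed edges, the in-memory counterpart of a
#' Reactome-style graph export. Nodes carry type labels, a display name,
#' sub-cellular compartments, a species and a currency-metabolite flag;
#' edges carry a single type string. Parallel edges between the same node
#' pair are allowed as long as their types differ.
#'
#' @param nodes data.frame with columns `id` (character, unique),
#'   `labels` (list of character vectors, each non-empty), `display_name`
#'   (character), `compartments` (list of character vectors), `species`
#'   (character, `""` for species-agnostic nodes) and `is_currency`
#'   (logical, defaults to `FALSE` when absent).
#' @param edges data.frame with columns `source`, `target`, `type`
#'   (all character). Every endpoint must exist in `nodes`; the
#'   (source, target, type) triple must be unique.
#' @return An object of class `property_graph` with elements `nodes` and
#'   `edges`, rows ordered by node id / (source, target, type).
#' @export
property_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$is_currency)) nodes$is_currency <- FALSE
  if (is.null(nodes$species)) nodes$species <- ""
  if (is.null(nodes$compartments)) nodes$compartments <- rep(list(character(0)), nrow(nodes))
  if (is.character(nodes$labels)) nodes$labels <- split_list_col(nodes$labels)
  if (is.character(nodes$compartments)) nodes$compartments <- split_list_col(nodes$compartments)
  nodes$id <- as.character(nodes$id)
  nodes$display_name <- as.character(nodes$display_name)
  nodes$species <- as.character(nodes$species)
  nodes$species[is.na(nodes$species)] <- ""
  nodes$is_currency <- as.logical(nodes$is_currency)
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$type <- as.character(edges$type)
  nodes <- nodes[order(nodes$id),
                 c("id", "labels", "display_name", "compartments",
                   "species", "is_currency"), drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$type),
                 c("source", "target", "type"), drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "property_graph")
  validate_property_graph(g)
  g
}

#' Validate a property graph's invariants
#'
#' Checks node-id uniqueness, non-empty labels, edge referential integrity
#' and uniqueness of (source, target, type) triples. Called by all
#' constructors; exposed for use after manual manipulation.
#'
#' @param g a `property_graph`
#' @return `g`, invisibly, if valid; otherwise an error.
#' @export
validate_property_graph <- function(g) {
  stopifnot(inherits(g, "property_graph"))
  n <- g$nodes; e <- g$edges
  if (anyDuplicated(n$id)) {
    stop_kg("duplicate node ids: ",
            paste(unique(n$id[duplicated(n$id)]), collapse = ", "),
            class = "kg_invalid_graph")
  }
  if (any(lengths(n$labels) == 0)) {
    stop_kg("node(s) with empty label set: ",
            paste(n$id[lengths(n$labels) == 0], collapse = ", "),
            class = "kg_invalid_graph")
  }
  if (nrow(e)) {
    missing_src <- !(e$source %in% n$id)
    missing_tgt <- !(e$target %in% n$id)
    if (any(missing_src | missing_tgt)) {
      bad <- which(missing_src | missing_tgt)[1]
      stop_kg("edge references absent node: ", e$source[bad], " -[",
              e$type[bad], "]-> ", e$target[bad],
              class = "kg_referential_error")
    }
    if (!all(nzchar(e$type))) stop_kg("edge with empty type", class = "kg_invalid_graph")
    key <- paste(e$source, e$target, e$type, sep = "\r")
    if (anyDuplicated(key)) {
      stop_kg("duplicate (source, target, type) edge triple",
              class = "kg_invalid_graph")
    }
  }
  invisible(g)
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("property_graph: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  labs <- sort(table(unlist(x$nodes$labels)), decreasing = TRUE)
  if (length(labs)) {
    cat("  node labels:", paste(sprintf("%s (%d)", names(labs), labs), collapse = ", "), "\n")
  }
  if (nrow(x$edges)) {
    et <- sort(table(x$edges$type), decreasing = TRUE)
    cat("  edge types: ", paste(sprintf("%s (%d)", names(et), et), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param g a `property_graph`
#' @return integer count
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Read a property graph from node and edge TSV tables
#'
#' The TSV dialect is UTF-8, tab-separated, with a mandatory header row and
#' `;` as the intra-field list separator for `labels` and `compartments`.
#'
#' @param node_table path to the node TSV (columns `id`, `labels`,
#'   `display_name`, `compartments`, `species`, `is_currency`)
#' @param edge_table path to the edge TSV (columns `source`, `target`, `type`)
#' @return a `property_graph`
#' @export
read_pathway_graph <- function(node_table, edge_table) {
  nodes <- utils::read.delim(node_table, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, colClasses = "character",
                             encoding = "UTF-8")
  edges <- utils::read.delim(edge_table, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, colClasses = "character",
                             encoding = "UTF-8")
  need_n <- c("id", "labels", "display_name", "compartments", "species", "is_currency")
  need_e <- c("source", "target", "type")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop_kg("node table missing column(s): ",
                            paste(miss, collapse = ", "), class = "kg_format_error")
  miss <- setdiff(need_e, names(edges))
  if (length(miss)) stop_kg("edge table missing column(s): ",
                            paste(miss, collapse = ", "), class = "kg_format_error")
  nodes$labels <- split_list_col(nodes$labels)
  nodes$compartments <- split_list_col(nodes$compartments)
  nodes$is_currency <- toupper(nodes$is_currency) %in% c("TRUE", "1", "T")
  property_graph(nodes[need_n], edges[need_e])
}

#' Write a property graph to node and edge TSV tables
#'
#' Inverse of [read_pathway_graph()]; the round trip is the identity on
#' valid graphs. Rows are written in the constructor's deterministic order
#' so output is byte-stable.
#'
#' @param g a `property_graph`
#' @param node_table,edge_table output paths
#' @return invisibly, the two paths
#' @export
write_pathway_graph <- function(g, node_table, edge_table) {
  validate_property_graph(g)
  n <- g$nodes
  out_n <- data.frame(id = n$id,
                      labels = join_list_col(n$labels),
                      display_name = n$display_name,
                      compartments = join_list_col(n$compartments),
                      species = n$species,
                      is_currency = ifelse(n$is_currency, "TRUE", "FALSE"),
                      stringsAsFactors = FALSE)
  utils::write.table(out_n, node_table, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(g$edges, edge_table, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(node_table, edge_table))
}

# igraph conversion keeps all node/edge properties as ';'-joined attributes;
# vertex name is the node id.
pg_to_igraph <- function(g) {
  n <- g$nodes
  vertices <- data.frame(name = n$id,
                         labels = join_list_col(n$labels),
                         display_name = n$display_name,
                         compartments = join_list_col(n$compartments),
                         species = n$species,
                         is_currency = n$is_currency,
                         stringsAsFactors = FALSE)
  edges <- g$edges
  if (nrow(edges)) {
    el <- data.frame(from = edges$source, to = edges$target, type = edges$type,
                     stringsAsFactors = FALSE)
  } else {
    el <- data.frame(from = character(0), to = character(0), type = character(0))
  }
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = vertices)
}

igraph_to_pg <- function(ig) {
  va <- igraph::vertex_attr(ig)
  nodes <- data.frame(id = va$name,
                      display_name = va$display_name %||% va$name,
                      species = va$species %||% "",
                      is_currency = as.logical(va$is_currency %||% FALSE),
                      stringsAsFactors = FALSE)
  nodes$labels <- split_list_col(va$labels %||% rep("Entity", length(va$name)))
  nodes$compartments <- split_list_col(va$compartments %||% rep("", length(va$name)))
  el <- igraph::as_data_frame(ig, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      type = el$type %||% rep("edge", nrow(el)),
                      stringsAsFactors = FALSE)
  property_graph(nodes, edges)
}

#' Read / write GraphML
#'
#' GraphML import and export for interoperability with other graph tools.
#' List-valued node properties travel as `;`-joined attribute strings.
#'
#' @param path GraphML file path
#' @return [read_graphml()]: a `property_graph`; [write_graphml()]: the
#'   path, invisibly.
#' @export
read_graphml <- function(path) {
  igraph_to_pg(igraph::read_graph(path, format = "graphml"))
}

#' @rdname read_graphml
#' @param g a `property_graph`
#' @export
write_graphml <- function(g, path) {
  validate_property_graph(g)
  igraph::write_graph(pg_to_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Reverse every edge of a graph
#'
#' Swaps source and target of all edges; used to compute reverse radiate
#' analysis on the edge-reversed graph.
#'
#' @param g a `property_graph`
#' @return a `property_graph` with all edges flipped
#' @export
reverse_edges <- function(g) {
  e <- g$edges
  property_graph(g$nodes, data.frame(source = e$target, target = e$source,
                                     type = e$type, stringsAsFactors = FALSE))
}
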