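#' Default traversable edge types
#'
#' Only these 12 Reactome-schema edge types are followed by the graph
#' algorithms; every other relationship is treated as metadata. The set is
#' configurable in [preprocess_config()] because the canonical list lives
#' in project notebooks, not in a fixed standard.
#'
#' @return character vector of 12 edge-type names
#' @export
default_traversable_edge_types <- function() {
  c("input", "output", "catalyst", "activeUnit", "regulator",
    "positivelyRegulates", "negativelyRegulates", "hasComponent",
    "hasMember", "hasCandidate", "hasEvent", "referenceEntity")
}

#' Default currency-metabolite display names
#'
#' Ubiquitous cofactors and small molecules (ATP, NAD(P)H, H+, ...) whose
#' hub connectivity creates biologically spurious shortcuts between
#' otherwise unrelated reactions. The regulatory protein ubiquitin is
#' flagged for the same reason. Matching is case-insensitive on the
#' display name.
#'
#' @return character vector of display names
#' @export
default_currency_names <- function() {
  c("ATP", "ADP", "AMP", "GTP", "GDP", "NAD+", "NADH", "NADP+", "NADPH",
    "FAD", "FADH2", "H+", "H2O", "O2", "CO2", "phosphate", "pyrophosphate",
    "CoA", "ubiquitin")
}

#' Preprocessing configuration
#'
#' Bundles the rules that turn a raw pathway graph export into the
#' analysis-ready graph: which node labels to delete, which species to
#' keep, which edge types to reverse or add, which display names to flag
#' as currency metabolites, and which edge types the graph algorithms may
#' traverse.
#'
#' @param drop_labels node labels whose carriers are removed (literature
#'   and provenance scaffolding: Person, Affiliation, Taxon, ...)
#' @param keep_species species name to keep; nodes with a different,
#'   non-empty species are removed. Species-agnostic nodes (empty species)
#'   are always kept.
#' @param reverse_edge_types edge types whose direction is flipped to give
#'   a consistent flow direction for traversal
#' @param add_edge_rules list of rules, each a list with elements
#'   `via` (existing edge type), `new_type`: for each existing edge
#'   u -[via]-> v an additional edge u -[new_type]-> v is created.
#'   Defaults to empty (the canonical add-list is notebook-defined).
#' @param currency_names display names flagged as currency (see
#'   [default_currency_names()])
#' @param traversable_edge_types edge types the algorithms may follow;
#'   must be non-empty (see [default_traversable_edge_types()])
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(drop_labels = c("Person", "Affiliation", "Taxon",
                                              "InstanceEdit", "LiteratureReference"),
                              keep_species = "Homo sapiens",
                              reverse_edge_types = character(0),
                              add_edge_rules = list(),
                              currency_names = default_currency_names(),
                              traversable_edge_types = default_traversable_edge_types()) {
  if (!length(traversable_edge_types)) {
    stop_kg("traversable_edge_types must be non-empty", class = "kg_config_error")
  }
  structure(list(drop_labels = drop_labels,
                 keep_species = keep_species,
                 reverse_edge_types = reverse_edge_types,
                 add_edge_rules = add_edge_rules,
                 currency_names = currency_names,
                 traversable_edge_types = traversable_edge_types),
            class = "preprocess_config")
}

#' Preprocess a raw pathway graph for analysis
#'
#' Applies, in order: label-based node removal, species filtering
#' (non-matching species removed, species-agnostic nodes kept), edge
#' reversal for the configured types, edge-addition rules, and currency
#' labeling. Edges incident to removed nodes are dropped. The operation is
#' idempotent: applying it twice gives the same graph as applying it once.
#'
#' @param g a `property_graph`
#' @param cfg a [preprocess_config()]
#' @param verbose emit per-rule removal counts as messages
#' @return the preprocessed `property_graph`
#' @export
preprocess_pathway_graph <- function(g, cfg = preprocess_config(), verbose = FALSE) {
  validate_property_graph(g)
  n <- g$nodes
  drop_by_label <- vapply(n$labels, function(l) any(l %in% cfg$drop_labels), logical(1))
  drop_by_species <- nzchar(n$species) & n$species != cfg$keep_species
  keep <- !(drop_by_label | drop_by_species)
  if (verbose) {
    message(sprintf("preprocess: removed %d node(s) by label, %d by species",
                    sum(drop_by_label), sum(drop_by_species & !drop_by_label)))
  }
  n <- n[keep, , drop = FALSE]
  e <- g$edges
  e <- e[e$source %in% n$id & e$target %in% n$id, , drop = FALSE]
  rev_sel <- e$type %in% cfg$reverse_edge_types
  if (any(rev_sel)) {
    tmp <- e$source[rev_sel]
    e$source[rev_sel] <- e$target[rev_sel]
    e$target[rev_sel] <- tmp
  }
  for (rule in cfg$add_edge_rules) {
    base <- e[e$type == rule$via, , drop = FALSE]
    if (nrow(base)) {
      add <- data.frame(source = base$source, target = base$target,
                        type = rule$new_type, stringsAsFactors = FALSE)
      e <- rbind(e, add)
    }
  }
  # reversal/addition can produce duplicate triples; keep one of each
  e <- e[!duplicated(paste(e$source, e$target, e$type, sep = "\r")), , drop = FALSE]
  out <- property_graph(n, e)
  if (n_nodes(out) == 0) warn_kg("preprocessing removed every node")
  label_currency_nodes(out, cfg$currency_names, verbose = verbose)
}

#' Flag currency-metabolite nodes
#'
#' Sets `is_currency = TRUE` on every node whose display name matches one
#' of `currency_names` case-insensitively. The flagged nodes are excluded
#' from traversal by [traversal_view()] so they cannot act as artificial
#' shortcuts between metabolic reactions.
#'
#' @param g a `property_graph`
#' @param currency_names display names to flag (includes ubiquitin by
#'   default)
#' @param verbose report the number of flagged nodes
#' @return a `property_graph` with updated `is_currency` flags
#' @export
label_currency_nodes <- function(g, currency_names = default_currency_names(),
                                 verbose = FALSE) {
  flag <- tolower(g$nodes$display_name) %in% tolower(currency_names)
  g$nodes$is_currency <- flag
  if (verbose) message(sprintf("currency labeling: %d node(s) flagged", sum(flag)))
  g
}

#' Restrict a graph to its traversable subgraph
#'
#' Returns the analysis view of a preprocessed graph: only edges whose
#' type is in `cfg$traversable_edge_types` survive, and (by default) all
#' currency-flagged nodes are removed together with their incident edges.
#' The input graph is not modified. Edge-type restriction and currency
#' exclusion commute.
#'
#' @param g a preprocessed `property_graph`
#' @param cfg a [preprocess_config()] supplying the traversable type set
#' @param exclude_currency drop currency nodes (default `TRUE`)
#' @return a `property_graph` subgraph
#' @export
traversal_view <- function(g, cfg = preprocess_config(), exclude_currency = TRUE) {
  n <- g$nodes
  e <- g$edges[g$edges$type %in% cfg$traversable_edge_types, , drop = FALSE]
  if (exclude_currency) {
    n <- n[!n$is_currency, , drop = FALSE]
    e <- e[e$source %in% n$id & e$target %in% n$id, , drop = FALSE]
  }
  property_graph(n, e)
}

#' Resolve identifiers to graph nodes with compartment preference
#'
#' Pathway exports model the same molecule once per sub-cellular
#' compartment, with a shared base identifier. For each requested id this
#' returns the matching node; when several compartment-specific instances
#' share the id prefix, the instance located in the requested compartment
#' is preferred (default: "extracellular region", so plasma metabolites
#' resolve to their extracellular form). An instance in a different
#' compartment is still returned, with a warning, when no preferred
#' instance exists.
#'
#' Matching: a node matches a requested id if its id equals the request
#' exactly, or equals the request followed by a `.`-suffixed compartment
#' qualifier (e.g. request `SYN-HSA-7` matches `SYN-HSA-7.cytosol`).
#'
#' @param g a `property_graph`
#' @param ids character vector of identifiers (non-empty)
#' @param compartment preferred compartment name, matched case-insensitively
#'   against each node's compartment list
#' @return character vector of resolved node ids (deduplicated, sorted);
#'   unresolved input ids are reported via warning. If nothing resolves,
#'   an error (downstream propagation would be undefined).
#' @export
find_nodes <- function(g, ids, compartment = "extracellular region") {
  if (!length(ids)) stop_kg("ids must be non-empty", class = "kg_precondition_error")
  comp_q <- tolower(compartment)
  resolved <- character(0)
  unresolved <- character(0)
  mismatched <- character(0)
  for (id in ids) {
    hit <- g$nodes$id == id |
      startsWith(g$nodes$id, paste0(id, "."))
    cand <- g$nodes[hit, , drop = FALSE]
    if (!nrow(cand)) { unresolved <- c(unresolved, id); next }
    in_comp <- vapply(cand$compartments, function(cc) any(tolower(cc) == comp_q),
                      logical(1))
    if (any(in_comp)) {
      resolved <- c(resolved, cand$id[in_comp])
    } else {
      resolved <- c(resolved, cand$id[1])
      mismatched <- c(mismatched, id)
    }
  }
  if (length(mismatched)) {
    warn_kg("no instance in compartment '", compartment, "' for: ",
            paste(mismatched, collapse = ", "),
            class = "kg_compartment_mismatch")
  }
  if (length(unresolved)) {
    warn_kg("unresolved id(s): ", paste(unresolved, collapse = ", "),
            class = "kg_unresolved_ids")
  }
  if (!length(resolved)) {
    stop_kg("none of the requested ids resolve to a graph node",
            class = "kg_empty_source_error")
  }
  sort(unique(resolved))
}
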