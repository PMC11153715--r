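#' Specification for the synthetic pathway-graph generator
#'
#' Describes a small Reactome-like world: `n_cascades` disjoint signaling
#' cascades, each starting from an extracellular metabolite ligand and
#' ending at a transcription factor; an ATP-like currency hub wired into
#' reactions across cascades; a ubiquitin node; and a handful of decoy
#' nodes (Person/Taxon provenance scaffolding and a mouse protein) that
#' preprocessing must remove. Defaults mirror the motivating use case of
#' six differential plasma metabolites feeding six receptor cascades.
#'
#' @param n_cascades number of planted ligand-to-TF cascades (default 6)
#' @param cascade_length number of kinase steps per cascade (default 4)
#' @param n_metabolites bystander extracellular metabolites attached as
#'   co-inputs to random reactions (default 10)
#' @param currency_hub_degree number of reactions the ATP hub connects to
#'   as input and output (default 8)
#' @param extra_random_edges downstream fan-out edges from terminal nodes
#'   to bystander metabolites; placed so they never create an alternative
#'   route into a cascade (default 10)
#' @param seed integer fixing all randomness
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(n_cascades = 6L, cascade_length = 4L,
                         n_metabolites = 10L, currency_hub_degree = 8L,
                         extra_random_edges = 10L, seed = 42L) {
  vals <- c(n_cascades, cascade_length, n_metabolites,
            currency_hub_degree, extra_random_edges)
  if (any(vals < 0)) stop_kg("fixture counts must be >= 0", class = "kg_config_error")
  structure(list(n_cascades = as.integer(n_cascades),
                 cascade_length = as.integer(cascade_length),
                 n_metabolites = as.integer(n_metabolites),
                 currency_hub_degree = as.integer(currency_hub_degree),
                 extra_random_edges = as.integer(extra_random_edges),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

syn_id <- function(i) sprintf("SYN-HSA-%06d", i)

#' Generate a synthetic pathway property graph with ground truth
#'
#' Builds the world described by a [fixture_spec()]. Each cascade c is the
#' chain
#' \preformatted{ligand_c -[input]-> R_c0 -[output]-> complex_c
#'   -[catalyst]-> R_c1 -[output]-> kinase_c1 -[catalyst]-> ... ->
#'   kinase_cL -[positivelyRegulates]-> TF_c}
#' so the ligand-to-TF route is unique within a cascade. The ATP hub is
#' wired as `reaction -[output]-> ATP` and `ATP -[input]-> reaction` to
#' reactions spread across cascades, creating exactly the cross-cascade
#' shortcut artifact that currency exclusion removes. Decoy Person /
#' Taxon / Affiliation nodes and one mouse protein are included for
#' preprocessing to delete.
#'
#' All randomness flows through one PRNG seeded from `spec$seed`; node ids
#' are issued deterministically so two runs with the same spec produce
#' byte-identical tables.
#'
#' @param spec a [fixture_spec()]
#' @return list with `graph` (a raw, un-preprocessed `property_graph`) and
#'   `manifest`: planted `chains` (list with `ligand`, `target` and the
#'   full node `path` per cascade), `kinases` and `tf` per cascade,
#'   `ligands`, `hub_id`, `ubiquitin_id`, `human_node_count` (nodes
#'   surviving default preprocessing), `decoys`.
#' @export
generate_pathway_graph <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; syn_id(next_id) }
  nodes <- list()
  edges <- list()
  add_node <- function(id, labels, name, compartments = character(0),
                       species = "Homo sapiens") {
    nodes[[length(nodes) + 1L]] <<- list(id = id, labels = list(labels),
                                         display_name = name,
                                         compartments = list(compartments),
                                         species = species)
    id
  }
  add_edge <- function(src, tgt, type) {
    edges[[length(edges) + 1L]] <<- c(src, tgt, type)
  }

  chains <- list()
  cascade_kinases <- list()
  cascade_tf <- character(0)
  ligands <- character(0)
  reactions <- character(0)

  for (cas in seq_len(spec$n_cascades)) {
    lig <- add_node(new_id(), "SimpleEntity", sprintf("metabolite-%d", cas),
                    "extracellular region")
    r0 <- add_node(new_id(), "Reaction", sprintf("binding-%d", cas),
                   "plasma membrane")
    cx <- add_node(new_id(), c("Complex", "Protein"),
                   sprintf("LIG%d:RCPT%d complex", cas, cas), "plasma membrane")
    add_edge(lig, r0, "input")
    add_edge(r0, cx, "output")
    path <- c(lig, r0, cx)
    reactions <- c(reactions, r0)
    prev <- cx
    kin <- character(0)
    for (k in seq_len(spec$cascade_length)) {
      rk <- add_node(new_id(), "Reaction",
                     sprintf("phosphorylation-%d-%d", cas, k), "cytosol")
      kk <- add_node(new_id(), "Protein", sprintf("SYNK%d%s", cas, LETTERS[k]),
                     "cytosol")
      add_edge(prev, rk, "catalyst")
      add_edge(rk, kk, "output")
      path <- c(path, rk, kk)
      reactions <- c(reactions, rk)
      prev <- kk
      kin <- c(kin, kk)
    }
    tf <- add_node(new_id(), c("Protein", "TranscriptionFactor"),
                   sprintf("SYNTF%d", cas), "nucleoplasm")
    add_edge(prev, tf, "positivelyRegulates")
    path <- c(path, tf)
    chains[[cas]] <- list(ligand = lig, target = tf, path = path)
    cascade_kinases[[cas]] <- kin
    cascade_tf <- c(cascade_tf, tf)
    ligands <- c(ligands, lig)
  }

  # currency hub: ATP as output of some reactions and input to others,
  # spread deterministically over all reactions -> cross-cascade shortcuts
  hub <- add_node(new_id(), "SimpleEntity", "ATP", "cytosol")
  if (spec$currency_hub_degree > 0 && length(reactions)) {
    deg <- min(spec$currency_hub_degree, length(reactions))
    picked <- sample(reactions, deg)
    half <- ceiling(deg / 2)
    for (r in picked[seq_len(half)]) add_edge(r, hub, "output")
    for (r in picked[-seq_len(half)]) add_edge(hub, r, "input")
  }
  ubi <- add_node(new_id(), "Protein", "ubiquitin", "cytosol")
  if (length(reactions)) add_edge(ubi, sample(reactions, 1), "regulator")

  # bystander metabolites: co-inputs to random reactions (cannot shorten a
  # ligand->TF route: they only add sources, not alternative bridges)
  bystanders <- character(0)
  for (b in seq_len(spec$n_metabolites)) {
    met <- add_node(new_id(), "SimpleEntity", sprintf("bystander-%d", b),
                    "extracellular region")
    if (length(reactions)) add_edge(met, sample(reactions, 1), "input")
    bystanders <- c(bystanders, met)
  }

  # decoys removed by preprocessing: provenance nodes + non-human protein
  decoys <- c(
    add_node(new_id(), "Person", "A. Curator", species = ""),
    add_node(new_id(), "Affiliation", "Some Institute", species = ""),
    add_node(new_id(), "Taxon", "Mus musculus", species = ""),
    add_node(new_id(), "Protein", "Synk1a (mouse)", "cytosol",
             species = "Mus musculus"))
  if (length(reactions)) {
    add_edge(decoys[4], sample(reactions, 1), "catalyst")
    add_edge(decoys[1], decoys[2], "affiliatedWith")
  }

  # downstream fan-out: terminal TFs / last kinases -> export reactions ->
  # bystander metabolites; leaves every planted route unique
  if (spec$extra_random_edges > 0 && length(bystanders) && spec$n_cascades > 0) {
    for (i in seq_len(spec$extra_random_edges)) {
      src <- sample(c(cascade_tf, vapply(cascade_kinases, utils::tail,
                                         character(1), 1)), 1)
      tgt <- sample(bystanders, 1)
      rex <- add_node(new_id(), "Reaction", sprintf("export-%d", i), "cytosol")
      add_edge(src, rex, "catalyst")
      add_edge(rex, tgt, "output")
    }
  }

  node_df <- data.frame(
    id = vapply(nodes, `[[`, character(1), "id"),
    display_name = vapply(nodes, `[[`, character(1), "display_name"),
    species = vapply(nodes, `[[`, character(1), "species"),
    is_currency = FALSE, stringsAsFactors = FALSE)
  node_df$labels <- lapply(nodes, function(x) x$labels[[1]])
  node_df$compartments <- lapply(nodes, function(x) x$compartments[[1]])
  edge_df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(edge_df) <- c("source", "target", "type")
  edge_df <- edge_df[!duplicated(paste(edge_df$source, edge_df$target,
                                       edge_df$type, sep = "\r")), ]
  g <- property_graph(node_df, edge_df)

  human <- !(vapply(node_df$labels, function(l)
    any(l %in% c("Person", "Affiliation", "Taxon")), logical(1))) &
    (node_df$species %in% c("", "Homo sapiens"))
  manifest <- list(chains = chains, kinases = cascade_kinases,
                   tf = cascade_tf, ligands = ligands,
                   hub_id = hub, ubiquitin_id = ubi,
                   bystanders = bystanders,
                   human_node_count = sum(human), decoys = decoys,
                   spec = unclass(spec))
  list(graph = g, manifest = manifest)
}

#' Generate synthetic gene-to-GO annotations with one planted term
#'
#' Gene-like nodes are the human Protein nodes of the graph (identified by
#' display name). Each gene receives random term assignments at a fixed
#' per-term rate, and one designated term is planted: it annotates exactly
#' the kinases of the first cascade (plus nothing else), so querying that
#' subset must rank the planted term first by q.
#'
#' @param g a generated `property_graph` (raw or preprocessed)
#' @param manifest the manifest returned with `g`
#' @param n_terms number of random background terms (default 20); 0 yields
#'   an empty annotation set with no planted term
#' @param rate per-gene probability of each random term (default 0.15)
#' @param seed integer seed
#' @return list with `annotations` (an [annotation_set()] over gene
#'   display names), `planted_term`, `planted_genes` (display names)
#' @export
generate_annotations <- function(g, manifest, n_terms = 20L, rate = 0.15,
                                 seed = 1L) {
  set.seed(seed)
  is_gene <- vapply(g$nodes$labels, function(l) "Protein" %in% l, logical(1)) &
    g$nodes$species %in% c("", "Homo sapiens") &
    !g$nodes$is_currency & tolower(g$nodes$display_name) != "ubiquitin"
  gene_ids <- g$nodes$id[is_gene]
  genes <- g$nodes$display_name[is_gene]
  names(genes) <- gene_ids
  pairs <- list()
  if (n_terms > 0) {
    for (ti in seq_len(n_terms)) {
      term <- sprintf("GO:%07d", ti)
      hit <- genes[stats::runif(length(genes)) < rate]
      if (length(hit)) pairs[[length(pairs) + 1L]] <-
          data.frame(gene = unname(hit), term = term, stringsAsFactors = FALSE)
    }
  }
  planted_term <- "GO:9999999"
  planted_ids <- if (n_terms > 0) manifest$kinases[[1]] %||% character(0) else character(0)
  planted_genes <- unname(genes[planted_ids[planted_ids %in% names(genes)]])
  if (length(planted_genes)) {
    pairs[[length(pairs) + 1L]] <-
      data.frame(gene = planted_genes, term = planted_term,
                 stringsAsFactors = FALSE)
  }
  tab <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene = character(0), term = character(0))
  ann <- annotation_set(tab, background = sort(unique(unname(genes))))
  list(annotations = ann, planted_term = planted_term,
       planted_genes = sort(planted_genes))
}

#' Build an entity dictionary and description table for a fixture graph
#'
#' Gives every human Protein node a dictionary entry of type `"gene"` (its
#' display name) plus a few chemical entries for the metabolites, and a
#' description table whose text for each kinase mentions the next kinase
#' in its cascade, so one round of semantic expansion walks one step down
#' the cascade.
#'
#' @param g a generated `property_graph`
#' @param manifest the generator manifest
#' @return list with `dictionary` (an [entity_dictionary()]) and
#'   `descriptions` (an [enrichment_table()] source data.frame)
#' @export
generate_dictionary <- function(g, manifest) {
  is_gene <- vapply(g$nodes$labels, function(l) "Protein" %in% l, logical(1)) &
    g$nodes$species %in% c("", "Homo sapiens")
  genes <- g$nodes$display_name[is_gene]
  is_chem <- vapply(g$nodes$labels, function(l) "SimpleEntity" %in% l, logical(1))
  chems <- unique(g$nodes$display_name[is_chem])
  dict <- entity_dictionary(rbind(
    data.frame(term = genes, id = genes, type = "gene", stringsAsFactors = FALSE),
    data.frame(term = chems, id = chems, type = "chemical", stringsAsFactors = FALSE)))
  id2name <- stats::setNames(g$nodes$display_name, g$nodes$id)
  rows <- list()
  for (cas in seq_along(manifest$kinases)) {
    kin <- manifest$kinases[[cas]]
    seqn <- c(kin, manifest$tf[cas])
    for (i in seq_along(seqn)) {
      gene <- id2name[[seqn[i]]]
      nxt <- if (i < length(seqn)) id2name[[seqn[i + 1]]] else NULL
      txt <- sprintf("%s is a signaling component of cascade %d.%s", gene, cas,
                     if (is.null(nxt)) "" else
                       sprintf(" It phosphorylates and activates %s.", nxt))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, ncbi = txt, uniprot = "", stringdb = "", go = "",
        stringsAsFactors = FALSE)
    }
  }
  descriptions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), ncbi = character(0))
  list(dictionary = dict, descriptions = descriptions)
}

#' Write a complete fixture bundle to a directory
#'
#' Writes node/edge TSVs, annotation TSV, dictionary TSV, description
#' table TSV and a JSON manifest, all byte-stable for a given spec.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory (created if needed)
#' @return invisibly, a named vector of the written paths
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_pathway_graph(spec)
  ann <- generate_annotations(fx$graph, fx$manifest, seed = spec$seed)
  dic <- generate_dictionary(fx$graph, fx$manifest)
  paths <- c(nodes = file.path(dir, "nodes.tsv"),
             edges = file.path(dir, "edges.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             dictionary = file.path(dir, "dictionary.tsv"),
             descriptions = file.path(dir, "descriptions.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_pathway_graph(fx$graph, paths["nodes"], paths["edges"])
  ann_pairs <- do.call(rbind, lapply(names(ann$annotations$gene2term), function(gn) {
    data.frame(gene = gn, term = ann$annotations$gene2term[[gn]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ann_pairs, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(dic$dictionary), paths["dictionary"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dic$descriptions, paths["descriptions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest_out <- fx$manifest
  manifest_out$planted_term <- ann$planted_term
  manifest_out$planted_genes <- ann$planted_genes
  jsonlite::write_json(manifest_out, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
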