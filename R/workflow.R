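#' Workflow configuration
#'
#' Bundles everything [run_workflow()] needs: the graph tables, the source
#' identifiers (e.g. differential plasma metabolites), analysis
#' parameters, the enrichment inputs and the output directory. Referenced
#' files must exist at run time.
#'
#' @param node_table,edge_table graph TSV paths (see [read_pathway_graph()])
#' @param sources character vector of source identifiers
#' @param compartment preferred compartment for source lookup
#' @param directions radiate directions to run (default both)
#' @param label_filter node label whose carriers are ranked and traced
#' @param top_k how many top-ranked nodes to keep and use as trace targets
#' @param trace_modes path criteria to trace (`"hops"`, `"influence"`)
#' @param annotations path to gene-term TSV (see [read_annotations()])
#' @param dictionary path to entity dictionary TSV
#' @param descriptions path to per-gene description TSV
#' @param semantic_iterations rounds of semantic expansion (0 = skip)
#' @param alpha enrichment significance level on q
#' @param out_dir output directory
#' @param seed integer seed echoed into the report (the pipeline itself is
#'   deterministic given its inputs)
#' @param preprocess a [preprocess_config()]
#' @param ppr a [ppr_config()]
#' @param exclude_currency drop currency nodes from the traversal view
#' @return a `workflow_config` list
#' @export
workflow_config <- function(node_table, edge_table, sources,
                            compartment = "extracellular region",
                            directions = c("forward", "reverse"),
                            label_filter = "Protein", top_k = 10L,
                            trace_modes = c("hops", "influence"),
                            annotations = NULL, dictionary = NULL,
                            descriptions = NULL, semantic_iterations = 0L,
                            alpha = 0.05, out_dir = ".", seed = 1L,
                            preprocess = preprocess_config(),
                            ppr = ppr_config(), exclude_currency = TRUE) {
  for (p in c(node_table, edge_table, annotations, dictionary, descriptions)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_kg("workflow input does not exist: ", p, class = "kg_config_error")
    }
  }
  structure(list(node_table = node_table, edge_table = edge_table,
                 sources = sources, compartment = compartment,
                 directions = directions, label_filter = label_filter,
                 top_k = as.integer(top_k), trace_modes = trace_modes,
                 annotations = annotations, dictionary = dictionary,
                 descriptions = descriptions,
                 semantic_iterations = as.integer(semantic_iterations),
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
                 preprocess = preprocess, ppr = ppr,
                 exclude_currency = exclude_currency),
            class = "workflow_config")
}

#' Run the complete radiate-analysis workflow
#'
#' Orchestrates, in order: graph preprocessing; forward and reverse
#' radiate analysis from the resolved source nodes; ranking of the
#' filtered label class; all-shortest-path and highest-influence tracing
#' from sources to the top-ranked nodes with Sankey export; enrichment
#' table assembly; GO enrichment of the top-ranked genes; entity-cloud
#' counting; and (optionally) iterative semantic expansion. Every stage
#' writes its artifact under `cfg$out_dir` and is echoed, with its
#' parameters and counts, into `report.json` — the machine-readable
#' storyboard of the run. Any stage failure aborts with the stage name and
#' cause; artifacts of completed stages are retained.
#'
#' The run is fully reproducible: given the same inputs and config the
#' report is byte-identical except for the single `timestamp` field.
#'
#' @param cfg a [workflow_config()]
#' @param verbose emit stage-scoped progress messages to stderr
#' @return the report, invisibly (also written to
#'   `file.path(cfg$out_dir, "report.json")`)
#' @export
run_workflow <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stages <- list()
  say <- function(stage, ...) if (verbose) message("[", stage, "] ", ...)
  run_stage <- function(name, params, fun) {
    say(name, "running")
    out <- tryCatch(fun(), error = function(e) {
      stop_kg("stage '", name, "' failed: ", conditionMessage(e),
              class = "kg_stage_failure")
    })
    stages[[length(stages) + 1L]] <<- c(list(name = name, params = params),
                                        out$meta)
    out$value
  }
  art <- function(f) file.path(cfg$out_dir, f)

  graph <- run_stage("preprocess",
    list(node_table = cfg$node_table, edge_table = cfg$edge_table,
         keep_species = cfg$preprocess$keep_species,
         drop_labels = cfg$preprocess$drop_labels,
         exclude_currency = cfg$exclude_currency), function() {
    raw <- read_pathway_graph(cfg$node_table, cfg$edge_table)
    pp <- preprocess_pathway_graph(raw, cfg$preprocess)
    write_pathway_graph(pp, art("graph_nodes.tsv"), art("graph_edges.tsv"))
    list(value = pp,
         meta = list(outputs = c(art("graph_nodes.tsv"), art("graph_edges.tsv")),
                     counts = list(raw_nodes = n_nodes(raw), raw_edges = n_edges(raw),
                                   nodes = n_nodes(pp), edges = n_edges(pp),
                                   currency = sum(pp$nodes$is_currency))))
  })
  view <- traversal_view(graph, cfg$preprocess, exclude_currency = cfg$exclude_currency)
  src <- find_nodes(view, cfg$sources, cfg$compartment)

  results <- list()
  for (dir in cfg$directions) {
    results[[dir]] <- run_stage(paste0("radiate_", dir),
      list(sources = src, direction = dir, damping = cfg$ppr$damping,
           tol = cfg$ppr$tol), function() {
      r <- radiate(view, src, dir, cfg$ppr)
      tab <- rank_nodes(r, view)
      f <- art(paste0("radiate_", dir, ".tsv"))
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = r, meta = list(outputs = f,
           counts = list(n_sources = length(src), n_scored = length(r$scores),
                         iterations = r$iterations, converged = r$converged)))
    })
  }
  fwd <- results[["forward"]] %||% results[[1]]

  ranked <- run_stage("rank",
    list(label_filter = cfg$label_filter, top_k = cfg$top_k), function() {
    tab <- rank_nodes(fwd, view, label_filter = cfg$label_filter,
                      top_k = cfg$top_k)
    f <- art("top_ranked.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = tab, meta = list(outputs = f,
         counts = list(n_ranked = nrow(tab))))
  })
  targets <- setdiff(ranked$node_id, src)
  if (!length(targets)) targets <- ranked$node_id

  traces <- run_stage("trace",
    list(modes = cfg$trace_modes, n_targets = length(targets)), function() {
    outs <- character(0); counts <- list()
    for (mode in cfg$trace_modes) {
      ps <- if (mode == "hops") {
        all_shortest_paths_pg(view, src, targets)
      } else {
        w <- influence_weights(view, fwd, cfg$ppr)
        highest_influence_paths(view, w, src, targets)
      }
      tg <- build_trace_graph(ps)
      f <- art(paste0("sankey_", mode, ".json"))
      export_sankey(tg, f)
      outs <- c(outs, f)
      counts[[mode]] <- list(n_paths = length(ps$paths),
                             n_unreachable = length(ps$unreachable),
                             truncated = ps$truncated)
    }
    list(value = NULL, meta = list(outputs = outs, counts = counts))
  })

  genes <- unique(ranked$display_name)
  etab <- NULL
  if (!is.null(cfg$descriptions)) {
    etab <- run_stage("enrichment_table",
      list(descriptions = cfg$descriptions, n_genes = length(genes)), function() {
      desc <- utils::read.delim(cfg$descriptions, sep = "\t", quote = "",
                                stringsAsFactors = FALSE, colClasses = "character")
      tab <- enrichment_table(genes, desc)
      f <- art("enrichment_table.tsv")
      utils::write.table(as.data.frame(tab), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(value = tab, meta = list(outputs = f,
           counts = list(n_rows = nrow(tab))))
    })
  }

  if (!is.null(cfg$annotations)) {
    run_stage("go_enrichment",
      list(annotations = cfg$annotations, alpha = cfg$alpha), function() {
      ann <- read_annotations(cfg$annotations)
      res <- suppressWarnings(go_enrichment(genes, ann, alpha = cfg$alpha))
      f <- art("go_enrichment.tsv")
      write_enrichment(res, f)
      list(value = res, meta = list(outputs = f,
           counts = list(n_terms = nrow(res),
                         n_significant = sum(res$significant))))
    })
  }

  if (!is.null(cfg$dictionary) && !is.null(etab)) {
    dict <- read_dictionary(cfg$dictionary)
    run_stage("entity_cloud", list(dictionary = cfg$dictionary), function() {
      cloud <- entity_cloud(etab, dict)
      f <- art("entity_cloud.tsv")
      utils::write.table(data.frame(concept = names(cloud),
                                    count = as.integer(cloud)),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = cloud, meta = list(outputs = f,
           counts = list(n_concepts = length(cloud))))
    })
    if (cfg$semantic_iterations > 0) {
      run_stage("semantic_expand",
        list(iterations = cfg$semantic_iterations), function() {
        full <- read_enrichment_table(cfg$descriptions)
        expanded <- semantic_expand(genes, full, dict,
                                    iterations = cfg$semantic_iterations)
        f <- art("expanded_genes.txt")
        writeLines(expanded, f)
        list(value = expanded, meta = list(outputs = f,
             counts = list(n_seed = length(genes), n_expanded = length(expanded))))
      })
    }
  }

  report <- list(tool = "kgradiate",
                 version = as.character(utils::packageVersion("kgradiate")),
                 seed = cfg$seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = list(sources = cfg$sources,
                               compartment = cfg$compartment,
                               directions = cfg$directions,
                               label_filter = cfg$label_filter,
                               top_k = cfg$top_k,
                               trace_modes = cfg$trace_modes,
                               alpha = cfg$alpha,
                               damping = cfg$ppr$damping,
                               exclude_currency = cfg$exclude_currency,
                               semantic_iterations = cfg$semantic_iterations),
                 resolved_sources = src,
                 stages = stages)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
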