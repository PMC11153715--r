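#' Influence weighting of edges from radiate scores
#'
#' Each edge (u, v) of the traversal view receives weight
#' \deqn{w(u,v) = 1 / \max(\pi(u), \pi(v), \epsilon)}
#' the inverse of the larger personalized-PageRank score of its two
#' endpoints, floored at `cfg$epsilon_floor` so zero-score nodes keep
#' finite weights (connectivity is preserved rather than dropping
#' unreached edges). Edges between influential nodes are therefore cheap,
#' and minimum-weight paths are the paths of highest influence.
#'
#' @param g the traversal view (`property_graph`)
#' @param r a `radiate_result` whose scores cover every node of `g`
#' @param cfg a [ppr_config()] (supplies `epsilon_floor`)
#' @return an `influence_weighting`: data.frame `source`, `target`,
#'   `type`, `weight`, one row per edge of `g`
#' @export
influence_weights <- function(g, r, cfg = ppr_config()) {
  stopifnot(inherits(r, "radiate_result"))
  missing <- setdiff(g$nodes$id, names(r$scores))
  if (length(missing)) {
    stop_kg("radiate result lacks scores for node(s): ",
            paste(utils::head(missing, 5), collapse = ", "),
            class = "kg_inconsistency_error")
  }
  e <- g$edges
  w <- 1 / pmax(r$scores[e$source], r$scores[e$target], cfg$epsilon_floor)
  out <- data.frame(source = e$source, target = e$target, type = e$type,
                    weight = unname(w), stringsAsFactors = FALSE)
  structure(out, class = c("influence_weighting", "data.frame"))
}

# Shared engine for both path modes. Enumerates, per (source, target)
# pair, every simple directed path whose cost is within rel_tol
# (relative) of the minimum, by depth-first search pruned with exact
# shortest-path distances to the target (admissible, so no minimal path
# is lost). weights = NULL means hop counting.
find_min_cost_paths <- function(g, sources, targets, weights = NULL,
                                rel_tol = 0, max_paths = 10000L) {
  validate_property_graph(g)
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (!length(sources) || !length(targets)) {
    stop_kg("sources and targets must be non-empty", class = "kg_precondition_error")
  }
  missing <- setdiff(c(sources, targets), g$nodes$id)
  if (length(missing)) {
    stop_kg("node(s) not in graph: ", paste(missing, collapse = ", "),
            class = "kg_unknown_source")
  }
  ids <- g$nodes$id
  n <- length(ids)
  e <- g$edges
  if (nrow(e)) {
    if (is.null(weights)) {
      ew <- rep(1, nrow(e))
    } else {
      key_g <- paste(e$source, e$target, e$type, sep = "\r")
      key_w <- paste(weights$source, weights$target, weights$type, sep = "\r")
      m <- match(key_g, key_w)
      if (anyNA(m)) stop_kg("weighting does not cover every edge",
                            class = "kg_inconsistency_error")
      ew <- weights$weight[m]
      if (any(!is.finite(ew)) || any(ew <= 0)) {
        stop_kg("edge weights must be finite and > 0", class = "kg_inconsistency_error")
      }
    }
    # collapse parallel edges: a path is a node sequence, so only the
    # cheapest transition between an ordered pair matters
    pair <- paste(e$source, e$target, sep = "\r")
    wmin <- tapply(ew, pair, min)
    upair <- names(wmin)
    parts <- strsplit(upair, "\r", fixed = TRUE)
    usrc <- vapply(parts, `[`, character(1), 1)
    utgt <- vapply(parts, `[`, character(1), 2)
    si <- match(usrc, ids); ti <- match(utgt, ids)
    adj <- split(data.frame(to = ti, w = as.numeric(wmin)), si)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = usrc, to = utgt, weight = as.numeric(wmin)),
      directed = TRUE, vertices = data.frame(name = ids))
  } else {
    adj <- list()
    ig <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ids)
  }
  # dist_to_target[v, t]: exact shortest distance from v to each target
  dist_to <- t(igraph::distances(ig, v = targets, to = ids, mode = "in",
                                 weights = if (nrow(e)) igraph::E(ig)$weight else NULL))
  rownames(dist_to) <- ids
  colnames(dist_to) <- targets

  paths <- list()
  costs <- numeric(0)
  path_src <- character(0)
  path_tgt <- character(0)
  unreachable <- list()
  truncated <- FALSE

  for (s in sources) {
    for (t in targets) {
      mincost <- dist_to[s, t]
      if (!is.finite(mincost)) {
        unreachable[[length(unreachable) + 1L]] <- c(s, t)
        next
      }
      budget <- mincost * (1 + rel_tol) + 1e-12
      s_i <- match(s, ids); t_i <- match(t, ids)
      found <- list(); found_cost <- numeric(0)
      n_found <- 0L
      # iterative DFS with explicit stack of (node, cost); path kept as vector
      on_path <- logical(n)
      dfs <- function(v_i, cost, path) {
        if (n_found >= max_paths) { truncated <<- TRUE; return() }
        if (v_i == t_i) {
          n_found <<- n_found + 1L
          found[[n_found]] <<- ids[path]
          found_cost[n_found] <<- cost
          return()
        }
        nb <- adj[[as.character(v_i)]]
        if (is.null(nb)) return()
        for (k in seq_len(nrow(nb))) {
          u <- nb$to[k]
          if (on_path[u]) next
          c2 <- cost + nb$w[k]
          rem <- dist_to[u, t]
          if (!is.finite(rem) || c2 + rem > budget) next
          on_path[u] <<- TRUE
          dfs(u, c2, c(path, u))
          on_path[u] <<- FALSE
        }
      }
      on_path[s_i] <- TRUE
      dfs(s_i, 0, s_i)
      if (n_found) {
        keep <- found_cost <= budget
        paths <- c(paths, found[keep])
        costs <- c(costs, found_cost[keep])
        path_src <- c(path_src, rep(s, sum(keep)))
        path_tgt <- c(path_tgt, rep(t, sum(keep)))
      }
    }
  }
  # deterministic order: by source, target, then lexicographic node sequence
  if (length(paths)) {
    keyp <- vapply(paths, function(p) paste(p, collapse = "\r"), character(1))
    ord <- order(path_src, path_tgt, lengths(paths), keyp)
    paths <- paths[ord]; costs <- costs[ord]
    path_src <- path_src[ord]; path_tgt <- path_tgt[ord]
  }
  structure(list(mode = if (is.null(weights)) "hops" else "influence",
                 paths = paths, costs = costs,
                 sources = path_src, targets = path_tgt,
                 unreachable = unreachable, truncated = truncated,
                 graph = g),
            class = "path_set")
}

#' All shortest paths between source and target sets
#'
#' For every (source, target) pair, returns all directed paths with the
#' minimum number of edges. Unreachable pairs are recorded in
#' `$unreachable`, not errored. A source equal to a target yields the
#' single zero-length path.
#'
#' @param g the traversal view (`property_graph`)
#' @param sources,targets character vectors of node ids, non-empty
#' @param max_paths cap on paths per (source, target) pair; exceeding it
#'   sets `$truncated = TRUE` (never silent)
#' @return a `path_set`: `mode`, `paths` (list of node-id sequences),
#'   `costs` (edge counts), per-path `sources`/`targets`, `unreachable`,
#'   `truncated`
#' @export
all_shortest_paths_pg <- function(g, sources, targets, max_paths = 10000L) {
  find_min_cost_paths(g, sources, targets, weights = NULL,
                      rel_tol = 0, max_paths = max_paths)
}

#' Paths of highest influence
#'
#' All paths whose total influence weight (sum of inverse-max-PPR edge
#' weights, see [influence_weights()]) is within `rel_tol` (relative) of
#' the minimum per (source, target) pair. With uniform scores this reduces
#' to [all_shortest_paths_pg()]. The tie tolerance exists because weighted
#' minimality is a floating-point comparison.
#'
#' @param g the traversal view
#' @param weighting an [influence_weights()] result covering every edge
#' @param sources,targets node id vectors
#' @param rel_tol relative tolerance for counting a path as minimal
#' @param max_paths cap per pair, truncation flagged
#' @return a `path_set` with `mode = "influence"`
#' @export
highest_influence_paths <- function(g, weighting, sources, targets,
                                    rel_tol = 1e-9, max_paths = 10000L) {
  find_min_cost_paths(g, sources, targets, weights = weighting,
                      rel_tol = rel_tol, max_paths = max_paths)
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set (%s): %d path(s), %d unreachable pair(s)%s\n",
              x$mode, length(x$paths), length(x$unreachable),
              if (x$truncated) " [TRUNCATED]" else ""))
  invisible(x)
}

#' Assemble a trace graph from a path set
#'
#' The trace graph is the union of all selected source-to-target paths:
#' nodes carry a role (`source`, `target` or `intermediate`; source wins
#' over target for degenerate zero-length paths) and every edge carries
#' `traversal_count`, the number of paths using it. Node ordering is
#' deterministic (sorted by id).
#'
#' @param p a `path_set`
#' @return a `trace_graph` with data.frames `nodes` (`id`, `name`, `role`)
#'   and `edges` (`source`, `target`, `edge_type`, `traversal_count`)
#' @export
build_trace_graph <- function(p) {
  stopifnot(inherits(p, "path_set"))
  g <- p$graph
  if (!length(p$paths)) {
    warn_kg("empty path set; trace graph has no nodes")
    return(structure(list(
      nodes = data.frame(id = character(0), name = character(0),
                         role = character(0), stringsAsFactors = FALSE),
      edges = data.frame(source = character(0), target = character(0),
                         edge_type = character(0), traversal_count = integer(0),
                         stringsAsFactors = FALSE)),
      class = "trace_graph"))
  }
  all_nodes <- sort(unique(unlist(p$paths)))
  role <- rep("intermediate", length(all_nodes))
  names(role) <- all_nodes
  role[unique(p$targets)] <- "target"
  role[unique(p$sources)] <- "source"
  # tally consecutive pairs over all paths
  pair_from <- character(0); pair_to <- character(0)
  for (path in p$paths) {
    if (length(path) >= 2) {
      pair_from <- c(pair_from, path[-length(path)])
      pair_to <- c(pair_to, path[-1])
    }
  }
  if (length(pair_from)) {
    key <- paste(pair_from, pair_to, sep = "\r")
    counts <- table(key)
    parts <- strsplit(names(counts), "\r", fixed = TRUE)
    esrc <- vapply(parts, `[`, character(1), 1)
    etgt <- vapply(parts, `[`, character(1), 2)
    # annotate with the underlying edge types (';'-joined when parallel)
    gkey <- paste(g$edges$source, g$edges$target, sep = "\r")
    etype <- vapply(names(counts), function(k) {
      paste(sort(unique(g$edges$type[gkey == k])), collapse = ";")
    }, character(1))
    edges <- data.frame(source = esrc, target = etgt, edge_type = unname(etype),
                        traversal_count = as.integer(counts),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        edge_type = character(0), traversal_count = integer(0),
                        stringsAsFactors = FALSE)
  }
  m <- match(all_nodes, g$nodes$id)
  nodes <- data.frame(id = all_nodes,
                      name = ifelse(is.na(m), all_nodes, g$nodes$display_name[m]),
                      role = unname(role),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "trace_graph")
}

#' @export
print.trace_graph <- function(x, ...) {
  cat(sprintf("trace_graph: %d nodes (%d source, %d target), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "source"),
              sum(x$nodes$role == "target"), nrow(x$edges)))
  invisible(x)
}

#' Export a trace graph as Sankey JSON
#'
#' Writes the index-based nodes/links JSON dialect used by plotly and d3
#' Sankey renderers: `"nodes"` is an array of `{id, name, role}` objects
#' and `"links"` an array of `{source_index, target_index, value,
#' edge_type}` with 0-based indices into the nodes array and
#' `value = traversal_count`. Output is byte-stable for a given trace.
#'
#' @param tg a `trace_graph`
#' @param out output file path
#' @return `out`, invisibly
#' @export
export_sankey <- function(tg, out) {
  stopifnot(inherits(tg, "trace_graph"))
  nodes <- lapply(seq_len(nrow(tg$nodes)), function(i) {
    list(id = tg$nodes$id[i], name = tg$nodes$name[i], role = tg$nodes$role[i])
  })
  links <- lapply(seq_len(nrow(tg$edges)), function(i) {
    list(source_index = match(tg$edges$source[i], tg$nodes$id) - 1L,
         target_index = match(tg$edges$target[i], tg$nodes$id) - 1L,
         value = tg$edges$traversal_count[i],
         edge_type = tg$edges$edge_type[i])
  })
  payload <- list(nodes = nodes, links = links)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, out, useBytes = TRUE)
  invisible(out)
}
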