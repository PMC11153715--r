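#' Personalized-PageRank configuration
#'
#' @param damping restart-complement probability d in (0,1); default 0.85,
#'   the conventional PageRank value (the method names the algorithm but
#'   fixes no parameters).
#' @param tol convergence tolerance on the L1 change of the score vector
#'   between iterations
#' @param max_iter maximum number of power iterations
#' @param epsilon_floor smallest usable score, used when inverting scores
#'   into edge weights so zero-score nodes do not produce infinite weights
#' @return a `ppr_config` list
#' @export
ppr_config <- function(damping = 0.85, tol = 1e-10, max_iter = 1000,
                       epsilon_floor = 1e-12) {
  if (!(damping > 0 && damping < 1)) stop_kg("damping must be in (0,1)",
                                             class = "kg_config_error")
  if (tol <= 0) stop_kg("tol must be > 0", class = "kg_config_error")
  structure(list(damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 epsilon_floor = epsilon_floor), class = "ppr_config")
}

#' Radiate analysis: personalized PageRank from a source set
#'
#' Ranks every node of the traversal view by personalized PageRank with
#' the teleport vector uniform over the source set. Forward direction uses
#' edge directionality as is and answers "which nodes are highly
#' influenced by the sources?"; reverse direction flips every edge before
#' the computation and answers "which nodes most influence the sources?".
#'
#' The chain is iterated as
#' \deqn{x_{t+1} = d\, x_t P + \big(d \sum_{u \in D} x_t(u) + (1-d)\big) v}
#' where `P` is the out-degree-normalized transition matrix (parallel
#' edges collapse to one transition with weight proportional to
#' multiplicity), `D` the dangling (out-degree-zero) nodes whose mass is
#' redistributed along the teleport vector `v`, and `d` the damping
#' factor. Convergence is declared when the L1 change drops below
#' `cfg$tol`. The converged vector is renormalized to sum exactly 1 to
#' absorb floating-point drift.
#'
#' @param g the traversal view (`property_graph`) to propagate on
#' @param sources character vector of source node ids, all present in `g`
#' @param direction `"forward"` or `"reverse"`
#' @param cfg a [ppr_config()]
#' @return a `radiate_result` list: `direction`, `sources`, `scores`
#'   (named numeric, sum 1, all nodes of `g`), `converged`, `iterations`.
#' @export
radiate <- function(g, sources, direction = c("forward", "reverse"),
                    cfg = ppr_config()) {
  direction <- match.arg(direction)
  if (direction == "reverse") {
    res <- radiate(reverse_edges(g), sources, "forward", cfg)
    res$direction <- "reverse"
    return(res)
  }
  validate_property_graph(g)
  sources <- unique(as.character(sources))
  if (!length(sources)) stop_kg("source set is empty", class = "kg_precondition_error")
  missing <- setdiff(sources, g$nodes$id)
  if (length(missing)) {
    stop_kg("source node(s) not in graph: ", paste(missing, collapse = ", "),
            class = "kg_unknown_source")
  }
  ids <- g$nodes$id
  n <- length(ids)
  v <- numeric(n)
  v[match(sources, ids)] <- 1 / length(sources)

  e <- g$edges
  if (nrow(e)) {
    i <- match(e$source, ids)
    j <- match(e$target, ids)
    # parallel edges between the same ordered pair accumulate multiplicity
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  outdeg <- Matrix::rowSums(A)
  dangling <- outdeg == 0
  inv_out <- ifelse(dangling, 0, 1 / outdeg)
  d <- cfg$damping
  x <- v
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    x_new <- d * as.numeric(Matrix::crossprod(A, x * inv_out)) +
      (d * sum(x[dangling]) + (1 - d)) * v
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) warn_kg("radiate did not converge in ", cfg$max_iter,
                          " iterations", class = "kg_nonconvergence")
  x <- x / sum(x)
  structure(list(direction = direction, sources = sources,
                 scores = stats::setNames(x, ids),
                 converged = converged, iterations = iter),
            class = "radiate_result")
}

#' @export
print.radiate_result <- function(x, ...) {
  cat(sprintf("radiate_result (%s): %d nodes, %d source(s), %d iteration(s)%s\n",
              x$direction, length(x$scores), length(x$sources), x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top scores:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Rank nodes of a radiate result
#'
#' Orders nodes by descending score, ties broken by ascending node id, and
#' optionally restricts to nodes carrying a given label (e.g. `"Protein"`
#' to extract the highly relevant protein nodes).
#'
#' @param r a `radiate_result`
#' @param g the `property_graph` the result was computed on (supplies
#'   labels and display names); may be omitted when `label_filter` is NULL
#' @param label_filter node label to keep, or `NULL` for all nodes
#' @param top_k keep the first `top_k` rows, or `NULL` for all
#' @return data.frame with columns `node_id`, `display_name`, `labels`,
#'   `pagerank`, `rank` (1-based, after filtering)
#' @export
rank_nodes <- function(r, g = NULL, label_filter = NULL, top_k = NULL) {
  stopifnot(inherits(r, "radiate_result"))
  ids <- names(r$scores)
  ord <- order(-r$scores, ids)
  ids <- ids[ord]
  sc <- unname(r$scores[ord])
  if (!is.null(g)) {
    m <- match(ids, g$nodes$id)
    dn <- g$nodes$display_name[m]
    labs <- join_list_col(g$nodes$labels[m])
  } else {
    dn <- ids
    labs <- rep("", length(ids))
  }
  out <- data.frame(node_id = ids, display_name = dn, labels = labs,
                    pagerank = sc, stringsAsFactors = FALSE)
  if (!is.null(label_filter)) {
    if (is.null(g)) stop_kg("label_filter requires the graph", class = "kg_precondition_error")
    keep <- vapply(g$nodes$labels[match(out$node_id, g$nodes$id)],
                   function(l) label_filter %in% l, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
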