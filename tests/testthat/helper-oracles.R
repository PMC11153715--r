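# Shared fixtures and independent oracles for the suite.

# Tiny hand-built graph: two routes A->D plus a currency hub.
toy_graph <- function() {
  nodes <- data.frame(
    id = c("A", "B", "C", "D", "ATP1"),
    labels = I(list("SimpleEntity", "Protein", "Protein", "Protein", "SimpleEntity")),
    display_name = c("met-A", "prot-B", "prot-C", "prot-D", "ATP"),
    compartments = I(list("extracellular region", "cytosol", "cytosol",
                          "nucleoplasm", "cytosol")),
    species = "Homo sapiens", is_currency = FALSE,
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("A", "A", "B", "C", "A", "ATP1"),
    target = c("B", "C", "D", "D", "ATP1", "D"),
    type = c("input", "input", "output", "output", "input", "input"),
    stringsAsFactors = FALSE)
  property_graph(nodes, edges)
}

# Random directed property graph with traversable edge types only.
random_pg <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  pairs$type <- rep("input", nrow(pairs))
  nodes <- data.frame(id = ids,
                      labels = I(as.list(sample(c("Protein", "SimpleEntity"),
                                                n, replace = TRUE))),
                      display_name = paste0("node-", ids),
                      compartments = I(rep(list("cytosol"), n)),
                      species = "Homo sapiens", is_currency = FALSE,
                      stringsAsFactors = FALSE)
  property_graph(nodes, pairs)
}

# Dense power-iteration PPR oracle, formulated independently of the
# package: builds the full n x n Google matrix with dangling rows replaced
# by the teleport vector, iterates to a fixed point.
dense_ppr_oracle <- function(g, sources, damping = 0.85, tol = 1e-14,
                             max_iter = 5000) {
  ids <- g$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(g$edges))) {
    A[g$edges$source[i], g$edges$target[i]] <-
      A[g$edges$source[i], g$edges$target[i]] + 1
  }
  v <- numeric(n); names(v) <- ids
  v[sources] <- 1 / length(sources)
  P <- A
  for (i in seq_len(n)) {
    rs <- sum(A[i, ])
    P[i, ] <- if (rs == 0) v else A[i, ] / rs
  }
  M <- damping * P + (1 - damping) * matrix(v, n, n, byrow = TRUE)
  x <- v
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(x %*% M)
    if (sum(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  names(x) <- ids
  x / sum(x)
}

# Exhaustive minimal-cost path oracle via igraph simple-path enumeration.
# weights: named vector on "src\rtgt" pairs, NULL for hop counting.
enumerate_min_paths <- function(g, s, t, weights = NULL, rel_tol = 1e-9) {
  if (s == t) return(list(list(s)))
  ig <- igraph::graph_from_data_frame(
    unique(g$edges[, c("source", "target")]), directed = TRUE,
    vertices = data.frame(name = g$nodes$id))
  sp <- igraph::all_simple_paths(ig, from = s, to = t, mode = "out")
  if (!length(sp)) return(list())
  paths <- lapply(sp, function(p) igraph::V(ig)$name[as.integer(p)])
  cost <- vapply(paths, function(p) {
    if (is.null(weights)) return(length(p) - 1)
    sum(weights[paste(p[-length(p)], p[-1], sep = "\r")])
  }, numeric(1))
  mc <- min(cost)
  paths[cost <= mc * (1 + rel_tol) + 1e-12]
}

path_key <- function(paths) sort(vapply(paths, paste, character(1), collapse = ">"))

pair_weights <- function(weighting) {
  w <- tapply(weighting$weight,
              paste(weighting$source, weighting$target, sep = "\r"), min)
  stats::setNames(as.numeric(w), names(w))
}
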