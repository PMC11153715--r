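#' Build an annotation set from gene-to-term assignments
#'
#' @param gene2term data.frame with columns `gene`, `term` (one row per
#'   assignment), or a named list gene -> character vector of terms
#' @param background character vector of background genes (the universe,
#'   `N = length(background)`); defaults to all annotated genes. Annotated
#'   genes must be a subset of the background.
#' @param term_names optional named character vector term_id -> name
#' @return an `annotation_set` with forward map (`gene2term`), inverse map
#'   (`term2gene`), `background` and `term_names`
#' @export
annotation_set <- function(gene2term, background = NULL, term_names = NULL) {
  if (is.data.frame(gene2term)) {
    stopifnot(all(c("gene", "term") %in% names(gene2term)))
    fwd <- split(as.character(gene2term$term), as.character(gene2term$gene))
  } else {
    fwd <- gene2term
  }
  fwd <- lapply(fwd, function(x) sort(unique(as.character(x))))
  genes <- names(fwd)
  if (is.null(background)) background <- genes
  background <- sort(unique(as.character(background)))
  if (!all(genes %in% background)) {
    stop_kg("annotated genes outside background: ",
            paste(utils::head(setdiff(genes, background), 5), collapse = ", "),
            class = "kg_invalid_annotation")
  }
  pairs_gene <- rep(genes, lengths(fwd))
  pairs_term <- unlist(fwd, use.names = FALSE)
  inv <- split(pairs_gene, pairs_term)
  inv <- lapply(inv, function(x) sort(unique(x)))
  structure(list(gene2term = fwd, term2gene = inv,
                 background = background,
                 term_names = term_names %||% stats::setNames(names(inv), names(inv))),
            class = "annotation_set")
}

#' Read annotations from a two-column TSV
#'
#' GAF-like format: `gene<TAB>term_id`, one assignment per line, header
#' row `gene	term`. An optional term-name TSV has header `term	name`.
#'
#' @param path assignment TSV path
#' @param term_name_path optional term-name TSV path
#' @param background optional background universe (default: annotated genes)
#' @return an [annotation_set()]
#' @export
read_annotations <- function(path, term_name_path = NULL, background = NULL) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("gene", "term") %in% names(tab))) {
    stop_kg("annotation table missing column(s): ",
            paste(setdiff(c("gene", "term"), names(tab)), collapse = ", "),
            class = "kg_format_error")
  }
  tn <- NULL
  if (!is.null(term_name_path)) {
    nm <- utils::read.delim(term_name_path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, colClasses = "character")
    tn <- stats::setNames(nm$name, nm$term)
  }
  annotation_set(tab, background = background, term_names = tn)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes q-values \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}
#' capped at 1, returned in the input order. Preserves the ranking of the
#' p-values and is invariant to input permutation.
#'
#' @param p numeric vector of p-values, all in `[0, 1]`
#' @return numeric vector of adjusted values, same length and order
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_kg("p-values must lie in [0, 1]", class = "kg_validation_error")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Gene Ontology enrichment by one-sided Fisher exact test
#'
#' For every term annotated to at least one query gene, tests whether the
#' query is enriched for the term using the one-sided (greater) Fisher
#' exact test, i.e. the hypergeometric upper tail
#' \eqn{P(X \ge k)} with `k` query genes annotated to the term, `n` the
#' effective query size, `K` background genes annotated to the term and
#' `N` the background size. The false discovery rate is controlled by
#' Benjamini-Hochberg over all tested terms; a q-value below `alpha`
#' (default 0.05) is flagged significant.
#'
#' Query genes outside the background are dropped with a warning. Terms
#' with zero overlap are not tested (this choice fixes the BH multiplicity
#' `m` and therefore the q-values). No ontology-graph ancestor propagation
#' is performed; annotations are taken as given.
#'
#' @param query character vector of gene names
#' @param ann an [annotation_set()]
#' @param alpha significance level on q
#' @return an `enrichment_result` data.frame with columns `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`, sorted by
#'   `q`, then `p`, then `term_id`. Empty (with warning) when no query
#'   gene is in the background.
#' @export
go_enrichment <- function(query, ann, alpha = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  query <- unique(as.character(query))
  outside <- setdiff(query, ann$background)
  if (length(outside)) {
    warn_kg("dropping ", length(outside), " query gene(s) outside background: ",
            paste(utils::head(outside, 5), collapse = ", "),
            class = "kg_query_outside_background")
    query <- setdiff(query, outside)
  }
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (!length(query)) {
    warn_kg("effective query is empty; no enrichment computed")
    return(empty)
  }
  N <- length(ann$background)
  n <- length(query)
  k_per_term <- vapply(ann$term2gene, function(gs) sum(query %in% gs), integer(1))
  tested <- names(k_per_term)[k_per_term >= 1]
  if (!length(tested)) return(empty)
  k <- k_per_term[tested]
  K <- lengths(ann$term2gene[tested])
  # one-sided Fisher exact == hypergeometric upper tail P(X >= k)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(term_id = tested,
                    term_name = unname(ann$term_names[tested]),
                    k = as.integer(k), n = as.integer(n),
                    K = as.integer(K), N = as.integer(N),
                    p = unname(p), q = q,
                    significant = q < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment result as TSV
#' @param res an `enrichment_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
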