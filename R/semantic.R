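#' Load an entity dictionary
#'
#' Dictionary TSV with header `term	id	type`, one surface form per row.
#' Types follow the eight standard biomedical entity classes: gene,
#' protein, disease, chemical, phenotype, anatomy, food, species.
#'
#' @param path dictionary TSV path
#' @return an `entity_dictionary` data.frame (`term`, `id`, `type`)
#' @export
read_dictionary <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("term", "id", "type") %in% names(tab))) {
    stop_kg("dictionary missing column(s): ",
            paste(setdiff(c("term", "id", "type"), names(tab)), collapse = ", "),
            class = "kg_format_error")
  }
  entity_dictionary(tab)
}

#' @rdname read_dictionary
#' @param tab data.frame with columns `term`, `id`, `type`
#' @export
entity_dictionary <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "id", "type") %in% names(tab)))
  tab <- tab[nzchar(tab$term), c("term", "id", "type")]
  tab <- tab[!duplicated(tab$term), , drop = FALSE]
  # longest-first so the leftmost-longest rule is a first-match scan
  tab <- tab[order(-nchar(tab$term), tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("entity_dictionary", "data.frame"))
}

is_word_char <- function(ch) grepl("^[A-Za-z0-9]$", ch)

#' Dictionary-based entity recognition in free text
#'
#' Finds leftmost-longest, non-overlapping dictionary matches anchored on
#' token boundaries (tokens are maximal alphanumeric runs; a match may
#' span several tokens, e.g. "interleukin 6"). Terms of at least 4
#' characters match case-insensitively; shorter symbols (gene symbols like
#' "SRC") match case-sensitively to avoid false hits on common words.
#'
#' @param text a single character string
#' @param dict an [entity_dictionary()]
#' @return data.frame of mentions sorted by start: `start`, `end` (0-based
#'   half-open character offsets so `substr(text, start+1, end)` equals
#'   `surface`), `surface`, `entity_type`, `concept_id`
#' @export
annotate_text <- function(text, dict) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(start = integer(0), end = integer(0),
                      surface = character(0), entity_type = character(0),
                      concept_id = character(0), stringsAsFactors = FALSE)
  if (!nzchar(text) || !nrow(dict)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nch <- length(chars)
  wordish <- grepl("[A-Za-z0-9]", chars)
  # token starts: word char not preceded by a word char
  tok_start <- which(wordish & !c(FALSE, wordish[-nch]))
  terms <- dict$term
  tlen <- nchar(terms)
  ci <- tlen >= 4
  res <- list()
  pos <- 1L
  starts <- tok_start
  while (length(starts)) {
    st <- starts[1]
    matched <- FALSE
    for (d in seq_along(terms)) {
      en <- st + tlen[d] - 1L
      if (en > nch) next
      cand <- substr(text, st, en)
      hit <- if (ci[d]) tolower(cand) == tolower(terms[d]) else cand == terms[d]
      if (!hit) next
      # right boundary: next char must not be alphanumeric
      if (en < nch && wordish[en + 1L]) next
      res[[length(res) + 1L]] <- data.frame(
        start = st - 1L, end = en, surface = cand,
        entity_type = dict$type[d], concept_id = dict$id[d],
        stringsAsFactors = FALSE)
      starts <- starts[starts > en]  # non-overlapping: resume after match
      matched <- TRUE
      break
    }
    if (!matched) starts <- starts[-1]
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$start), , drop = FALSE]
}

#' Entity cloud: aggregated mention counts
#'
#' Counts recognized entities over a corpus (a character vector of texts
#' or the description columns of an [enrichment_table()]), optionally
#' restricted to one entity type. The counts are what an entity cloud
#' displays size-proportionally.
#'
#' @param texts character vector, or an `enrichment_table`
#' @param dict an [entity_dictionary()]
#' @param entity_type optional filter (e.g. `"gene"`)
#' @return named integer vector concept_id -> count, descending, ties by
#'   concept id
#' @export
entity_cloud <- function(texts, dict, entity_type = NULL) {
  if (inherits(texts, "enrichment_table")) texts <- enrichment_texts(texts)
  counts <- integer(0)
  for (tx in texts) {
    m <- annotate_text(tx, dict)
    if (!is.null(entity_type)) m <- m[m$entity_type == entity_type, , drop = FALSE]
    if (nrow(m)) {
      tb <- table(m$concept_id)
      for (id in names(tb)) {
        prev <- if (id %in% names(counts)) counts[[id]] else 0L
        counts[id] <- prev + tb[[id]]
      }
    }
  }
  if (!length(counts)) return(stats::setNames(integer(0), character(0)))
  counts[order(-counts, names(counts))]
}

#' Per-gene enrichment table of description texts
#'
#' Compiles, per input gene, the textual descriptions (and source URLs)
#' from reference resources -- NCBI, UniProt, StringDB and Gene Ontology
#' in the canonical setup. Descriptions arrive as files; no live queries
#' are made. Missing sources are stored as empty strings.
#'
#' @param genes character vector of gene names (one row each)
#' @param descriptions data.frame with a `gene` column plus one column per
#'   source (free text); extra `<source>_url` columns are carried along
#' @return an `enrichment_table` data.frame, one row per input gene
#' @export
enrichment_table <- function(genes, descriptions) {
  genes <- unique(as.character(genes))
  stopifnot("gene" %in% names(descriptions))
  m <- match(genes, descriptions$gene)
  out <- descriptions[m, , drop = FALSE]
  out$gene <- genes
  for (cl in setdiff(names(out), "gene")) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), "", as.character(out[[cl]]))
  }
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' @rdname enrichment_table
#' @param path TSV with header `gene` plus source columns
#' @export
read_enrichment_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!("gene" %in% names(tab))) {
    stop_kg("enrichment table missing 'gene' column", class = "kg_format_error")
  }
  structure(tab, class = c("enrichment_table", "data.frame"))
}

# concatenated description texts of one table row / all rows
enrichment_texts <- function(tab, genes = NULL) {
  stopifnot(inherits(tab, "enrichment_table"))
  if (!is.null(genes)) tab <- tab[tab$gene %in% genes, , drop = FALSE]
  text_cols <- setdiff(names(tab), c("gene", grep("_url$", names(tab), value = TRUE)))
  apply(tab[, text_cols, drop = FALSE], 1, paste, collapse = " ")
}

#' Iterative semantic expansion of a gene set
#'
#' One iteration annotates the enrichment-table description texts of the
#' current gene set with the dictionary, extracts mentions of type
#' `"gene"`, and unions the mentioned concept ids into the set. The set is
#' monotone non-decreasing per iteration and reaches a fixed point (its
#' closure) in finitely many steps.
#'
#' @param seed_genes starting gene set
#' @param table an [enrichment_table()] providing description texts
#' @param dict an [entity_dictionary()] whose gene entries have
#'   `concept_id` equal to the gene name used in `table`
#' @param iterations number of expansion rounds (>= 1)
#' @return character vector, sorted: the expanded gene set
#' @export
semantic_expand <- function(seed_genes, table, dict, iterations = 1L) {
  stopifnot(iterations >= 1)
  current <- sort(unique(as.character(seed_genes)))
  for (i in seq_len(iterations)) {
    texts <- enrichment_texts(table, genes = current)
    found <- character(0)
    for (tx in texts) {
      m <- annotate_text(tx, dict)
      found <- c(found, m$concept_id[m$entity_type == "gene"])
    }
    nxt <- sort(unique(c(current, found)))
    if (identical(nxt, current)) break  # fixed point
    current <- nxt
  }
  current
}
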