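`%||%` <- function(a, b) if (is.null(a)) b else a

# Collapse a list-of-character column to ';'-separated strings (TSV dialect).
join_list_col <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_list_col <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

stop_kg <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "kgradiate_error")))
}

warn_kg <- function(..., class = "kgradiate_warning") {
  warning(warningCondition(paste0(...), class = class))
}
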