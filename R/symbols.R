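#' Normalize gene symbols
#'
#' Canonicalizes gene symbols for exact-string matching: trims whitespace,
#' upper-cases, and removes hyphens (so `IL-6` and `IL6`, or `IL-1B` and
#' `IL1B`, collapse to one spelling). No alias or ortholog mapping is
#' attempted; symbols from different sources must agree after this
#' normalization to be matched.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_symbols(c(" il-6", "Casp3", "IL1B"))
#' @export
normalize_gene_symbols <- function(x) {
  stopifnot(is.character(x))
  gsub("-", "", toupper(trimws(x)), fixed = TRUE)
}

# internal: validate a gene set (character vector of symbols)
as_gene_set <- function(genes, set_id = "gene set") {
  if (!is.character(genes)) {
    stop(set_id, ": genes must be a character vector", call. = FALSE)
  }
  genes <- normalize_gene_symbols(genes)
  genes <- genes[nzchar(genes)]
  unique(genes)
}
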