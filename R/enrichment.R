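#' Over-representation analysis against a pathway library
#'
#' For each pathway set, tests whether the query gene set shares more
#' members with it than expected under random sampling from a gene
#' universe: raw p = one-sided hypergeometric tail
#' P\[X >= overlap\], X ~ Hypergeometric(universe_size, set_size,
#' query_size). P-values are corrected across all tested pathways
#' (Benjamini-Hochberg by default) and rows are sorted by adjusted p,
#' then term id.
#'
#' Every pathway in the library is tested and counted in the correction;
#' `min_overlap` only filters the reported rows (default 0 = report
#' everything, so even disjoint pathways appear with raw p = 1), to avoid
#' silently dropping small terms.
#'
#' @param query character vector of gene symbols (e.g. the genes shared
#'   by two disease networks).
#' @param library named list of pathway gene sets, as from
#'   [read_gene_sets()] with the `"gmt"` dialect.
#' @param universe_size gene universe size; default 20000 (approximate
#'   protein-coding gene count). Must be at least |query u set| for every
#'   set.
#' @param min_overlap report only pathways with at least this many query
#'   genes (filter applied after correction; does not change p-values).
#' @param adjust `"BH"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return an `enrichment_result` data.frame: `term`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `raw_p`, `adjusted_p`,
#'   `associated_genes` (list of character vectors, sorted).
#' @seealso [rank_connectors()], [bh_adjust()]
#' @export
enrich <- function(query, library, universe_size = 20000, min_overlap = 0,
                   adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  query <- as_gene_set(query, "query")
  if (!length(library)) {
    warning("empty pathway library: empty enrichment result")
    return(empty_enrichment())
  }
  stopifnot(is.list(library), !is.null(names(library)),
            all(nzchar(names(library))))
  sets <- lapply(library, as_gene_set)
  n_union <- vapply(sets, function(s) length(union(s, query)), 1L)
  if (any(universe_size < n_union)) {
    stop("universe_size (", universe_size, ") smaller than |query u set| ",
         "for pathway '", names(sets)[which(universe_size < n_union)[1L]],
         "'", call. = FALSE)
  }
  hits <- lapply(sets, function(s) sort(intersect(s, query)))
  overlap <- lengths(hits)
  set_size <- lengths(sets)
  raw_p <- stats::phyper(overlap - 1, set_size, universe_size - set_size,
                         length(query), lower.tail = FALSE)
  adj_p <- if (adjust == "BH") bh_adjust(raw_p) else
    pmin(1, raw_p * length(raw_p))
  out <- data.frame(term = names(sets), overlap_count = as.integer(overlap),
                    set_size = as.integer(set_size),
                    query_size = length(query),
                    universe_size = as.integer(universe_size),
                    raw_p = as.numeric(raw_p),
                    adjusted_p = as.numeric(adj_p), row.names = NULL)
  out$associated_genes <- unname(hits)
  out <- out[out$overlap_count >= min_overlap, , drop = FALSE]
  out <- out[order(out$adjusted_p, out$term, method = "radix"), ,
             drop = FALSE]
  row.names(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

empty_enrichment <- function() {
  structure(data.frame(term = character(), overlap_count = integer(),
                       set_size = integer(), query_size = integer(),
                       universe_size = integer(), raw_p = numeric(),
                       adjusted_p = numeric()),
            class = c("enrichment_result", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: with p-values sorted
#' ascending, adj_(i) = min over j >= i of m * p_(j) / j, capped at 1,
#' returned in the input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values, each in (0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) && (anyNA(p) || any(p <= 0 | p > 1))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank connector pathways
#'
#' Orders an enrichment table so that its head is the "key connector"
#' pathway: ascending adjusted p-value, ties broken by descending overlap
#' (more associated genes first), then term id. Accepts either an
#' [enrich()] result or the packaged published pathway table
#' ([load_table2_fixture()]).
#'
#' @param x a data.frame with columns `term` (or `term` via the fixture's
#'   `term` column), `adjusted_p`, and `overlap_count` or
#'   `associated_genes`.
#' @return the same rows re-ordered, with a `rank` column prepended; the
#'   first row is the top-ranked connector.
#' @export
rank_connectors <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) > 0L,
            all(c("term", "adjusted_p") %in% names(x)))
  ov <- if ("overlap_count" %in% names(x)) x$overlap_count
        else lengths(x$associated_genes)
  out <- x[order(x$adjusted_p, -ov, x$term, method = "radix"), ,
           drop = FALSE]
  row.names(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("<enrichment_result> ", nrow(x), " pathways tested (query ",
      if (nrow(x)) x$query_size[[1]] else 0, " genes, universe ",
      if (nrow(x)) x$universe_size[[1]] else 0, ")\n", sep = "")
  if (nrow(x)) {
    head_df <- utils::head(as.data.frame(x)[
      c("term", "overlap_count", "set_size", "raw_p", "adjusted_p")], n)
    print(head_df)
  }
  invisible(x)
}

#' Write an enrichment result
#'
#' TSV with columns term, overlap_count, set_size, query_size,
#' universe_size, raw_p, adjusted_p, associated_genes (comma-joined).
#'
#' @param x an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  df <- as.data.frame(x)
  df$associated_genes <- vapply(
    if (is.null(x$associated_genes)) rep(list(character()), nrow(df))
    else x$associated_genes,
    paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
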