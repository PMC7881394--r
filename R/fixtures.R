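#' Published hub-bottleneck table for the AD / diabetes comparison
#'
#' The packaged transcription of the published per-disease hub-bottleneck
#' table of the Alzheimer's disease (AD) versus type 2 diabetes network
#' comparison: 26 rows (14 AD, 12 Diabetes), each with the gene's degree
#' and normalized betweenness centrality in its disease network. Gene
#' symbols are normalized with [normalize_gene_symbols()] (the source
#' prints `IL-6`; it is returned as `IL6`); degree and betweenness are
#' returned exactly as printed. These centralities were computed on
#' database snapshots that are not reconstructible, so they are packaged
#' as reference data rather than regenerated.
#'
#' @return a data.frame with columns `disease` (`"AD"` / `"Diabetes"`),
#'   `gene`, `degree` (integer), `betweenness` (numeric in \[0, 1\]).
#' @examples
#' tab1 <- load_table1_fixture()
#' table(tab1$disease)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "ad_diabetes_hub_bottlenecks.tsv",
                      package = "comorbidnet", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$gene <- normalize_gene_symbols(x$gene)
  x$degree <- as.integer(x$degree)
  stopifnot(!anyDuplicated(x[c("disease", "gene")]),
            all(x$degree >= 0L),
            all(x$betweenness >= 0 & x$betweenness <= 1))
  x
}

#' Published pathway-enrichment table for the AD / diabetes shared genes
#'
#' The packaged transcription of the published enrichment results for the
#' 40 genes shared by the AD and diabetes networks: 34 pathway rows from
#' three ontology sources (KEGG, Reactome, WikiPathways), each with its
#' adjusted p-value and associated gene list. Gene symbols in
#' `associated_genes` are normalized (the source mixes `IL-6`/`IL6` and
#' `IL-1B`/`IL1B` spellings); term names and p-values are as printed.
#'
#' @return a data.frame with columns `source`, `term`, `adjusted_p`
#'   (numeric), `associated_genes` (list of character vectors), and
#'   `overlap_count` (length of the gene list).
#' @examples
#' tab2 <- load_table2_fixture()
#' table(tab2$source)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "ad_diabetes_shared_pathways.tsv",
                      package = "comorbidnet", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$associated_genes <- lapply(strsplit(x$associated_genes, ","), as_gene_set)
  x$overlap_count <- lengths(x$associated_genes)
  stopifnot(all(x$adjusted_p > 0 & x$adjusted_p <= 1),
            all(x$overlap_count > 0L))
  x
}
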