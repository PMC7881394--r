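#' Genes shared by two sets
#'
#' Exact symbol intersection after normalization, sorted alphabetically.
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted character vector of shared symbols.
#' @export
shared_genes <- function(a, b) {
  sort(intersect(as_gene_set(a), as_gene_set(b)))
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors of gene symbols; at least one must be
#'   non-empty.
#' @return |A n B| / |A u B|.
#' @export
jaccard_index <- function(a, b) {
  a <- as_gene_set(a); b <- as_gene_set(b)
  u <- union(a, b)
  if (!length(u)) {
    stop("jaccard_index undefined: both gene sets are empty", call. = FALSE)
  }
  length(intersect(a, b)) / length(u)
}

#' Hypergeometric significance of a gene-set overlap
#'
#' One-sided tail probability P\[X >= |A n B|\] where X ~
#' Hypergeometric(universe_size, |A|, |B|): the probability that two sets
#' of these sizes, drawn at random from the universe, share at least the
#' observed number of genes.
#'
#' @param a,b character vectors of gene symbols.
#' @param universe_size size of the gene universe both sets were drawn
#'   from; must be at least |A u B|.
#' @return the tail probability, in (0, 1\].
#' @export
overlap_significance <- function(a, b, universe_size) {
  a <- as_gene_set(a); b <- as_gene_set(b)
  stopifnot(is.numeric(universe_size), length(universe_size) == 1L)
  n_union <- length(union(a, b))
  if (universe_size < n_union) {
    stop("universe_size (", universe_size, ") smaller than |A u B| (",
         n_union, ")", call. = FALSE)
  }
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                lower.tail = FALSE)
}

#' Compare two disease networks
#'
#' Assembles the full overlap picture of two disease networks and their
#' hub-bottleneck selections: shared nodes, shared hub-bottlenecks,
#' Jaccard index of the node sets, and the hypergeometric significance of
#' the node overlap. The default universe is the union of the two node
#' sets (self-contained and conservative); pass e.g.
#' `universe_size = 20000` for a genome-scale universe.
#'
#' @param net_a,net_b `disease_network` objects.
#' @param sel_a,sel_b matching `selection_result` objects from
#'   [call_hub_bottlenecks()] on each network's centrality table.
#' @param universe_size `"auto"` (union of node sets) or a positive
#'   integer.
#' @return an `overlap_result`: list with `disease_a`, `disease_b`,
#'   `n_nodes_a`, `n_nodes_b`, `shared_nodes`, `shared_hub_bottlenecks`,
#'   `jaccard`, `universe_size`, `hypergeom_p`.
#' @export
compare_networks <- function(net_a, sel_a, net_b, sel_b,
                             universe_size = "auto") {
  nodes_a <- network_nodes(net_a)
  nodes_b <- network_nodes(net_b)
  for (chk in list(list(sel_a, nodes_a, net_a), list(sel_b, nodes_b, net_b))) {
    if (!all(chk[[1]]$table$node %in% chk[[2]])) {
      stop("selection does not derive from network '",
           chk[[3]]$disease_id, "'", call. = FALSE)
    }
  }
  if (identical(universe_size, "auto")) {
    universe_size <- length(union(nodes_a, nodes_b))
  }
  structure(list(
    disease_a = net_a$disease_id, disease_b = net_b$disease_id,
    n_nodes_a = length(nodes_a), n_nodes_b = length(nodes_b),
    shared_nodes = shared_genes(nodes_a, nodes_b),
    shared_hub_bottlenecks = shared_genes(sel_a$hub_bottlenecks,
                                          sel_b$hub_bottlenecks),
    jaccard = jaccard_index(nodes_a, nodes_b),
    universe_size = as.integer(universe_size),
    hypergeom_p = overlap_significance(nodes_a, nodes_b, universe_size)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$disease_a, " (", x$n_nodes_a, " nodes) vs ",
      x$disease_b, " (", x$n_nodes_b, " nodes)\n",
      "  shared nodes:           ", length(x$shared_nodes), "\n",
      "  shared hub-bottlenecks: ", length(x$shared_hub_bottlenecks),
      if (length(x$shared_hub_bottlenecks))
        paste0(" (", paste(x$shared_hub_bottlenecks, collapse = ", "), ")")
      else "", "\n",
      "  Jaccard index:          ", signif(x$jaccard, 4), "\n",
      "  hypergeometric p:       ", signif(x$hypergeom_p, 4),
      " (universe ", x$universe_size, ")\n", sep = "")
  invisible(x)
}

#' Write an overlap result
#'
#' One TSV row of the scalar fields plus the shared gene lists as
#' comma-joined columns.
#'
#' @param x an `overlap_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(x, path) {
  df <- data.frame(
    disease_a = x$disease_a, disease_b = x$disease_b,
    n_nodes_a = x$n_nodes_a, n_nodes_b = x$n_nodes_b,
    n_shared_nodes = length(x$shared_nodes),
    n_shared_hub_bottlenecks = length(x$shared_hub_bottlenecks),
    jaccard = x$jaccard, universe_size = x$universe_size,
    hypergeom_p = x$hypergeom_p,
    shared_hub_bottlenecks = paste(x$shared_hub_bottlenecks,
                                   collapse = ","),
    shared_nodes = paste(x$shared_nodes, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
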