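#' Build a disease PPI network
#'
#' Constructs the simple undirected network of a disease as the induced
#' subgraph of a scored interaction table on the disease gene set: an edge
#' is retained iff both endpoints belong to the gene set and its
#' confidence score is at least `min_score`. By default genes left without
#' any retained edge are excluded, mirroring how exported disease networks
#' typically contain fewer nodes than the disease gene list.
#'
#' @param genes character vector of gene symbols (one disease gene set);
#'   normalized with [normalize_gene_symbols()].
#' @param interactions an `interaction_table` from [read_interactions()]
#'   (or any data.frame with columns `a`, `b`, `score` in \[0, 1\]).
#' @param min_score minimum confidence score in \[0, 1\] for an edge to be
#'   kept. Default 0.4, the conventional "medium confidence" STRING
#'   cutoff.
#' @param keep_isolated keep genes with no retained edge as isolated
#'   nodes? Default `FALSE`.
#' @param disease_id label for the network.
#' @return a `disease_network`: a list with elements `disease_id`,
#'   `graph` (an [igraph][igraph::igraph-package] undirected simple
#'   graph whose edges carry a `score` attribute), `min_score`, and
#'   `n_genes_input`.
#' @examples
#' edges <- data.frame(a = c("A", "B"), b = c("B", "D"),
#'                     score = c(0.9, 0.9))
#' net <- build_network(c("A", "B", "C"), edges, min_score = 0.4)
#' network_summary(net)
#' @export
build_network <- function(genes, interactions, min_score = 0.4,
                          keep_isolated = FALSE, disease_id = "disease") {
  stopifnot(is.numeric(min_score), length(min_score) == 1L,
            min_score >= 0, min_score <= 1)
  genes <- as_gene_set(genes, disease_id)
  if (!length(genes)) {
    stop("network_build [", disease_id, "]: empty gene set", call. = FALSE)
  }
  if (!inherits(interactions, "interaction_table")) {
    interactions <- as_interaction_table(interactions)
  }
  keep <- interactions$a %in% genes & interactions$b %in% genes &
    interactions$score >= min_score
  edges <- interactions[keep, , drop = FALSE]
  nodes <- if (keep_isolated) genes else sort(unique(c(edges$a, edges$b)))
  if (!length(nodes)) {
    stop("network_build [", disease_id, "]: empty network (no gene-set ",
         "edge reaches min_score = ", min_score, ")", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  message("network_build [", disease_id, "]: ", igraph::vcount(g),
          " nodes, ", igraph::ecount(g), " edges (from ", length(genes),
          " genes, min_score ", min_score, ")")
  structure(list(disease_id = disease_id, graph = g, min_score = min_score,
                 n_genes_input = length(genes)),
            class = "disease_network")
}

#' Summarize a disease network
#'
#' @param net a `disease_network`.
#' @return a data.frame with one row: `node_count`, `edge_count`,
#'   `component_count`, `mean_degree` (= 2 x edges / nodes).
#' @export
network_summary <- function(net) {
  g <- network_graph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network", call. = FALSE)
  m <- igraph::ecount(g)
  data.frame(node_count = n, edge_count = m,
             component_count = igraph::components(g)$no,
             mean_degree = 2 * m / n)
}

#' Network node symbols
#'
#' @param net a `disease_network`.
#' @return character vector of node gene symbols.
#' @export
network_nodes <- function(net) {
  igraph::V(network_graph(net))$name
}

#' Serialize a network as an edge-list table
#'
#' @param net a `disease_network`.
#' @param path output path for a 3-column TSV (a, b, score).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  g <- network_graph(net)
  df <- igraph::as_data_frame(g, what = "edges")
  names(df)[1:2] <- c("a", "b")
  if (is.null(df$score)) df$score <- rep(1, nrow(df))
  write_interactions(as_interaction_table(df), path)
}

#' @export
print.disease_network <- function(x, ...) {
  cat("<disease_network> ", x$disease_id, ": ", igraph::vcount(x$graph),
      " nodes, ", igraph::ecount(x$graph), " edges (min_score ",
      x$min_score, ", from ", x$n_genes_input, " genes)\n", sep = "")
  invisible(x)
}

# internal: accept a disease_network or a bare igraph
network_graph <- function(net) {
  if (inherits(net, "disease_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  stop("expected a disease_network or igraph object", call. = FALSE)
}
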