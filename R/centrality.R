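#' Degree and normalized betweenness of every network node
#'
#' Degree is the unweighted count of incident edges. Betweenness of node
#' v is the sum over unordered node pairs (s, t), both distinct from v,
#' of the fraction of shortest s-t paths that pass through v; pairs with
#' no connecting path contribute zero. Values are normalized by the pair
#' count (N-1)(N-2)/2, so they lie in \[0, 1\] and the center of a star
#' scores exactly 1; for networks with fewer than 3 nodes the normalized
#' betweenness is defined as 0. Shortest paths are unweighted: confidence
#' scores act only as an edge filter upstream, never as distances.
#'
#' @param net a `disease_network` or an igraph undirected graph.
#' @return a `centrality_table`: a data.frame with columns `node`,
#'   `degree` (integer), `betweenness` (numeric in \[0, 1\]), one row per
#'   network node.
#' @examples
#' path3 <- igraph::make_graph(~ A - B - C)
#' node_centrality(path3)  # middle node: betweenness 1
#' @export
node_centrality <- function(net) {
  g <- network_graph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- if (n < 3L) {
    stats::setNames(numeric(n), names(deg))
  } else {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  }
  structure(data.frame(node = names(deg), degree = as.integer(deg),
                       betweenness = as.numeric(btw), row.names = NULL),
            class = c("centrality_table", "data.frame"))
}

#' @rdname node_centrality
#' @return `degree_centrality()` / `betweenness_centrality()`: the named
#'   numeric vector of the corresponding column.
#' @export
degree_centrality <- function(net) {
  ct <- node_centrality(net)
  stats::setNames(ct$degree, ct$node)
}

#' @rdname node_centrality
#' @export
betweenness_centrality <- function(net) {
  ct <- node_centrality(net)
  stats::setNames(ct$betweenness, ct$node)
}

#' Brute-force betweenness oracle
#'
#' Computes normalized betweenness by explicit breadth-first-search
#' shortest-path counting from every node, entirely independent of the
#' production implementation, for use as a test oracle on small networks.
#' For every ordered pair (s, t) it accumulates sigma_sv * sigma_vt /
#' sigma_st for each intermediate v on a shortest path, using only base R.
#'
#' @param net a `disease_network` or igraph graph with at most `max_nodes`
#'   nodes.
#' @param max_nodes refuse larger networks (exhaustive enumeration only).
#' @return named numeric vector of normalized betweenness values.
#' @export
betweenness_oracle <- function(net, max_nodes = 60L) {
  g <- network_graph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network", call. = FALSE)
  if (n > max_nodes) {
    stop("betweenness_oracle: ", n, " nodes exceeds the exhaustive cap of ",
         max_nodes, call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n < 3L) return(stats::setNames(numeric(n), nodes))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  D <- matrix(Inf, n, n)      # geodesic distances
  S <- matrix(0, n, n)        # shortest-path counts
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[u] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[u] + 1) sigma[w] <- sigma[w] + sigma[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], `+`) == D & is.finite(D) & S > 0
    on_path[v, ] <- FALSE
    on_path[, v] <- FALSE
    contrib <- outer(S[, v], S[v, ]) / pmax(S, 1)
    b[v] <- sum(contrib[on_path & upper.tri(on_path)])
  }
  stats::setNames(b / ((n - 1) * (n - 2) / 2), nodes)
}

#' Write a centrality table
#'
#' Tab-separated columns `node`, `degree`, `betweenness`, with
#' betweenness printed to 6 decimal places.
#'
#' @param cent a `centrality_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(cent, path) {
  out <- data.frame(node = cent$node, degree = cent$degree,
                    betweenness = sprintf("%.6f", cent$betweenness))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
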