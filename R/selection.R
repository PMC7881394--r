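#' Hub selection: degree above mean + 2 SD
#'
#' A node is a hub iff its degree is strictly above the network's average
#' degree plus twice the standard deviation of degrees. The SD is the
#' population SD (divisor N) by default, since the node set is the entire
#' network under study, not a sample; `sd_mode = "sample"` (divisor N-1)
#' is available because conventions differ.
#'
#' @param cent a `centrality_table` from [node_centrality()] (any
#'   data.frame with columns `node` and `degree` works).
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return a list with `genes` (character vector of hubs) and
#'   `thresholds` (`mean_degree`, `sd_degree`, `hub_cutoff`, `sd_mode`).
#' @examples
#' ct <- data.frame(node = letters[1:10], degree = c(rep(2, 9), 20))
#' call_hubs(ct)  # cutoff 3.8 + 2 * 5.4 = 14.6 -> only the degree-20 node
#' @export
call_hubs <- function(cent, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  d <- cent$degree
  if (length(d) < 2L) {
    stop("hub selection needs at least 2 nodes (degree SD undefined)",
         call. = FALSE)
  }
  mu <- mean(d)
  sdv <- if (sd_mode == "population") {
    sqrt(mean((d - mu)^2))
  } else {
    stats::sd(d)
  }
  cutoff <- mu + 2 * sdv
  list(genes = cent$node[d > cutoff],   # strictly "above"
       thresholds = list(mean_degree = mu, sd_degree = sdv,
                         hub_cutoff = cutoff, sd_mode = sd_mode))
}

#' Bottleneck selection: top fraction of betweenness
#'
#' Selects the top `fraction` of nodes by betweenness centrality:
#' k = ceiling(fraction x N) nodes, extended to include every node tied
#' with the k-th largest value, so the selection never depends on input
#' order.
#'
#' @param cent a `centrality_table` (needs columns `node`,
#'   `betweenness`).
#' @param fraction fraction of nodes to take, in (0, 1\]; default 0.05.
#' @return a list with `genes` and `thresholds` (`bottleneck_fraction`,
#'   `bottleneck_rank_count` = k, `bottleneck_cutoff` = realized value
#'   cutoff).
#' @export
call_bottlenecks <- function(cent, fraction = 0.05) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  b <- cent$betweenness
  n <- length(b)
  if (n < 1L) stop("empty centrality table", call. = FALSE)
  k <- ceiling(fraction * n)
  cutoff <- sort(b, decreasing = TRUE)[k]
  list(genes = cent$node[b >= cutoff],
       thresholds = list(bottleneck_fraction = fraction,
                         bottleneck_rank_count = as.integer(k),
                         bottleneck_cutoff = cutoff))
}

#' Hub-bottleneck selection
#'
#' A hub-bottleneck is a node that is simultaneously a hub
#' ([call_hubs()]) and a bottleneck ([call_bottlenecks()]); these are the
#' pipeline's candidate key genes.
#'
#' @inheritParams call_hubs
#' @inheritParams call_bottlenecks
#' @return a `selection_result`: list with `hubs`, `bottlenecks`,
#'   `hub_bottlenecks` (their intersection), `thresholds` (both rules'
#'   thresholds merged), and `table` (per-node logical flags `is_hub`,
#'   `is_bottleneck`, `is_hub_bottleneck` joined to the centrality
#'   columns).
#' @examples
#' star <- igraph::make_star(10, mode = "undirected")
#' igraph::V(star)$name <- paste0("g", 1:10)
#' call_hub_bottlenecks(node_centrality(star))$hub_bottlenecks  # the center
#' @export
call_hub_bottlenecks <- function(cent, fraction = 0.05,
                                 sd_mode = c("population", "sample")) {
  hubs <- call_hubs(cent, sd_mode)
  bots <- call_bottlenecks(cent, fraction)
  hb <- intersect(hubs$genes, bots$genes)
  tab <- as.data.frame(cent)
  tab$is_hub <- tab$node %in% hubs$genes
  tab$is_bottleneck <- tab$node %in% bots$genes
  tab$is_hub_bottleneck <- tab$node %in% hb
  structure(list(hubs = hubs$genes, bottlenecks = bots$genes,
                 hub_bottlenecks = hb,
                 thresholds = c(hubs$thresholds, bots$thresholds),
                 table = tab),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  th <- x$thresholds
  cat("<selection_result> ", nrow(x$table), " nodes: ",
      length(x$hubs), " hubs (degree > ", format(th$hub_cutoff), "), ",
      length(x$bottlenecks), " bottlenecks (top ",
      format(100 * th$bottleneck_fraction), "% betweenness, k = ",
      th$bottleneck_rank_count, "), ",
      length(x$hub_bottlenecks), " hub-bottlenecks\n", sep = "")
  if (length(x$hub_bottlenecks)) {
    cat("  hub-bottlenecks: ", paste(sort(x$hub_bottlenecks),
                                     collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a selection result
#'
#' Writes the per-node table (node, degree, betweenness, is_hub,
#' is_bottleneck, is_hub_bottleneck) as TSV, plus the thresholds as a
#' JSON sidecar at `<path>.thresholds.json`.
#'
#' @param sel a `selection_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  utils::write.table(sel$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sel$thresholds,
                       paste0(path, ".thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
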