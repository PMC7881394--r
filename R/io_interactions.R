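#' Read a scored protein-protein interaction table
#'
#' Reads a three-column tab-separated edge table (symbol A, symbol B,
#' confidence score), the dialect of a STRING interaction export. Lines
#' starting with `#` are ignored. The score scale must be declared
#' explicitly: `"unit"` for scores already in \[0, 1\], `"string999"` for
#' STRING combined scores in \[0, 1000\] which are divided by 1000. No
#' auto-detection is attempted — a silently misread scale corrupts every
#' downstream threshold.
#'
#' Cleaning applied after parsing: symbols normalized with
#' [normalize_gene_symbols()]; self-pairs dropped; duplicate unordered
#' pairs collapsed to their maximum score. The counts of dropped
#' self-pairs and collapsed duplicates are reported via [message()] and
#' stored in the attributes `n_self_dropped` and `n_duplicates_collapsed`.
#'
#' @param path path to the edge table.
#' @param score_scale `"unit"` or `"string999"`.
#' @return an `interaction_table`: a data.frame with columns `a`, `b`,
#'   `score` (scores in \[0, 1\]), each unordered pair once with `a < b`,
#'   rows sorted by (`a`, `b`).
#' @seealso [write_interactions()], [build_network()]
#' @export
read_interactions <- function(path, score_scale = c("unit", "string999")) {
  score_scale <- match.arg(score_scale)
  lines <- read_input_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("interaction line ", names(lines)[which(nf < 3L)[1L]], " in '",
         path, "' has fewer than 3 columns", call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(score)) {
    stop("non-numeric score on line ", names(lines)[which(is.na(score))[1L]],
         " in '", path, "'", call. = FALSE)
  }
  hi <- if (score_scale == "string999") 1000 else 1
  if (any(score < 0 | score > hi)) {
    stop("score outside declared scale '", score_scale, "' (expected [0, ",
         hi, "]) on line ",
         names(lines)[which(score < 0 | score > hi)[1L]], call. = FALSE)
  }
  if (score_scale == "string999") score <- score / 1000
  as_interaction_table(data.frame(a = a, b = b, score = score),
                       verbose = TRUE)
}

# internal: canonicalize an edge data.frame into an interaction_table:
# normalized symbols, no self-pairs, one record per unordered pair (max
# score), a < b, rows ordered by (a, b)
as_interaction_table <- function(edges, verbose = FALSE) {
  a <- normalize_gene_symbols(edges$a)
  b <- normalize_gene_symbols(edges$b)
  score <- edges$score
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  self <- lo == hi
  n_self <- sum(self)
  lo <- lo[!self]; hi <- hi[!self]; score <- score[!self]
  key <- paste(lo, hi, sep = "\r")
  n_dup <- length(key) - length(unique(key))
  if (n_dup > 0L) {
    score <- tapply(score, key, max)
    pair <- strsplit(names(score), "\r", fixed = TRUE)
    lo <- vapply(pair, `[[`, "", 1L)
    hi <- vapply(pair, `[[`, "", 2L)
    score <- as.numeric(score)
  }
  ord <- order(lo, hi, method = "radix")
  out <- data.frame(a = lo[ord], b = hi[ord], score = score[ord])
  if (verbose) {
    message("interactions: ", nrow(out), " edges kept; dropped ", n_self,
            " self-pair(s), collapsed ", n_dup, " duplicate pair(s)")
  }
  structure(out,
            n_self_dropped = n_self,
            n_duplicates_collapsed = n_dup,
            class = c("interaction_table", "data.frame"))
}

#' Write an interaction table
#'
#' Serializes an edge table as three tab-separated columns (a, b, score)
#' preceded by a `#`-comment header line; [read_interactions()] with
#' `score_scale = "unit"` reads it back unchanged.
#'
#' @param edges an `interaction_table` or any data.frame with columns
#'   `a`, `b`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(edges, path) {
  stopifnot(all(c("a", "b", "score") %in% names(edges)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#a\tb\tscore", con)
  utils::write.table(edges[, c("a", "b", "score")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
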