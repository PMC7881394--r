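#' Read disease or pathway gene sets
#'
#' Reads gene sets from either a two-column table (set id, gene symbol;
#' tab-separated, one gene per line, repeated ids accumulate into one set)
#' or GMT lines (set id, description, then member genes). Symbols are
#' normalized with [normalize_gene_symbols()] and duplicates within a set
#' are collapsed.
#'
#' @param path path to the input file.
#' @param dialect `"two_column_tsv"` or `"gmt"`.
#' @return a named list of character vectors, one element per set, in
#'   order of first appearance.
#' @seealso [write_gene_sets()]
#' @export
read_gene_sets <- function(path, dialect = c("two_column_tsv", "gmt")) {
  dialect <- match.arg(dialect)
  lines <- read_input_lines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    lineno <- names(lines)[[i]]  # position in the original file
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (dialect == "two_column_tsv") {
      if (length(fields) < 2L || !nzchar(trimws(fields[[1]])) ||
          !nzchar(trimws(fields[[2]]))) {
        stop("malformed two-column gene-set line ", lineno, " in '", path,
             "'", call. = FALSE)
      }
      id <- trimws(fields[[1]])
      sets[[id]] <- c(sets[[id]], fields[[2]])
    } else {
      if (length(fields) < 3L || !nzchar(trimws(fields[[1]]))) {
        stop("malformed GMT line ", lineno, " in '", path,
             "' (need id, description, >=1 gene)", call. = FALSE)
      }
      id <- trimws(fields[[1]])
      sets[[id]] <- c(sets[[id]], fields[-(1:2)])
    }
  }
  sets <- lapply(sets, as_gene_set)
  empty <- !vapply(sets, length, 1L)
  if (any(empty)) {
    stop("empty gene set(s) after normalization: ",
         paste(names(sets)[empty], collapse = ", "), call. = FALSE)
  }
  sets
}

#' Write gene sets
#'
#' Serializes a named list of gene symbol vectors in either of the two
#' dialects [read_gene_sets()] accepts; a written file re-reads to an
#' identical value.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param dialect `"two_column_tsv"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, dialect = c("two_column_tsv", "gmt")) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  lines <- if (dialect == "gmt") {
    vapply(names(sets), function(id) {
      paste(c(id, "na", sets[[id]]), collapse = "\t")
    }, "")
  } else {
    unlist(lapply(names(sets), function(id) paste(id, sets[[id]], sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

# internal: non-empty, non-comment lines of a text file
read_input_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- stats::setNames(lines[keep], which(keep))
  if (!length(lines)) stop("empty input file: '", path, "'", call. = FALSE)
  lines
}
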