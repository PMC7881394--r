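#' Configuration for the synthetic benchmark generator
#'
#' Bundles and validates every parameter of the synthetic scenario: a
#' scale-free background interactome with planted high-degree hubs, a
#' pair of disease gene sets with a controlled overlap that contains a
#' known subset of the planted hubs, and a pathway library with one
#' planted over-represented set. All generator outputs are pure functions
#' of this configuration (randomness is seeded from `seed`).
#'
#' Defaults mirror the scale of the worked AD/diabetes comparison: 2000
#' background genes, disease gene sets of 386 and 523 symbols sharing 40
#' genes, 4 planted hubs of which 2 are shared by both gene sets (so each
#' disease carries 3), and a 10-set pathway library whose planted set
#' draws 80% of its 15 members from the shared genes. Planted hubs are
#' wired to 30x the background mean degree, which places them above the
#' expected extreme of the scale-free degree tail (roughly m * sqrt(n)
#' edges, about 22x the mean at the default scale) — a weaker "planted"
#' hub would be indistinguishable from natural background hubs by any
#' degree rule.
#'
#' @param n_genes background interactome size.
#' @param attachment_edges edges added per node during preferential
#'   attachment (graph mean degree is about twice this).
#' @param n_planted_hubs number of planted hubs in the interactome.
#' @param n_shared_hubs how many planted hubs both disease sets contain;
#'   the rest are split alternately between the two sets.
#' @param hub_degree_multiplier planted hubs are wired to uniformly
#'   sampled partners until their degree reaches this multiple of the
#'   background mean degree; must be > 1.
#' @param set_size_a,set_size_b disease gene-set sizes.
#' @param overlap_count number of genes shared by the two sets.
#' @param n_pathways pathway library size (1 planted + rest background).
#' @param pathway_size genes per pathway.
#' @param enrichment_rate fraction of the planted pathway drawn from the
#'   target gene set, in \[0, 1\].
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L, attachment_edges = 2L,
                             n_planted_hubs = 4L, n_shared_hubs = 2L,
                             hub_degree_multiplier = 30,
                             set_size_a = 386L, set_size_b = 523L,
                             overlap_count = 40L, n_pathways = 10L,
                             pathway_size = 15L, enrichment_rate = 0.8,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              attachment_edges = as.integer(attachment_edges),
              n_planted_hubs = as.integer(n_planted_hubs),
              n_shared_hubs = as.integer(n_shared_hubs),
              hub_degree_multiplier = hub_degree_multiplier,
              set_size_a = as.integer(set_size_a),
              set_size_b = as.integer(set_size_b),
              overlap_count = as.integer(overlap_count),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              enrichment_rate = enrichment_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= attachment_edges + 1L, attachment_edges >= 1L,
              n_planted_hubs >= 0L, n_shared_hubs >= 0L,
              n_shared_hubs <= n_planted_hubs,
              hub_degree_multiplier > 1,
              set_size_a >= 1L, set_size_b >= 1L,
              set_size_a <= n_genes, set_size_b <= n_genes,
              overlap_count >= 0L,
              overlap_count <= min(set_size_a, set_size_b),
              n_shared_hubs <= overlap_count,
              n_pathways >= 1L, pathway_size >= 1L,
              pathway_size <= n_genes,
              enrichment_rate >= 0, enrichment_rate <= 1)
  })
  structure(cfg, class = "synthetic_config")
}

# internal: synthetic symbol names G0001...
synthetic_symbols <- function(n) {
  sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic interactome with planted hubs
#'
#' Draws a linear preferential-attachment (scale-free) background graph
#' over synthetic symbols `G0001...`, then wires each planted hub to
#' additional uniformly sampled partners until its degree reaches
#' `hub_degree_multiplier` times the background mean degree. Confidence
#' scores are uniform on \[0.4, 1\] (above the default network-building
#' threshold; thresholding behaviour is exercised with explicit low-score
#' edges in tests, not here).
#'
#' @param cfg a [synthetic_config()].
#' @return an `interaction_table` with attribute `planted_hubs` (the
#'   planted symbols, first `n_shared_hubs` destined for both disease
#'   sets).
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$attachment_edges,
                         directed = FALSE)
  igraph::V(g)$name <- synthetic_symbols(cfg$n_genes)
  target <- ceiling(cfg$hub_degree_multiplier *
                      mean(igraph::degree(g)))
  if (target >= cfg$n_genes) {
    stop("infeasible config: planted hub target degree ", target,
         " >= n_genes", call. = FALSE)
  }
  hubs <- character(0)
  if (cfg$n_planted_hubs > 0L) {
    hubs <- sample(igraph::V(g)$name, cfg$n_planted_hubs)
    for (h in hubs) {
      need <- target - igraph::degree(g, h)
      if (need > 0) {
        partners <- setdiff(igraph::V(g)$name,
                            c(h, names(igraph::neighbors(g, h))))
        new_p <- sample(partners, need)
        g <- igraph::add_edges(g, as.vector(rbind(h, new_p)))
      }
    }
  }
  df <- igraph::as_data_frame(g, what = "edges")
  names(df) <- c("a", "b")
  df$score <- round(stats::runif(nrow(df), 0.4, 1.0), 3)
  out <- as_interaction_table(df)
  attr(out, "planted_hubs") <- hubs
  out
}

#' Generate a pair of disease gene sets with controlled overlap
#'
#' Samples `overlap_count` shared genes — seeded with the first
#' `n_shared_hubs` planted hubs, so shared hub-bottlenecks exist by
#' construction — then disjoint remainders (each receiving its share of
#' the non-shared planted hubs, alternating) up to the configured set
#' sizes.
#'
#' @param cfg a [synthetic_config()].
#' @param interactome the matching [generate_interactome()] output
#'   (carries the planted-hub attribute).
#' @return a list with `set_a`, `set_b` (character vectors),
#'   `shared_genes` (the ground-truth overlap), `shared_hubs`, `hubs_a`,
#'   `hubs_b` (planted hubs present in each set).
#' @export
generate_disease_pair <- function(cfg, interactome) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_symbols(cfg$n_genes)
  hubs <- attr(interactome, "planted_hubs")
  if (is.null(hubs)) hubs <- character(0)
  shared_hubs <- utils::head(hubs, cfg$n_shared_hubs)
  other_hubs <- setdiff(hubs, shared_hubs)
  hubs_a_only <- other_hubs[seq_along(other_hubs) %% 2L == 1L]
  hubs_b_only <- setdiff(other_hubs, hubs_a_only)
  n_a_rest <- cfg$set_size_a - cfg$overlap_count - length(hubs_a_only)
  n_b_rest <- cfg$set_size_b - cfg$overlap_count - length(hubs_b_only)
  if (n_a_rest < 0L || n_b_rest < 0L ||
      cfg$overlap_count + n_a_rest + n_b_rest +
        length(other_hubs) > cfg$n_genes) {
    stop("infeasible config: set sizes incompatible with overlap and ",
         "planted hubs", call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  pool <- setdiff(genes, hubs)
  shared <- c(shared_hubs, sample(pool, cfg$overlap_count -
                                    length(shared_hubs)))
  pool <- setdiff(pool, shared)
  a_rest <- sample(pool, n_a_rest)
  pool <- setdiff(pool, a_rest)
  b_rest <- sample(pool, n_b_rest)
  list(set_a = c(shared, hubs_a_only, a_rest),
       set_b = c(shared, hubs_b_only, b_rest),
       shared_genes = shared,
       shared_hubs = shared_hubs,
       hubs_a = c(shared_hubs, hubs_a_only),
       hubs_b = c(shared_hubs, hubs_b_only))
}

#' Generate a pathway library with one planted enriched set
#'
#' Builds `n_pathways` pathway gene sets over the synthetic gene
#' universe: one planted set draws `round(enrichment_rate * pathway_size)`
#' members from `target_genes` (the rest from the remaining genes), the
#' others are uniform background samples. The planted set's position in
#' the library is itself randomized.
#'
#' @param cfg a [synthetic_config()].
#' @param target_genes character vector the planted pathway should be
#'   enriched for (e.g. the ground-truth shared genes).
#' @return a list with `library` (named list of gene sets,
#'   GMT-serializable via [write_gene_sets()]) and `planted_term` (the
#'   planted set's name).
#' @export
generate_pathway_library <- function(cfg, target_genes) {
  stopifnot(inherits(cfg, "synthetic_config"))
  target_genes <- as_gene_set(target_genes, "target_genes")
  genes <- synthetic_symbols(cfg$n_genes)
  n_target <- round(cfg$enrichment_rate * cfg$pathway_size)
  if (n_target > length(target_genes)) {
    stop("infeasible config: planted pathway needs ", n_target,
         " target genes but only ", length(target_genes), " available",
         call. = FALSE)
  }
  set.seed(cfg$seed + 2L)
  planted <- c(sample(target_genes, n_target),
               sample(setdiff(genes, target_genes),
                      cfg$pathway_size - n_target))
  lib <- c(list(planted),
           lapply(seq_len(cfg$n_pathways - 1L),
                  function(i) sample(genes, cfg$pathway_size)))
  lib <- lib[sample(length(lib))]
  names(lib) <- sprintf("PW%03d", seq_along(lib))
  planted_term <- names(lib)[vapply(lib, identical, TRUE, planted)]
  list(library = lapply(lib, sort), planted_term = planted_term)
}

#' Generate and optionally write a full synthetic scenario
#'
#' Convenience wrapper producing all three synthetic inputs from one
#' configuration; with `dir` set, writes them in the package's file
#' dialects (interactions TSV, two-column gene-set TSV, GMT) plus a JSON
#' manifest of the configuration.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory (created if missing).
#' @return a list with `config`, `interactome`, `pair`, `pathways`, and
#'   (if written) `files`.
#' @export
generate_scenario <- function(cfg, dir = NULL) {
  interactome <- generate_interactome(cfg)
  pair <- generate_disease_pair(cfg, interactome)
  pathways <- generate_pathway_library(cfg, pair$shared_genes)
  out <- list(config = cfg, interactome = interactome, pair = pair,
              pathways = pathways)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      interactions = file.path(dir, "interactome.tsv"),
      gene_sets = file.path(dir, "gene_sets.tsv"),
      pathways = file.path(dir, "pathways.gmt"),
      manifest = file.path(dir, "scenario_manifest.json"))
    write_interactions(interactome, files$interactions)
    write_gene_sets(list(disease_a = pair$set_a, disease_b = pair$set_b),
                    files$gene_sets, dialect = "two_column_tsv")
    write_gene_sets(pathways$library, files$pathways, dialect = "gmt")
    jsonlite::write_json(
      c(unclass(cfg),
        list(planted_hubs = attr(interactome, "planted_hubs"),
             planted_term = pathways$planted_term,
             shared_hubs = pair$shared_hubs)),
      files$manifest, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
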