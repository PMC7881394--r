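#' Pipeline run configuration
#'
#' Collects and validates everything [run_pipeline()] needs. Input files
#' may be omitted when a `synthetic` configuration is supplied, in which
#' case the scenario is generated (and written under
#' `<out_dir>/inputs/`) before the analysis runs on it exactly as it
#' would on real exports.
#'
#' @param gene_sets_path path to a disease gene-set file.
#' @param gene_sets_dialect `"two_column_tsv"` or `"gmt"`.
#' @param interactions_path path to a scored edge table.
#' @param score_scale `"unit"` or `"string999"`.
#' @param pathways_path optional GMT pathway library; enrichment is
#'   skipped when absent.
#' @param disease_a,disease_b set ids of the two diseases to compare;
#'   default: the first two sets in the file.
#' @param min_score,keep_isolated see [build_network()].
#' @param bottleneck_fraction,sd_mode see [call_hub_bottlenecks()].
#' @param overlap_universe `"auto"` or integer, see [compare_networks()].
#' @param enrichment_universe see [enrich()].
#' @param adjust_method `"BH"` or `"bonferroni"`.
#' @param min_overlap see [enrich()].
#' @param out_dir output directory.
#' @param synthetic optional [synthetic_config()] replacing the input
#'   paths.
#' @return a validated `run_config` list.
#' @export
run_config <- function(gene_sets_path = NULL,
                       gene_sets_dialect = "two_column_tsv",
                       interactions_path = NULL, score_scale = "unit",
                       pathways_path = NULL,
                       disease_a = NULL, disease_b = NULL,
                       min_score = 0.4, keep_isolated = FALSE,
                       bottleneck_fraction = 0.05,
                       sd_mode = "population",
                       overlap_universe = "auto",
                       enrichment_universe = 20000,
                       adjust_method = "BH", min_overlap = 0,
                       out_dir = tempfile("comorbidnet_run_"),
                       synthetic = NULL) {
  stopifnot(min_score >= 0, min_score <= 1,
            bottleneck_fraction > 0, bottleneck_fraction <= 1)
  if (is.null(synthetic)) {
    for (p in c(gene_sets_path, interactions_path, pathways_path)) {
      if (!file.exists(p)) stop("input not found: '", p, "'", call. = FALSE)
    }
    if (is.null(gene_sets_path) || is.null(interactions_path)) {
      stop("gene_sets_path and interactions_path are required unless a ",
           "synthetic config is given", call. = FALSE)
    }
  } else {
    stopifnot(inherits(synthetic, "synthetic_config"))
  }
  structure(list(gene_sets_path = gene_sets_path,
                 gene_sets_dialect = gene_sets_dialect,
                 interactions_path = interactions_path,
                 score_scale = score_scale,
                 pathways_path = pathways_path,
                 disease_a = disease_a, disease_b = disease_b,
                 min_score = min_score, keep_isolated = keep_isolated,
                 bottleneck_fraction = bottleneck_fraction,
                 sd_mode = sd_mode,
                 overlap_universe = overlap_universe,
                 enrichment_universe = enrichment_universe,
                 adjust_method = adjust_method,
                 min_overlap = min_overlap,
                 out_dir = out_dir, synthetic = synthetic),
            class = "run_config")
}

#' Run the end-to-end disease-comparison pipeline
#'
#' Executes the full analysis: read (or generate) inputs, build the two
#' disease networks, compute centralities, select hub-bottlenecks,
#' compare the networks, and (when a pathway library is available) run
#' over-representation analysis of the shared genes and rank connector
#' pathways. Per-stage outputs are written under `cfg$out_dir`
#' (centrality and selection TSVs per disease, overlap summary,
#' enrichment table) together with a JSON run manifest recording every
#' threshold and seed; a failure in any stage aborts with a message
#' naming the stage.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_report` list: `config`, `networks`, `centralities`,
#'   `selections`, `overlap`, `enrichment` (or `NULL`), `connectors` (or
#'   `NULL`), `scenario` (the generated synthetic inputs with their
#'   planted ground truth, or `NULL`), `files`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("io", {
    if (!is.null(cfg$synthetic)) {
      scn <- generate_scenario(cfg$synthetic,
                               dir = file.path(cfg$out_dir, "inputs"))
      list(sets = list(disease_a = scn$pair$set_a,
                       disease_b = scn$pair$set_b),
           interactions = scn$interactome,
           pathways = scn$pathways$library,
           scenario = scn)
    } else {
      list(sets = read_gene_sets(cfg$gene_sets_path,
                                 cfg$gene_sets_dialect),
           interactions = read_interactions(cfg$interactions_path,
                                            cfg$score_scale),
           pathways = if (!is.null(cfg$pathways_path)) {
             read_gene_sets(cfg$pathways_path, "gmt")
           },
           scenario = NULL)
    }
  })
  ids <- c(cfg$disease_a %||% names(inputs$sets)[[1]],
           cfg$disease_b %||% names(inputs$sets)[[2]])
  if (anyNA(ids) || !all(ids %in% names(inputs$sets))) {
    stop("pipeline stage [io] failed: need two disease ids among: ",
         paste(names(inputs$sets), collapse = ", "), call. = FALSE)
  }

  networks <- stage("network_build", lapply(stats::setNames(ids, ids),
    function(id) build_network(inputs$sets[[id]], inputs$interactions,
                               min_score = cfg$min_score,
                               keep_isolated = cfg$keep_isolated,
                               disease_id = id)))
  centralities <- stage("centrality", lapply(networks, node_centrality))
  selections <- stage("selection", lapply(
    centralities, call_hub_bottlenecks,
    fraction = cfg$bottleneck_fraction, sd_mode = cfg$sd_mode))
  overlap <- stage("comparison", compare_networks(
    networks[[1]], selections[[1]], networks[[2]], selections[[2]],
    universe_size = cfg$overlap_universe))

  enrichment <- connectors <- NULL
  if (!is.null(inputs$pathways)) {
    enrichment <- stage("enrichment", enrich(
      overlap$shared_nodes, inputs$pathways,
      universe_size = cfg$enrichment_universe,
      min_overlap = cfg$min_overlap, adjust = cfg$adjust_method))
    connectors <- stage("enrichment", rank_connectors(enrichment))
  }

  files <- stage("report", {
    f <- list()
    for (id in ids) {
      f[[paste0("centrality_", id)]] <-
        write_centrality(centralities[[id]],
                         file.path(cfg$out_dir,
                                   paste0("centrality_", id, ".tsv")))
      f[[paste0("selection_", id)]] <-
        write_selection(selections[[id]],
                        file.path(cfg$out_dir,
                                  paste0("selection_", id, ".tsv")))
    }
    f$overlap <- write_overlap(overlap,
                               file.path(cfg$out_dir, "overlap.tsv"))
    if (!is.null(enrichment)) {
      f$enrichment <- write_enrichment(
        connectors, file.path(cfg$out_dir, "enrichment.tsv"))
    }
    f
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("comorbidnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    diseases = ids,
    parameters = cfg[c("min_score", "keep_isolated", "bottleneck_fraction",
                       "sd_mode", "overlap_universe", "enrichment_universe",
                       "adjust_method", "min_overlap")],
    inputs = cfg[c("gene_sets_path", "gene_sets_dialect",
                   "interactions_path", "score_scale", "pathways_path")],
    synthetic = if (!is.null(cfg$synthetic)) unclass(cfg$synthetic),
    thresholds = lapply(selections, `[[`, "thresholds"),
    network_summaries = lapply(networks, function(n)
      as.list(network_summary(n))),
    results = list(
      n_shared_nodes = length(overlap$shared_nodes),
      shared_hub_bottlenecks = overlap$shared_hub_bottlenecks,
      jaccard = overlap$jaccard,
      hypergeom_p = overlap$hypergeom_p,
      top_connector = if (!is.null(connectors)) connectors$term[[1]],
      top_connector_adjusted_p =
        if (!is.null(connectors)) connectors$adjusted_p[[1]]))
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files$manifest <- manifest_path

  structure(list(config = cfg, networks = networks,
                 centralities = centralities, selections = selections,
                 overlap = overlap, enrichment = enrichment,
                 connectors = connectors, scenario = inputs$scenario,
                 files = files, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", paste(x$manifest$diseases, collapse = " vs "),
      "\n", sep = "")
  print(x$overlap)
  if (!is.null(x$connectors)) {
    cat("  top connector: ", x$connectors$term[[1]], " (adjusted p ",
        signif(x$connectors$adjusted_p[[1]], 3), ")\n", sep = "")
  }
  cat("  outputs: ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}

#' Recompute the packaged worked-example numbers
#'
#' Re-derives, from the packaged published tables, every headline number
#' of the AD/diabetes worked example — per-disease hub-bottleneck counts,
#' the 7-gene intersection, the pathway-source partition, and the
#' top-ranked connector — and checks each against its published value.
#'
#' @param quiet suppress the printed table.
#' @return (invisibly) a data.frame with columns `check`, `value`,
#'   `expected`, `pass`.
#' @export
fixture_report <- function(quiet = FALSE) {
  tab1 <- load_table1_fixture()
  tab2 <- load_table2_fixture()
  hb_ad <- tab1$gene[tab1$disease == "AD"]
  hb_dm <- tab1$gene[tab1$disease == "Diabetes"]
  common <- shared_genes(hb_ad, hb_dm)
  ranked <- rank_connectors(tab2)
  src <- table(tab2$source)
  checks <- data.frame(
    check = c("AD hub-bottlenecks", "Diabetes hub-bottlenecks",
              "shared hub-bottlenecks", "pathways total",
              "KEGG pathways", "Reactome pathways",
              "WikiPathways pathways", "top connector term",
              "top connector adjusted p"),
    value = c(length(hb_ad), length(hb_dm), length(common), nrow(tab2),
              src[["KEGG"]], src[["Reactome"]], src[["WikiPathways"]],
              ranked$term[[1]], format(ranked$adjusted_p[[1]])),
    expected = c(14, 12, 7, 34, 15, 5, 14,
                 "Non-alcoholic fatty liver disease (NAFLD)",
                 format(7.09e-15)),
    stringsAsFactors = FALSE)
  checks$pass <- checks$value == checks$expected
  if (!quiet) print(checks, right = FALSE)
  invisible(checks)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
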