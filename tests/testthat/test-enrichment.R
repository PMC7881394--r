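test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)      # m = 1
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH output is monotone, >= raw p, and permutation-equivariant", {
  for (s in 1:15) {
    set.seed(s)
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("enrichment p-values match the brute-force summation oracle", {
  for (s in 1:25) {
    set.seed(s)
    u <- sample(10:30, 1)
    syms <- sprintf("U%02d", seq_len(u))
    query <- sample(syms, sample(2:(u - 2), 1))
    lib <- lapply(1:4, function(i) sample(syms, sample(2:(u - 2), 1)))
    names(lib) <- paste0("P", 1:4)
    res <- enrich(query, lib, universe_size = u)
    for (i in seq_len(nrow(res))) {
      row <- res[i, ]
      expect_equal(row$raw_p,
                   hyper_tail_brute(row$overlap_count, u, row$set_size,
                                    length(query)), tolerance = 1e-12)
      expect_equal(length(row$associated_genes[[1]]), row$overlap_count)
      expect_setequal(row$associated_genes[[1]],
                      intersect(lib[[row$term]], query))
    }
    expect_equal(res$adjusted_p, bh_adjust(res$raw_p), tolerance = 1e-12)
    expect_true(all(diff(res$adjusted_p) >= -1e-15))
  }
})

test_that("enrich handles edge cases per contract", {
  lib <- list(hit = c("A", "B", "C"), miss = c("X", "Y", "Z"))
  res <- enrich(c("A", "B", "C"), lib, universe_size = 100)
  # disjoint pathway appears with raw p = P[X >= 0] = 1
  expect_equal(res$raw_p[res$term == "miss"], 1)
  expect_equal(res$overlap_count[res$term == "miss"], 0L)
  # query == pathway in a large universe: extreme tail
  expect_equal(res$raw_p[res$term == "hit"],
               hyper_tail_brute(3, 100, 3, 3), tolerance = 1e-12)
  expect_identical(res$term[1], "hit")

  expect_warning(res0 <- enrich(c("A"), list(), universe_size = 100),
                 "empty pathway library")
  expect_equal(nrow(res0), 0L)
  expect_error(enrich(c("A", "B"), list(p = c("C", "D")),
                      universe_size = 3), "universe_size")
  # bonferroni is never below BH
  res_b <- enrich(c("A", "B", "C"), lib, universe_size = 100,
                  adjust = "bonferroni")
  expect_true(all(res_b$adjusted_p >=
                    res$adjusted_p[match(res_b$term, res$term)] - 1e-15))
  # min_overlap filters reported rows without changing p-values
  res_f <- enrich(c("A", "B", "C"), lib, universe_size = 100,
                  min_overlap = 1)
  expect_identical(res_f$term, "hit")
  expect_equal(res_f$adjusted_p, res$adjusted_p[res$term == "hit"])
})

test_that("an overlap-0 pathway never lowers other adjusted p-values", {
  set.seed(3)
  syms <- sprintf("U%02d", 1:40)
  query <- syms[1:10]
  lib <- lapply(1:5, function(i) sample(syms, 8))
  names(lib) <- paste0("P", 1:5)
  base <- enrich(query, lib, universe_size = 1000)
  lib2 <- c(lib, list(Z = sprintf("V%02d", 1:8)))  # disjoint from universe syms
  ext <- enrich(query, lib2, universe_size = 1000)
  m <- match(base$term, ext$term)
  expect_equal(ext$raw_p[m], base$raw_p)
  expect_true(all(ext$adjusted_p[m] >= base$adjusted_p - 1e-12))
})

test_that("a planted pathway is ranked first in almost all seeded runs", {
  target <- sprintf("G%04d", 1:40)
  hits <- 0L
  for (s in 1:100) {
    cfg <- synthetic_config(n_genes = 500, set_size_a = 60,
                            set_size_b = 60, overlap_count = 40,
                            n_pathways = 10, pathway_size = 15,
                            enrichment_rate = 0.8, seed = s)
    gen <- generate_pathway_library(cfg, target)
    res <- enrich(target, gen$library, universe_size = 500)
    if (res$term[1] == gen$planted_term &&
        res$adjusted_p[1] == min(res$adjusted_p)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("connector ranking puts NAFLD at the head of the published table", {
  ranked <- rank_connectors(load_table2_fixture())
  expect_identical(ranked$term[1],
                   "Non-alcoholic fatty liver disease (NAFLD)")
  expect_identical(ranked$source[1], "KEGG")
  expect_equal(ranked$adjusted_p[1], 7.09e-15)
  expect_equal(ranked$rank, 1:34)
  expect_true(all(diff(ranked$adjusted_p) >= 0))

  one <- data.frame(term = "only", adjusted_p = 0.5, overlap_count = 3)
  expect_identical(rank_connectors(one)$term, "only")

  ties <- data.frame(term = c("small", "big"), adjusted_p = c(1e-4, 1e-4),
                     overlap_count = c(5L, 13L))
  expect_identical(rank_connectors(ties)$term, c("big", "small"))
})

test_that("enrichment results serialize with comma-joined gene lists", {
  lib <- list(hit = c("A", "B", "C"))
  res <- enrich(c("A", "B"), lib, universe_size = 50)
  f <- withr::local_tempfile()
  write_enrichment(res, f)
  back <- read.delim(f)
  expect_identical(back$associated_genes, "A,B")
})
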