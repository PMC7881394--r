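ct <- function(degree, betweenness = seq_along(degree) / 100) {
  data.frame(node = sprintf("g%02d", seq_along(degree)),
             degree = degree, betweenness = betweenness)
}

test_that("hub rule reproduces hand-computed population thresholds", {
  # degrees {2 x9, 20}: mean 3.8, population SD 5.4, cutoff 14.6
  res <- call_hubs(ct(c(rep(2, 9), 20)))
  expect_equal(res$thresholds$mean_degree, 3.8)
  expect_equal(res$thresholds$sd_degree, 5.4)
  expect_equal(res$thresholds$hub_cutoff, 14.6)
  expect_identical(res$genes, "g10")

  # degrees {1,1,1,1,10}: cutoff exactly 10; "above" is strict
  res2 <- call_hubs(ct(c(1, 1, 1, 1, 10)))
  expect_equal(res2$thresholds$hub_cutoff, 10)
  expect_identical(res2$genes, character(0))

  # equal degrees: SD 0, nothing strictly above the mean
  expect_identical(call_hubs(ct(rep(4, 8)))$genes, character(0))

  expect_error(call_hubs(ct(5)), "at least 2 nodes")
})

test_that("sample-SD mode widens the cutoff accordingly", {
  d <- c(rep(2, 9), 20)
  res <- call_hubs(ct(d), sd_mode = "sample")
  expect_equal(res$thresholds$sd_degree, sd(d))
  expect_gt(res$thresholds$hub_cutoff, 14.6)
})

test_that("bottleneck rule takes ceiling(fraction x N) with boundary ties", {
  # 20 distinct values, 5% -> exactly the maximum
  res <- call_bottlenecks(ct(rep(1, 20), betweenness = (1:20) / 20))
  expect_equal(res$thresholds$bottleneck_rank_count, 1L)
  expect_identical(res$genes, "g20")

  # top value shared by 3 nodes -> all three selected
  b <- c(rep(0.1, 17), rep(0.9, 3))
  res2 <- call_bottlenecks(ct(rep(1, 20), betweenness = b))
  expect_setequal(res2$genes, c("g18", "g19", "g20"))
  expect_equal(res2$thresholds$bottleneck_cutoff, 0.9)

  # fraction 1 -> everything
  expect_length(call_bottlenecks(ct(rep(1, 7)), fraction = 1)$genes, 7L)

  # k is a ceiling: 21 nodes at 5% -> 2 ranks
  res3 <- call_bottlenecks(ct(rep(1, 21), betweenness = (1:21) / 21))
  expect_equal(res3$thresholds$bottleneck_rank_count, 2L)
  expect_setequal(res3$genes, c("g20", "g21"))

  expect_error(call_bottlenecks(ct(rep(1, 5)), fraction = 0), "fraction")
})

test_that("hub-bottlenecks are the intersection of both rules", {
  star <- igraph::make_star(10, mode = "undirected")
  igraph::V(star)$name <- c("center", paste0("leaf", 1:9))
  sel <- call_hub_bottlenecks(node_centrality(star))
  # K_{1,9}: mean 1.8, pop SD 2.4, cutoff 6.6; center betweenness 1
  expect_equal(sel$thresholds$hub_cutoff, 6.6)
  expect_identical(sel$hub_bottlenecks, "center")

  cyc <- igraph::make_ring(10)
  igraph::V(cyc)$name <- paste0("c", 1:10)
  sel2 <- call_hub_bottlenecks(node_centrality(cyc))
  expect_identical(sel2$hubs, character(0))
  expect_identical(sel2$hub_bottlenecks, character(0))

  # plain set algebra on a crafted table: hubs {A,B}, bottlenecks {B,C}
  tab <- data.frame(node = c("A", "B", "C", "D", rep("x", 16)),
                    degree = c(30, 30, 1, 1, rep(1, 16)),
                    betweenness = c(0.1, 0.9, 0.9, 0.1, rep(0, 16)))
  tab$node <- make.unique(tab$node)
  sel3 <- call_hub_bottlenecks(tab, fraction = 0.1)
  expect_setequal(sel3$hubs, c("A", "B"))
  expect_setequal(sel3$bottlenecks, c("B", "C"))
  expect_identical(sel3$hub_bottlenecks, "B")
})

test_that("selection invariants hold on random centrality tables", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:80, 1)
    tab <- ct(rpois(n, 4) + 1, betweenness = round(runif(n), 2))
    sel <- call_hub_bottlenecks(tab, fraction = 0.05)
    expect_true(all(sel$hub_bottlenecks %in% sel$hubs))
    expect_true(all(sel$hub_bottlenecks %in% sel$bottlenecks))
    expect_true(all(c(sel$hubs, sel$bottlenecks) %in% tab$node))
    k <- ceiling(0.05 * n)
    expect_gte(length(sel$bottlenecks), k)
    b_sorted <- sort(tab$betweenness, decreasing = TRUE)
    if (k == n || b_sorted[k] > b_sorted[k + 1]) {  # no boundary tie
      expect_length(sel$bottlenecks, k)
    }
    # permuting rows never changes the selected sets
    perm <- sample(n)
    sel_p <- call_hub_bottlenecks(tab[perm, ], fraction = 0.05)
    expect_setequal(sel_p$hubs, sel$hubs)
    expect_setequal(sel_p$bottlenecks, sel$bottlenecks)
    expect_setequal(sel_p$hub_bottlenecks, sel$hub_bottlenecks)
  }
})

test_that("planted hubs are recovered exactly from synthetic networks", {
  # hubs wired far above the scale-free background tail (40x mean degree)
  # must be the only hub-bottlenecks called, across seeds
  for (s in 1:20) {
    cfg <- synthetic_config(n_genes = 203, attachment_edges = 2,
                            n_planted_hubs = 3, n_shared_hubs = 0,
                            hub_degree_multiplier = 40,
                            set_size_a = 203, set_size_b = 203,
                            overlap_count = 0, seed = s)
    tab <- generate_interactome(cfg)
    net <- suppressMessages(build_network(unique(c(tab$a, tab$b)), tab,
                                          min_score = 0))
    sel <- call_hub_bottlenecks(node_centrality(net))
    expect_setequal(sel$hub_bottlenecks, attr(tab, "planted_hubs"))
  }
})

test_that("selection results serialize with per-node flags and thresholds", {
  star <- igraph::make_star(10, mode = "undirected")
  igraph::V(star)$name <- c("center", paste0("leaf", 1:9))
  sel <- call_hub_bottlenecks(node_centrality(star))
  f <- withr::local_tempfile()
  write_selection(sel, f)
  back <- read.delim(f)
  expect_equal(sum(back$is_hub_bottleneck), 1L)
  meta <- jsonlite::read_json(paste0(f, ".thresholds.json"))
  expect_equal(meta$hub_cutoff, 6.6)
  expect_equal(meta$bottleneck_rank_count, 1L)
})
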