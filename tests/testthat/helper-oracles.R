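# Independent oracles and small generators shared across test files.

# Seeded Erdos-Renyi graph with named vertices (may be disconnected).
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# Brute-force hypergeometric upper tail P[X >= k] for an overlap of two
# sets of sizes sa, sb drawn from a universe of size u: explicit summation
# of the probability mass function.
hyper_tail_brute <- function(k, u, sa, sb) {
  i <- seq(max(k, 0, sa + sb - u), min(sa, sb))
  if (!length(i) || k > min(sa, sb)) return(0)
  sum(choose(sa, i) * choose(u - sa, sb - i)) / choose(u, sb)
}

# Step-up FDR adjustment written as the literal definition:
# adj_(i) = min over j >= i of m * p_(j) / j (on sorted p), capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Drop the bookkeeping attributes of an interaction_table, keeping only
# the edge columns, for value comparisons.
edge_values <- function(x) {
  data.frame(a = x$a, b = x$b, score = x$score)
}

# Two gene sets of sizes sa, sb sharing exactly k symbols, drawn from a
# universe of u symbols.
overlap_sets <- function(k, u, sa, sb) {
  syms <- sprintf("U%02d", seq_len(u))
  a <- syms[seq_len(sa)]
  b <- c(a[seq_len(k)], setdiff(syms, a)[seq_len(sb - k)])
  list(a = a, b = b)
}
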