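---
title: "Comparing disease networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing disease networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidnet)
```

`comorbidnet` implements a disease-comparison workflow common in network
medicine: two diseases are each represented by the protein–protein
interaction (PPI) network induced by their associated genes, the
topologically central genes of each network are called, and what the two
networks share is characterized — first as gene overlap, then as pathway
over-representation of the shared genes, whose top-ranked term is read
as a candidate "connector" between the diseases. This vignette records
the model, the parameter choices, and the places where the design was
genuinely open.

## From exported tables to networks

The workflow deliberately starts from *files*, not live databases: a
disease gene set (two-column TSV or GMT), a scored edge table (the
STRING export dialect), a GMT pathway library. Database snapshots
change; files are citable and reproducible. Three normalization rules
are applied everywhere and are worth stating bluntly:

- symbols are matched as exact strings after trimming, upper-casing and
  **hyphen removal** (`IL-6` ≡ `IL6`, `IL-1B` ≡ `IL1B`). Published gene
  lists mix these spellings freely; hyphen removal folds them together.
  No alias or ortholog mapping is attempted — if two sources use
  genuinely different symbols for one gene, they will not match, and
  symbols whose identity depends on a hyphen would be conflated. This
  is a documented limitation, not a claim of identifier resolution.
- the score scale of an edge table (`unit` vs `string999`) must be
  declared by the caller. Auto-detection was rejected: a table of
  scores like `900` silently read as unit-scale probabilities would
  corrupt every threshold downstream.
- duplicate unordered pairs collapse to their **maximum** score, and
  self-pairs are dropped; both counts are reported.

A disease network is the induced subgraph of the edge table on the gene
set, keeping edges with score ≥ `min_score`. The default
`min_score = 0.4` is the conventional STRING "medium confidence" cutoff;
the source study states no cutoff, so it is configurable. Genes without
a surviving edge are dropped by default (`keep_isolated = FALSE`): the
published networks contain fewer nodes than their gene lists (347 nodes
from 386 AD genes; 211 from 523 diabetes genes), consistent with
unmapped or unconnected genes being absent, and isolated nodes carry no
centrality signal. The full network is analyzed, not the largest
component — betweenness is well defined on disconnected graphs, and
there is no evidence the original analysis filtered components.

## Centrality and the hub-bottleneck rules

Degree is the unweighted edge count; confidence scores are a filter,
never a distance (published hub degrees are integers, i.e. unweighted).
Betweenness of node *v* sums, over unordered pairs *(s, t)* with
*s, t ≠ v*, the fraction of shortest *s–t* paths through *v*,
normalized by the pair count *(N−1)(N−2)/2* so values lie in [0, 1]
and a star center scores exactly 1. Choices that matter numerically:

- **Unreachable pairs contribute zero** — no per-component
  renormalization. This is the simplest well-defined extension to
  disconnected graphs and keeps values comparable across networks.
- For *N* < 3 the normalizer vanishes; betweenness is defined as 0.
- The production implementation is Brandes' algorithm (via `igraph`);
  `betweenness_oracle()` is an independent brute-force BFS
  path-enumeration in base R, capped at 60 nodes, kept solely so tests
  can check one route against the other (they agree to 1e-12 on
  hundreds of seeded random graphs).

Selection applies two rules to the centrality table:

- **Hubs**: degree strictly above `mean + 2·SD`. "Above" is taken
  literally (strict `>`), so a node sitting exactly on the cutoff is
  *not* a hub, and a degree-regular network has no hubs. The SD is the
  **population** SD (divisor *N*): the network's nodes are the entire
  population under study, not a sample from one. Because conventions
  differ, `sd_mode = "sample"` is available.
- **Bottlenecks**: the top 5% of betweenness, as *k* = ⌈0.05·*N*⌉
  nodes with **boundary ties included** — ties must not be broken by
  input order, so the selection can exceed *k* but never depends on row
  permutation. The fraction is configurable (some definitions use top
  10%; 5% is the operative default).
- **Hub-bottlenecks** are the intersection, with both rules' thresholds
  recorded in the result and in serialized output.

## Comparing two networks

`compare_networks()` reports shared nodes, shared hub-bottlenecks, the
Jaccard index of the node sets, and a one-sided hypergeometric tail
P[X ≥ overlap] for X ~ Hypergeom(universe, |A|, |B|). Overlap statistics
are computed on **network node sets**, not the raw gene lists — "shared
proteins between networks" means nodes that survived network
construction on both sides. The default universe is `|A ∪ B|`: it is
self-contained (no external gene count needed) and conservative; a
genome-scale universe (e.g. 20 000) can be passed explicitly. The
original analysis performed no overlap significance test at all, so
this statistic is an addition, not a reproduction.

## Over-representation and connector ranking

`enrich()` tests the shared genes against each pathway with the same
one-sided hypergeometric tail (equivalently one-sided Fisher), with a
default universe of 20 000 protein-coding genes (configurable and
recorded in the output). Correction is Benjamini–Hochberg by default
(the published table says only "adjusted p-value"; Bonferroni is
available). Every library term is tested and counted in the correction
*m*; `min_overlap` (default 0) filters only the reported rows, never
the tested set — dropping zero-overlap terms from *m* would make
adjusted p-values depend on which uninteresting terms happened to be in
the library. Rows are ordered by adjusted p, ties by larger overlap,
then term id; `rank_connectors()` applies the same ordering to either
an enrichment result or the packaged published table, and its head row
is the nominated connector.

The published tables themselves (`load_table1_fixture()`,
`load_table2_fixture()`) are **reference data, not regeneration
targets**: their centralities and p-values depend on unstated DisGeNET,
STRING and ClueGO versions and cannot be recomputed from first
principles. The package therefore anchors its worked example on the
printed values (row counts 14/12, the 7-gene intersection, the
15/5/14 source partition, the minimal adjusted p of 7.09e-15 for KEGG
NAFLD) and keeps them in plain-text fixtures. One internal discrepancy
of the source is preserved as printed rather than resolved: the male
infertility row lists 9 associated genes while the surrounding
discussion says 8.

## The synthetic benchmark

The generator exists to answer one question: *if the data contained the
structure this pipeline assumes, would the pipeline find it?* It
emulates the statistical shape of the inputs — nothing biological:

- **Interactome**: linear preferential attachment (`igraph::sample_pa`,
  `m = 2` edges per node, so mean degree ≈ 4) over 2000 synthetic
  symbols, giving the heavy-tailed degree distribution characteristic
  of PPI networks. Scores are uniform on [0.4, 1], i.e. above the
  default threshold; thresholding behaviour is exercised in tests with
  explicit low-score edges instead of entangling it with recovery.
- **Planted hubs** are wired to uniformly sampled partners until their
  degree reaches `hub_degree_multiplier` × the background mean degree.
  The default multiplier is **30**. This is the one parameter where
  naive intuition fails: in a scale-free background the natural maximum
  degree grows like *m*·√*n* (≈ 22× the mean at *n* = 2000), so a hub
  planted at, say, 5× the mean sits well inside the background tail
  and is unrecoverable *in principle* by any degree rule. A planted
  hub must out-degree the background's natural extremes to constitute
  ground truth; 30× places it just above them at the default scale.
- **Disease pair**: gene sets of 386 and 523 symbols (the worked
  example's sizes) sharing exactly 40 genes, the overlap seeded with 2
  of the 4 planted hubs so that shared hub-bottlenecks exist by
  construction; remaining hubs split between the sets (3 planted hubs
  per disease).
- **Pathway library**: 10 sets of 15 genes; one planted set draws 80%
  of its members from the shared genes, the rest are uniform
  background.

All outputs are pure functions of the configuration and its single
seed. What the benchmark does *not* emulate: evidence-score structure,
literature/ascertainment bias, tissue specificity, modular or clustered
PPI topology, or realistic pathway overlap structure. Passing the
recovery tests therefore shows the *inference machinery* is sound — it
does not validate biological conclusions drawn from any particular
database export.

The packaged end-to-end check runs the full pipeline on 20 seeded
default scenarios and requires the planted shared hubs to appear among
the recovered shared hub-bottlenecks and the planted pathway to rank
first in at least 18 of 20; the induced disease networks in this
scenario have a few hundred nodes each, which keeps the whole suite
fast while leaving the selection rules non-trivial (background
hub-bottlenecks do occur; recovery, not absence of false positives, is
the end-to-end criterion). A stricter zero-false-positive property is
asserted at small scale (~200 background nodes) with hubs wired to 40×
the mean, where the degree cutoff — itself inflated by the planted
nodes — excludes the background extremes.

## Degenerate inputs and numerical conventions

- Empty network after thresholding → explicit error (centrality would
  be undefined), naming the disease.
- Single-node centrality table → hub selection refuses (an SD over one
  node is meaningless for selection).
- `jaccard_index` on two empty sets and a universe smaller than
  `|A ∪ B|` → errors, not NaN.
- p-values are validated into (0, 1] before BH; the adjusted values are
  compared against a literal "min over j ≥ i of m·p/j" double loop in
  tests.
- Betweenness equality between implementation and oracle is asserted at
  1e-12; hypergeometric tails against brute-force PMF summation for
  every universe ≤ 30.
- All serialized tables have fixed, documented column orders;
  betweenness is written with 6 decimals, matching the precision of the
  published table.

## Interface notes

The package is used from R: `run_pipeline()` orchestrates
build → centrality → selection → comparison → enrichment with per-stage
error messages, per-stage TSV outputs and a JSON manifest holding every
threshold, seed and version, sufficient to re-run the analysis
identically; `fixture_report()` recomputes the worked-example numbers
as a pass/fail table. `scripts/acceptance.R` wraps the same entry
points for a from-scratch reproduction run.

## Known limitations

- Exact-string gene matching (see above) — no identifier mapping.
- Two diseases per comparison; no multi-disease matrix.
- No term–term clustering of enriched pathways (ClueGO-style kappa
  networks are out of scope); the connector is read off a flat ranking.
- The hypergeometric overlap test treats genes as exchangeable; degree
  bias of disease genes is not modelled.
- Published fixture values are anchors for the worked example only;
  reconstructing the original 347/211-node networks would require the
  original database snapshots.
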