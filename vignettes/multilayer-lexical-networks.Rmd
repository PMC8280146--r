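---
title: "Multilayer phonological-semantic lexical networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer phonological-semantic lexical networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexnet)
```

## The model

The mental lexicon stores words with both a meaning (semantic) and a sound
(phonological) representation. `lexnet` treats these as two layers of one
multilayer network over a shared word set and provides the machinery to ask
how strongly the layers overlap, what adding links from one layer to the
other does to path lengths, and whether a mixed architecture is more
efficient (shorter average distances) than either layer alone.

**Phonological layer.** Words are phoneme token sequences; two words are
connected exactly when their token-level Levenshtein distance is 1 — one
phoneme added, deleted, or substituted. The layer is unweighted, and all
path lengths everywhere in the package are hop counts. Homophones (edit
distance 0) are not linked. The layer typically fragments into a giant
component plus many isolates; analyses consume the giant component.

**Semantic layer.** From a free-association table of
(cue, response, participant count) records, the link strength between cues
$C_i$ and $C_j$ is

$$\mathrm{Link}(C_i, C_j) \;=\; \sum_{k} \min\!\big(\#P_{C_i}A(k),\; \#P_{C_j}A(k)\big),$$

the sum over responses $k$ produced to both cues of the smaller participant
count. A term enters only when that minimum is at least
`min_shared_participants` (default 2): an overlap a single participant
could have produced is treated as noise. The result is a weighted,
undirected network on the cue words; responses that are not cues contribute
to weights but are not nodes. Before any distance comparison with the
phonological layer the semantic layer is converted to unweighted, usually
after keeping a top fraction of links by strength (default 1%).

**Null models.** Two randomisations are used, and each analysis names its
default. The degree-preserving shuffle rewires by double-edge swaps and
keeps every node's degree (the default null for the window-overlap
analysis). The edge permutation redraws all endpoints uniformly at the same
node and edge count, destroying the degree sequence (the default for the
distance-class overlap null series, matching a permutation of the semantic
links). Which null backed which original figure panel is not decidable from
the source description; the per-stage defaults are configuration, not a
reconstruction.

## The analyses

**Window overlap** (`sort_and_window` + `window_overlap_ratio`). Semantic
links are sorted ascending by strength and cut into equal windows. Per
window and phonological distance $d$, we sample links, measure the fraction
lying at phonological distance exactly $d$, normalise by the number of
distance-$d$ pairs, and divide by the same quantity measured against a
freshly drawn null per iteration. Ratios are formed against the mean null
fraction across iterations (a ratio-of-averages), and `ratio_sd` is the
spread of the per-iteration ratios. Both the observed and null fractions
are measured on the same sampled links; sampling both sides symmetrically
was an open choice and is the documented one. Windows whose links all fall
outside the phonological component are flagged `empty`.

**Distance-class overlap** (`distance_class_pairs` +
`distance_class_overlap`). Phonological pairs at exact distance $d$ are
sampled, and the fraction that are weak / medium / strong semantic links is
measured, plus a shuffled-semantic series. The original description permutes
the full semantic link set yet plots a series on the scale of one strength
group, so the null series here is a group-sized random edge set (or a
group-sized subsample of a degree-preserving shuffle of the three groups'
union).

**Strength groups.** `terciles` cuts the ascending sort into three
contiguous groups (remainder to the weak end, so 10 links split 4/3/3).
`separated` takes three equal groups of `floor(E/5)` links from the bottom,
centre, and top with equal gaps — a concrete, declared reading of
"maximally separable", not a reconstruction.

**Link addition** (`nonoverlapping_links`, `measure_reduction`,
`reduction_ratio_experiment`, `rps_table`). Non-overlapping links of one
layer (pairs connected there but not in the target layer) are added to the
target and the total distance reduction (including indirect reductions via
new paths) is compared with adding the same number of uniformly random
absent pairs, drawn by rejection sampling so the theoretical fully
connected layer is never materialised. The baseline is the pooled mean of
the random iterations — the per-iteration sums are normalised by the mean
random sum, so a ratio of 1 means chance-level shortening. The Ratio of
Path Shortening, RPS$(k)$, compares the count of pairs reduced from
original distance $k$ directly to distance 1 against the random analogue;
cells with a zero random denominator are flagged undefined. The reverse
direction (semantic strength groups added to the phonological layer) uses
the same operations with layers swapped, with the added-link budget scaled
proportionally (`round(|target edges| * 4439/100000)`).

**Degree-matched quadruples** (`build_matched_quadruple`,
`distance_sweep`). For a strength window, four networks on the shared nodes
with identical edge counts are compared: semantic (spanning connector
preferring stronger links, filled from the window's strongest links
downward), phonological (fixed), multilayer (merge, pruned to a spanning
connector, then refilled alternately with the strongest remaining semantic
link and a seeded-random phonological link — the refill order was
under-specified and this alternation is the package's documented choice),
and random (edge permutation, the documented default for the fourth
member). Mean distances average hop counts over finite pairs
(`policy = "exclude"`), since averages on fragmented networks are otherwise
undefined; the original analyses work on giant components.

**Communities** (`detect_communities`, `interlink_fraction`). Louvain
modularity maximisation at resolution `gamma = 1`. Louvain is
order-dependent, so five seeded restarts are run and the highest-modularity
partition kept. The inter-link fraction of an edge set is the share of
edges crossing community boundaries; for uniformly random edges it
converges to $1 - \sum_c (n_c/n)^2$.

**Fraction sweep** (`fraction_sweep`). At a fixed total edge budget (the
phonological layer's edge count), multilayer networks are built for a grid
of semantic link fractions. The spanning connector is rebuilt per fraction
with layer-biased costs so its composition tracks the requested mixture;
without this, the connector exhausts one layer's budget at desk scale and
extreme fractions become unrealizable (such fractions are skipped with a
warning, never silently).

**Reaction times** (`match_degree`, `rt_by_path_length`,
`subsample_network_replicates`). RT pairs are bucketed by network path
length 1-4 (longer paths and disconnected pairs are excluded, following
the finding that relatedness judgments track path length only in that
range). Networks may be rebuilt per iteration; each iteration buckets by
its own network's distances and only the mean degree is matched between
compared networks — degree-distribution similarity is a deliberate
simplification left out.

## The synthetic lexicon

Raw large-scale association data is not bundled; `generate_lexicon`,
`generate_associations`, and `generate_rts` produce inputs with the
statistical structure the analyses assume, controlled by
`synthetic_config`:

* Words are phoneme strings over a small alphabet (default 10 symbols,
  lengths 3-6); with probability `mutation_prob` (0.6) a new word is a
  one-phoneme mutation of an existing word. This yields a sparse
  phonological layer whose giant component covers over half the words —
  mirroring a sparse sound layer under a dense meaning layer — while
  random-string generation alone would leave the layer nearly edgeless.
* Words belong to planted topic communities (default 4); each word prefers
  a small subset (5) of its topic's response pool (40 responses). 50
  participants per cue each give 3 responses: with probability
  `coupling_rho` from a phonological neighbour's preferred set, otherwise
  from the cue's own preferred set with odds `intra_community_boost` (8)
  against a uniform draw from another topic. Coupling therefore enters
  through shared response pools and must pass through the link-strength
  estimator to surface as a semantic link — the generator does not wire the
  semantic graph directly, so tests exercise the estimator, not just the
  statistic. `coupling_rho = 0` decouples the layers exactly (the null
  condition); `0.8` plants a strong, recoverable signal.
* RTs follow `intercept + slope * path_length + noise` (defaults
  650 + 40L ms, sd 30 ms), sampled balanced over path lengths 1-4.

One master seed fixes the lexicon, associations, RTs, all nulls, and all
outputs bit-for-bit; every randomised operation takes an explicit seed and
`spawn_seeds` derives per-iteration streams.

What the generator does **not** emulate: English phonotactics, Zipfian
response frequencies, cue-level sample-size imbalance, and asymmetric
association directions. Passing tests show the estimators and resampling
analyses recover planted structure and stay calibrated under the null; they
do not certify effect sizes on real association norms.

## Numerical choices and ties

* All distances are hop counts; semantic weights order links but never
  weight paths.
* Strength ties: association strengths are small integers, so tie blocks
  are large. Ties are broken by a deterministic polynomial hash of the edge
  key, then lexicographically. A purely lexicographic tie-break would slice
  windows by shared orthographic prefix — which correlates with phonological
  proximity — and plant spurious overlap into strength windows under the
  null; the hash keeps the order reproducible while decorrelating it from
  the words themselves.
* `filter_top_fraction` keeps `ceiling(f * E)` links; group sizes and
  window boundaries are documented above; the degree-matching tolerance is
  0.05 on mean degree (exact equality is unattainable with integer edge
  counts).
* Degenerate inputs error loudly: empty networks, windows with no eligible
  pairs (flagged, not an exception), unreachable degree targets (reporting
  the achievable value), and random-addition requests with no free pairs.

## Problem sizes

The package defaults target desk scale: 500-word lexicons, strength windows
of 1,000 links with 100-link samples, 25 Monte-Carlo iterations, and
networks of a few hundred nodes — the regimes used throughout the test
suite and the reproduction script. Study-scale parameters (windows of
100,000 links, samples of 10,000 and 3,000, 100 iterations) are the
documented configuration defaults on the same code paths.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_words = 300, coupling_rho = 0.8, seed = 7)
lex <- generate_lexicon(cfg)
assoc <- generate_associations(cfg, lex)

sem <- build_semantic_network(assoc)
phono <- giant_component(build_phonological_network(lex))

shared <- intersect(igraph::V(sem)$name, igraph::V(phono)$name)
sem_shared <- igraph::induced_subgraph(sem, shared)
phono_shared <- giant_component(igraph::induced_subgraph(phono, shared))

wins <- sort_and_window(sem_shared, 1000)
window_overlap_ratio(wins, phono_shared, distances = 1:3,
                     sample_size = 100, n_iterations = 25, seed = 11)
```

## Known limitations

* The multilayer refill and "maximally separable" group constructions are
  declared conventions where the source description is under-specified.
* Only mean degree is matched in RT comparisons, not the degree
  distribution.
* Significance testing of the exported distributions (ANOVA,
  Kruskal-Wallis, Mann-Whitney) is intentionally left to the user;
  the package emits the per-iteration distributions.
* Directed association structure, weighted shortest paths, and edit
  distances above 1 as links are out of scope.
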