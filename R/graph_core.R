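# Shared graph primitives: distances, components, null models, spanning
# connectors, distance summaries, edge-list TSV I/O.
#
# A "lexical network" is an undirected simple igraph with vertex names
# (words) and, when weighted, a positive edge attribute `weight`.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a lexical network
#'
#' Builds an undirected simple graph whose vertices are words. Self-loops and
#' duplicate edges are rejected rather than silently dropped, so that a
#' malformed edge list surfaces at construction time.
#'
#' @param edges data frame with columns `word_a`, `word_b` and optionally
#'   `weight` (positive association strength). May have zero rows.
#' @param nodes optional character vector of words; defaults to the words
#'   appearing in `edges`. Isolated words are kept as degree-0 vertices.
#' @return an igraph object; weighted iff `edges` had a `weight` column.
#' @export
lexical_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(word_a = character(), word_b = character())
  }
  stopifnot(all(c("word_a", "word_b") %in% names(edges)))
  a <- as.character(edges$word_a)
  b <- as.character(edges$word_b)
  if (any(a == b)) {
    stop("self-loop edge(s) on: ", paste(unique(a[a == b]), collapse = ", "))
  }
  key <- edge_keys(a, b)
  if (anyDuplicated(key)) {
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  nodes <- nodes %||% sort(unique(c(a, b)))
  miss <- setdiff(c(a, b), nodes)
  if (length(miss)) stop("edge endpoint(s) not in node set: ", paste(miss, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
  if ("weight" %in% names(edges)) {
    w <- as.numeric(edges$weight)
    if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive and finite")
    igraph::E(g)$weight <- w
  }
  g
}

# canonical "a|b" keys for unordered word pairs
edge_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Extract the edge list of a network as a tibble
#'
#' @param net lexical network.
#' @return tibble with `word_a < word_b` (lexicographic canonical order) and,
#'   if the network is weighted, a `weight` column.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  out <- tibble::tibble(
    word_a = pmin(el[, 1], el[, 2]),
    word_b = pmax(el[, 1], el[, 2])
  )
  if ("weight" %in% igraph::edge_attr_names(net)) {
    out$weight <- igraph::E(net)$weight
  }
  out
}

#' Hop-count shortest-path distance between two words
#'
#' Edge weights are ignored: all distances in these analyses are link counts,
#' the weighted semantic layer being converted to unweighted before distance
#' computation.
#'
#' @param net lexical network.
#' @param a,b words; must be vertices of `net`.
#' @return non-negative integer, `0` for `a == b`, `Inf` when `a` and `b`
#'   lie in different components.
#' @export
shortest_path_distance <- function(net, a, b) {
  nm <- igraph::V(net)$name
  for (w in c(a, b)) {
    if (!w %in% nm) stop("unknown word: '", w, "'")
  }
  as.numeric(igraph::distances(net, v = a, to = b, weights = NA))
}

#' Giant (largest connected) component
#'
#' Ties between equally large components are broken deterministically in
#' favour of the component containing the lexicographically smallest word.
#'
#' @param net nonempty lexical network.
#' @return the induced subgraph on the largest component.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network has no giant component")
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    smallest <- vapply(big, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, character(1))
    big <- big[order(smallest)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Degree-preserving edge shuffle (double-edge-swap null)
#'
#' Randomises the wiring while keeping every node's degree fixed, by repeated
#' double-edge swaps; swaps that would create a self-loop or multi-edge are
#' rejected and retried. Weights are dropped: the null is unweighted.
#'
#' @param net lexical network.
#' @param n_swaps number of attempted swaps; default ten per edge, a common
#'   mixing heuristic.
#' @param seed integer seed; the same seed reproduces the same null.
#' @return unweighted lexical network with the identical degree sequence.
#' @export
degree_preserving_shuffle <- function(net, n_swaps = 10 * igraph::ecount(net),
                                      seed = 1L) {
  stopifnot(n_swaps >= 0)
  g <- net
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  if (n_swaps == 0 || igraph::ecount(g) < 2) return(g)
  withr::with_seed(seed, igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
}

#' Edge-permutation null model
#'
#' Redraws all edge endpoints uniformly at random (no self-loops, no
#' duplicates) on the same node set with the same edge count. Unlike
#' [degree_preserving_shuffle()], the degree sequence is not preserved: any
#' node-link relation is destroyed.
#'
#' @param net lexical network.
#' @param seed integer seed.
#' @return unweighted lexical network, same nodes, same number of edges.
#' @export
edge_permutation_null <- function(net, seed = 1L) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  g <- withr::with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
  igraph::V(g)$name <- igraph::V(net)$name
  g
}

#' Spanning connector (per-component spanning forest)
#'
#' Returns, for each connected component of the candidate graph, a spanning
#' tree; the union connects exactly the components the candidates connect,
#' with the minimum number of links. When candidates carry weights, stronger
#' links are preferred; ties (including the fully unweighted case) are broken
#' by a seeded random jitter, so the result is deterministic given the seed.
#'
#' @param nodes character vector of words.
#' @param candidate_edges data frame `word_a`, `word_b` (+ optional `weight`)
#'   over `nodes`.
#' @param seed integer seed for tie-breaking.
#' @return tibble of the selected edges (canonical order), possibly empty.
#' @export
spanning_connector <- function(nodes, candidate_edges, seed = 1L) {
  g <- lexical_network(candidate_edges, nodes = nodes)
  if (igraph::ecount(g) == 0) {
    return(tibble::tibble(word_a = character(), word_b = character()))
  }
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  # mst minimises cost; prefer strong links -> cost decreasing in weight
  cost <- max(w) - w + 1
  jitter <- withr::with_seed(seed, runif(length(cost), 0, 0.5))
  forest <- igraph::mst(g, weights = cost + jitter)
  network_edges(forest)[, c("word_a", "word_b")]
}

#' Mean shortest-path distance summary
#'
#' Averages hop-count distances over unordered pairs of distinct nodes.
#' Policy `"exclude"` drops pairs in different components; policy
#' `"giant_component_only"` restricts the network to its giant component
#' first (on a connected network both agree).
#'
#' @param net nonempty lexical network.
#' @param policy disconnected-pair policy.
#' @param label network label carried into the summary.
#' @return one-row tibble: `network_label`, `mean_distance`, `n_pairs_used`,
#'   `disconnected_policy`.
#' @export
mean_distance_summary <- function(net,
                                  policy = c("exclude", "giant_component_only"),
                                  label = "network") {
  policy <- match.arg(policy)
  if (igraph::vcount(net) == 0) stop("empty network")
  if (policy == "giant_component_only") net <- giant_component(net)
  d <- igraph::distances(net, weights = NA)
  ut <- d[upper.tri(d)]
  fin <- ut[is.finite(ut)]
  if (length(fin) == 0) stop("no finite node pair under policy '", policy, "'")
  tibble::tibble(
    network_label = label,
    mean_distance = mean(fin),
    n_pairs_used = length(fin),
    disconnected_policy = policy
  )
}

#' Read / write edge lists as TSV
#'
#' Format: header line `#source<TAB>target<TAB>weight`, then one edge per
#' line; the weight column is omitted for unweighted graphs. UTF-8.
#'
#' @param net lexical network (for writing).
#' @param path file path.
#' @return `read_edge_tsv`: a lexical network; `write_edge_tsv`: `path`,
#'   invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  ed <- network_edges(net)
  weighted <- "weight" %in% names(ed)
  header <- if (weighted) "#source\ttarget\tweight" else "#source\ttarget"
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(ed)) {
    body <- if (weighted) {
      paste(ed$word_a, ed$word_b, format(ed$weight, scientific = FALSE, trim = TRUE), sep = "\t")
    } else {
      paste(ed$word_a, ed$word_b, sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_edge_tsv
#' @param nodes optional node set for the read graph (words absent from the
#'   edge list are kept as isolates).
#' @export
read_edge_tsv <- function(path, nodes = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(lexical_network(NULL, nodes = nodes %||% character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(!ncol %in% c(2L, 3L)) || length(unique(ncol)) != 1) {
    stop("malformed edge TSV: expected uniform 2 or 3 tab-separated columns")
  }
  ed <- data.frame(
    word_a = vapply(parts, `[[`, character(1), 1L),
    word_b = vapply(parts, `[[`, character(1), 2L)
  )
  if (ncol[1] == 3L) ed$weight <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  lexical_network(ed, nodes = nodes)
}

#' Spawn deterministic child seeds from a master seed
#'
#' All randomised stages take explicit seeds; a run-level master seed spawns
#' per-iteration seeds so that one integer fixes the whole pipeline.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each below 2^31.
#' @export
spawn_seeds <- function(master, n) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max - 1L, n))
}
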