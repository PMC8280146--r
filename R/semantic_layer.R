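# Semantic layer estimated from free-association data.
#
# The strength of the link between two cue words is the sum, over associative
# responses produced to both cues, of the smaller participant count —
# counting a shared response only when more than one participant stands
# behind it on both sides (min >= min_shared_participants, default 2). This
# filters overlap terms that a single participant's response could have
# created.

validate_association_table <- function(table) {
  stopifnot(all(c("cue", "response", "participant_count") %in% names(table)))
  tab <- tibble::as_tibble(table)
  tab$cue <- as.character(tab$cue)
  tab$response <- as.character(tab$response)
  tab$participant_count <- as.integer(tab$participant_count)
  if (any(tab$participant_count < 1)) stop("participant_count must be >= 1")
  if (anyDuplicated(paste(tab$cue, tab$response, sep = "\r"))) {
    stop("duplicate (cue, response) record(s); aggregate counts first")
  }
  tab
}

#' Read a free-association table
#'
#' TSV with columns `cue<TAB>response<TAB>participant_count`.
#'
#' @param path file path.
#' @return tibble with columns `cue`, `response`, `participant_count`.
#' @export
read_association_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("cue", "response", "participant_count"),
                          comment.char = "#", fileEncoding = "UTF-8",
                          colClasses = c("character", "character", "integer"))
  validate_association_table(df)
}

#' Normalize association responses
#'
#' Lowercases and trims responses (and cues), then re-aggregates counts.
#' `merge_fn` is a pluggable normalization hook (for example plural/singular
#' merging) applied to every word; it defaults to off. No stemming is done.
#'
#' @param table association table.
#' @param merge_fn optional `function(character) -> character` applied to
#'   cues and responses before aggregation.
#' @return normalized association table.
#' @export
normalize_associations <- function(table, merge_fn = NULL) {
  tab <- tibble::as_tibble(table)
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    if (!is.null(merge_fn)) x <- as.character(merge_fn(x))
    x
  }
  tab$cue <- norm(tab$cue)
  tab$response <- norm(tab$response)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$cue, .data$response),
    participant_count = sum(.data$participant_count), .groups = "drop"
  )
  validate_association_table(out)
}

#' Association link strength between two cue words
#'
#' Over all responses produced to both cues, sums the smaller of the two
#' participant counts, keeping only terms where that minimum reaches
#' `min_shared_participants` (default 2: more than one participant must
#' stand behind the shared response on each side).
#'
#' @param table association table (`cue`, `response`, `participant_count`).
#' @param ci,cj distinct cue words present in the table's cue set.
#' @param min_shared_participants minimum per-term shared participant count.
#' @return non-negative integer strength.
#' @export
link_strength <- function(table, ci, cj, min_shared_participants = 2L) {
  tab <- validate_association_table(table)
  cues <- unique(tab$cue)
  for (w in c(ci, cj)) if (!w %in% cues) stop("unknown cue: '", w, "'")
  if (ci == cj) stop("cue pair must be distinct")
  ri <- tab[tab$cue == ci, c("response", "participant_count")]
  rj <- tab[tab$cue == cj, c("response", "participant_count")]
  m <- merge(ri, rj, by = "response")
  if (nrow(m) == 0) return(0L)
  term <- pmin(m$participant_count.x, m$participant_count.y)
  sum(term[term >= min_shared_participants])
}

#' Build the weighted semantic network from an association table
#'
#' Nodes are the cue words; an edge joins every cue pair with positive
#' [link_strength()], with the strength as weight. Responses that are not
#' themselves cues contribute to weights but are not nodes. The association
#' direction is not preserved: the network is undirected.
#'
#' @inheritParams link_strength
#' @return weighted lexical network over all cues (cues without any link are
#'   isolated nodes).
#' @export
build_semantic_network <- function(table, min_shared_participants = 2L) {
  tab <- validate_association_table(table)
  cues <- sort(unique(tab$cue))
  if (length(cues) < 2) stop("need at least two cues")
  # pair cues through shared responses; min(count_i, count_j) >= threshold
  # implies both counts >= threshold, so records below it cannot contribute
  tab <- tab[tab$participant_count >= min_shared_participants, , drop = FALSE]
  edges <- NULL
  if (nrow(tab)) {
    joined <- dplyr::inner_join(tab, tab, by = "response",
                                relationship = "many-to-many",
                                suffix = c("_i", "_j"))
    joined <- joined[joined$cue_i < joined$cue_j, , drop = FALSE]
    if (nrow(joined)) {
      joined$term <- pmin(joined$participant_count_i, joined$participant_count_j)
      edges <- dplyr::summarise(
        dplyr::group_by(joined, word_a = .data$cue_i, word_b = .data$cue_j),
        weight = sum(.data$term), .groups = "drop"
      )
    }
  }
  lexical_network(edges, nodes = cues)
}

# deterministic polynomial hash of edge keys, used to break strength ties.
# Association strengths are small integers, so tie blocks are large; a
# lexicographic tie-break would slice windows by shared orthographic prefix,
# which correlates with phonological proximity and would plant spurious
# overlap into strength windows. The hash decorrelates tie order from the
# words themselves while staying fully reproducible.
edge_hash <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  vapply(key, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# edges sorted ascending by weight; ties broken by the deterministic edge
# hash (then lexicographically) — the order every windowing/grouping/
# filtering operation relies on
sorted_semantic_edges <- function(net, decreasing = FALSE) {
  ed <- network_edges(net)
  if (!"weight" %in% names(ed)) stop("network must be weighted")
  ord <- order(ed$weight, edge_hash(ed$word_a, ed$word_b), ed$word_a, ed$word_b)
  if (decreasing) ord <- rev(ord)
  ed[ord, , drop = FALSE]
}

#' Keep the strongest fraction of semantic links, unweighted
#'
#' Retains the `ceiling(fraction * |edges|)` strongest links (boundary ties
#' broken lexicographically) and drops weights, as done before comparing the
#' semantic layer with the unweighted phonological layer.
#'
#' @param net weighted lexical network with at least one edge.
#' @param fraction fraction in (0, 1]; the top 1% is the default analysis
#'   filter (2%, 3%, 5% probe robustness).
#' @return unweighted lexical network on the same node set.
#' @export
filter_top_fraction <- function(net, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  ed <- sorted_semantic_edges(net, decreasing = TRUE)
  if (nrow(ed) == 0) stop("network has no edges")
  keep <- utils::head(ed, ceiling(fraction * nrow(ed)))
  lexical_network(keep[, c("word_a", "word_b")], nodes = igraph::V(net)$name)
}

#' Split semantic links into weak / medium / strong groups
#'
#' `"terciles"`: links sorted ascending by strength are cut into three
#' contiguous groups whose sizes differ by at most one (any remainder goes to
#' the weak end first, so 10 links give sizes 4, 3, 3). `"separated"`: three
#' equal groups of size `floor(|edges| / 5)` taken from the bottom, centre
#' and top of the sorted order, with the remaining links forming equal-size
#' gaps between them — a concrete reading of "maximally separable" strength
#' groups.
#'
#' @param net weighted lexical network with at least 3 edges.
#' @param mode grouping mode.
#' @return named list `weak`, `medium`, `strong` of edge tibbles
#'   (`word_a`, `word_b`, `weight`).
#' @export
strength_groups <- function(net, mode = c("terciles", "separated")) {
  mode <- match.arg(mode)
  ed <- sorted_semantic_edges(net)
  n <- nrow(ed)
  if (n < 3) stop("need at least 3 edges to form strength groups")
  if (mode == "terciles") {
    base <- n %/% 3L
    rem <- n %% 3L
    sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
    idx <- list(
      weak = seq_len(sizes[1]),
      medium = sizes[1] + seq_len(sizes[2]),
      strong = sizes[1] + sizes[2] + seq_len(sizes[3])
    )
  } else {
    gsize <- max(1L, n %/% 5L)
    mid_start <- (n - gsize) %/% 2L + 1L
    idx <- list(
      weak = seq_len(gsize),
      medium = seq(mid_start, length.out = gsize),
      strong = seq(n - gsize + 1L, length.out = gsize)
    )
  }
  lapply(idx, function(i) ed[i, , drop = FALSE])
}

#' Sort semantic links ascending and cut into equal-size strength windows
#'
#' Links are sorted ascending by strength (ties lexicographic) and split into
#' consecutive windows of `window_size` links; the last window may be
#' smaller. The study-scale window is 100,000 links; desk-scale presets use
#' around 1,000.
#'
#' @param net weighted lexical network.
#' @param window_size links per window (>= 1).
#' @return list of `strength_window` objects: each a list with `window_id`,
#'   `rank_range` (half-open `[lo, hi)` over the ascending sort) and `links`
#'   (edge tibble).
#' @export
sort_and_window <- function(net, window_size) {
  stopifnot(window_size >= 1)
  ed <- sorted_semantic_edges(net)
  n <- nrow(ed)
  if (n == 0) return(list())
  starts <- seq(1L, n, by = as.integer(window_size))
  lapply(seq_along(starts), function(k) {
    lo <- starts[k]
    hi <- min(lo + window_size - 1L, n)
    structure(
      list(
        window_id = sprintf("w%03d", k),
        rank_range = c(lo, hi + 1L),
        links = ed[seq(lo, hi), , drop = FALSE]
      ),
      class = "strength_window"
    )
  })
}

#' Write a weighted edge list TSV for a semantic network
#'
#' @param net weighted lexical network.
#' @param path file path.
#' @export
write_semantic_tsv <- function(net, path) write_edge_tsv(net, path)
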