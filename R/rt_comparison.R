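# Path length versus reaction times for word-pair relatedness judgments,
# with degree-matched network variants and edge-subsample replicates.

#' Read a reaction-time table
#'
#' TSV with columns `word_a<TAB>word_b<TAB>rt_ms`; pairs are unordered.
#'
#' @param path file path.
#' @return tibble with columns `word_a`, `word_b`, `rt_ms`.
#' @export
read_rt_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("word_a", "word_b", "rt_ms"),
                          comment.char = "#", fileEncoding = "UTF-8",
                          colClasses = c("character", "character", "numeric"))
  validate_rt_table(df)
}

validate_rt_table <- function(rts) {
  stopifnot(all(c("word_a", "word_b", "rt_ms") %in% names(rts)))
  tab <- tibble::as_tibble(rts)
  if (any(tab$rt_ms <= 0)) stop("rt_ms must be positive")
  a <- pmin(tab$word_a, tab$word_b)
  b <- pmax(tab$word_a, tab$word_b)
  tab$word_a <- a; tab$word_b <- b
  tab
}

#' Match a network to a target mean degree by seeded link addition
#'
#' Keeps a spanning connector over the network's own edges, then adds links
#' drawn from `candidate_links` until the mean degree is within `tol` of
#' `target_mean_degree` (used to align with the reference semantic network's
#' mean degree of 11.7 before RT comparison). If the network already matches
#' the target, it is returned unchanged. Additions are seeded-random; when
#' `origin` labels and `origin_fractions` are supplied (e.g. phonological
#' and semantic links at a 20%/80% ratio), per-origin quotas are honoured to
#' within one link.
#'
#' @param net lexical network.
#' @param target_mean_degree target mean degree.
#' @param candidate_links edge tibble to draw additions from.
#' @param seed integer seed.
#' @param origin optional character vector labelling each candidate link.
#' @param origin_fractions optional named numeric fractions per origin label
#'   (must sum to 1).
#' @param tol mean-degree tolerance (default 0.05; exact equality is
#'   unattainable with integer edge counts).
#' @return lexical network with mean degree within `tol` of the target; if
#'   `origin` was given, an edge attribute `origin` marks each edge's layer
#'   (`base` for the spanning connector).
#' @export
match_degree <- function(net, target_mean_degree, candidate_links, seed = 1L,
                         origin = NULL, origin_fractions = NULL, tol = 0.05) {
  n <- igraph::vcount(net)
  cur <- 2 * igraph::ecount(net) / n
  if (abs(cur - target_mean_degree) <= tol) return(net)
  if (cur > target_mean_degree) {
    stop("network mean degree ", round(cur, 3), " already above target ",
         target_mean_degree)
  }
  nodes <- igraph::V(net)$name
  cand <- tibble::as_tibble(candidate_links)
  cand <- cand[cand$word_a %in% nodes & cand$word_b %in% nodes, , drop = FALSE]
  if (!is.null(origin)) {
    origin <- origin[candidate_links$word_a %in% nodes & candidate_links$word_b %in% nodes]
    stopifnot(length(origin) == nrow(cand), !is.null(origin_fractions),
              abs(sum(origin_fractions) - 1) < 1e-8)
  }
  forest <- spanning_connector(nodes, network_edges(net), seed = seed)
  fk <- edge_keys(forest$word_a, forest$word_b)
  ck <- edge_keys(cand$word_a, cand$word_b)
  avail <- !ck %in% fk & !duplicated(ck)
  E_target <- round(target_mean_degree * n / 2)
  n_add <- E_target - nrow(forest)
  if (n_add < 0) stop("spanning connector alone exceeds the target degree")
  if (sum(avail) < n_add) {
    stop("candidates insufficient; achievable mean degree: ",
         round(2 * (nrow(forest) + sum(avail)) / n, 3))
  }
  if (is.null(origin)) {
    pick <- withr::with_seed(seed, sample(which(avail), n_add))
    add <- cand[pick, c("word_a", "word_b"), drop = FALSE]
    add_origin <- rep("candidate", n_add)
  } else {
    labs <- names(origin_fractions)
    quota <- floor(origin_fractions * n_add)
    rem <- n_add - sum(quota)
    if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1
    picks <- integer(0)
    sseeds <- spawn_seeds(seed, length(labs))
    for (li in seq_along(labs)) {
      pool <- which(avail & origin == labs[li])
      if (length(pool) < quota[li]) {
        stop("not enough '", labs[li], "' candidates: have ", length(pool),
             ", need ", quota[li])
      }
      picks <- c(picks, withr::with_seed(sseeds[li], sample(pool, quota[li])))
    }
    add <- cand[picks, c("word_a", "word_b"), drop = FALSE]
    add_origin <- origin[picks]
  }
  g <- lexical_network(rbind(forest, add), nodes = nodes)
  og <- c(rep("base", nrow(forest)), add_origin)
  # map origins onto the graph's canonical edge order
  gk <- edge_keys(network_edges(g)$word_a, network_edges(g)$word_b)
  ok <- edge_keys(c(forest$word_a, add$word_a), c(forest$word_b, add$word_b))
  igraph::E(g)$origin <- og[match(gk, ok)]
  g
}

#' Mean reaction time by network path length
#'
#' Buckets RT pairs by their shortest-path length in the network (lengths
#' `1..max_length`; longer or disconnected pairs are excluded, following the
#' finding that relatedness judgments are informative for path lengths 1-4)
#' and averages RT per length. The network may be rebuilt per iteration
#' (pass a `function(seed)` returning a network, as with degree-matched
#' variants rebuilt from different links); per-length means are then
#' averaged over iterations with the across-iteration standard deviation.
#' Each iteration buckets by its own network's path lengths.
#'
#' @param net lexical network, or `function(seed)` returning one.
#' @param rts RT table (`word_a`, `word_b`, `rt_ms`).
#' @param max_length largest path length retained (default 4).
#' @param n_network_iterations network rebuild iterations (default 5).
#' @param seed master seed.
#' @return tibble: `path_length`, `mean_rt`, `sd_rt` (across iterations),
#'   `n_pairs` (mean per iteration). Lengths with no pairs in any iteration
#'   are reported with `NA` means.
#' @export
rt_by_path_length <- function(net, rts, max_length = 4L,
                              n_network_iterations = 5L, seed = 1L) {
  rts <- validate_rt_table(rts)
  seeds <- spawn_seeds(seed, n_network_iterations)
  per_iter <- array(NA_real_, c(n_network_iterations, max_length))
  per_n <- array(0L, c(n_network_iterations, max_length))
  for (it in seq_len(n_network_iterations)) {
    g <- if (is.function(net)) net(seeds[it]) else net
    nm <- igraph::V(g)$name
    keep <- rts$word_a %in% nm & rts$word_b %in% nm
    sub <- rts[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    d <- igraph::distances(g, v = unique(sub$word_a), to = unique(sub$word_b),
                           weights = NA)
    L <- d[cbind(match(sub$word_a, rownames(d)), match(sub$word_b, colnames(d)))]
    for (k in seq_len(max_length)) {
      sel <- is.finite(L) & L == k
      per_n[it, k] <- sum(sel)
      if (any(sel)) per_iter[it, k] <- mean(sub$rt_ms[sel])
    }
  }
  tibble::tibble(
    path_length = seq_len(max_length),
    mean_rt = vapply(seq_len(max_length), function(k) {
      v <- per_iter[, k]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    sd_rt = vapply(seq_len(max_length), function(k) {
      v <- per_iter[, k]
      if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE)
    }, numeric(1)),
    n_pairs = colMeans(per_n)
  )
}

#' Seeded edge-subsample replicates of a network
#'
#' Draws `n_replicates` networks, each retaining `floor(keep_fraction * E)`
#' uniformly sampled edges (used to build a distribution of networks from a
#' reference network provided after construction: the study keeps 50% of
#' links, ten times).
#'
#' @param net lexical network.
#' @param keep_fraction fraction of edges kept, in (0, 1].
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @return list of lexical networks (node set preserved).
#' @export
subsample_network_replicates <- function(net, keep_fraction, n_replicates = 10L,
                                         seed = 1L) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1, n_replicates >= 1)
  ed <- network_edges(net)
  m_keep <- floor(keep_fraction * nrow(ed))
  seeds <- spawn_seeds(seed, n_replicates)
  lapply(seeds, function(s) {
    pick <- withr::with_seed(s, sample.int(nrow(ed), m_keep))
    lexical_network(ed[pick, , drop = FALSE], nodes = igraph::V(net)$name)
  })
}
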