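# Distance reduction from adding non-overlapping links of one layer to the
# other, versus adding random non-existing links; includes the Ratio of Path
# Shortening (RPS).

#' Non-overlapping links of one layer with respect to another
#'
#' Edges of `source` whose endpoints both exist in `target` but which are
#' not edges of `target` — pairs connected in exactly one layer.
#'
#' @param source,target lexical networks sharing at least two nodes.
#' @return tibble of edges (`word_a`, `word_b`, plus `weight` if `source`
#'   is weighted).
#' @export
nonoverlapping_links <- function(source, target) {
  shared <- intersect(igraph::V(source)$name, igraph::V(target)$name)
  if (length(shared) < 2) stop("layers share fewer than two nodes")
  se <- network_edges(source)
  te <- network_edges(target)
  keep <- se$word_a %in% shared & se$word_b %in% shared &
    !edge_keys(se$word_a, se$word_b) %in% edge_keys(te$word_a, te$word_b)
  se[keep, , drop = FALSE]
}

#' Measure the distance reduction caused by adding links
#'
#' Computes all-pairs hop distances before and after adding `added` to
#' `target`. `total_reduction` sums `d_before - d_after` over pairs with
#' finite before-distance (indirect reductions, via new paths through added
#' links, are therefore included). `direct_reduction_counts[k]` counts the
#' pairs at original distance `k >= 2` whose distance dropped to 1, i.e.
#' the pairs that themselves received an added link.
#'
#' @param target lexical network.
#' @param added data frame of edges to add; endpoints must be nodes of
#'   `target` and the edges must be absent from it.
#' @return list with `total_reduction`, `direct_reduction_counts` (named
#'   integer vector keyed by original distance), `n_links_added`.
#' @export
measure_reduction <- function(target, added) {
  nm <- igraph::V(target)$name
  if (nrow(added)) {
    miss <- setdiff(c(added$word_a, added$word_b), nm)
    if (length(miss)) stop("added edge endpoint(s) not in target: ", paste(miss, collapse = ", "))
    te <- network_edges(target)
    dupe <- edge_keys(added$word_a, added$word_b) %in% edge_keys(te$word_a, te$word_b)
    if (any(dupe)) stop("added edge(s) already present in target")
  }
  d0 <- igraph::distances(target, weights = NA)
  g1 <- igraph::add_edges(target, rbind(match(added$word_a, nm), match(added$word_b, nm)))
  d1 <- igraph::distances(g1, weights = NA)
  ut <- upper.tri(d0)
  before <- d0[ut]; after <- d1[ut]
  fin <- is.finite(before)
  total <- sum(pmax(0, before[fin] - after[fin]))
  direct <- before[fin][after[fin] == 1 & before[fin] > 1]
  counts <- table(direct)
  list(
    total_reduction = total,
    direct_reduction_counts = setNames(as.integer(counts), names(counts)),
    n_links_added = nrow(added)
  )
}

# shared Monte-Carlo core for the link-addition experiments: per iteration,
# one random-addition baseline run and one run per link class
run_link_addition <- function(target, link_classes, n_add, n_iterations, seed) {
  stopifnot(n_add >= 1, n_iterations >= 1)
  nm <- igraph::V(target)$name
  n <- length(nm)
  te <- network_edges(target)
  existing <- edge_keys(te$word_a, te$word_b)
  class_keys <- unlist(lapply(link_classes, function(cl) edge_keys(cl$word_a, cl$word_b)),
                       use.names = FALSE)
  forbidden <- unique(c(existing, class_keys))
  n_free <- n * (n - 1) / 2 - length(unique(forbidden))
  if (n_free < n_add) {
    stop("not enough absent pairs outside the link classes to add ", n_add,
         " random links (", n_free, " available)")
  }
  short <- vapply(link_classes, nrow, integer(1)) < n_add
  if (any(short)) {
    stop("link class(es) smaller than n_add: ",
         paste(names(link_classes)[short], collapse = ", "))
  }

  draw_random_absent <- function(s) {
    # rejection sampling from the theoretical fully connected layer,
    # excluding existing edges and all class links
    out_a <- integer(0); out_b <- integer(0)
    withr::with_seed(s, {
      while (length(out_a) < n_add) {
        need <- n_add - length(out_a)
        i <- sample.int(n, 4 * need + 20, replace = TRUE)
        j <- sample.int(n, 4 * need + 20, replace = TRUE)
        ok <- i < j
        i <- i[ok]; j <- j[ok]
        key <- edge_keys(nm[i], nm[j])
        ok <- !key %in% forbidden & !duplicated(key) &
          !key %in% edge_keys(nm[out_a], nm[out_b])
        out_a <- c(out_a, i[ok]); out_b <- c(out_b, j[ok])
      }
    })
    data.frame(word_a = nm[out_a[seq_len(n_add)]], word_b = nm[out_b[seq_len(n_add)]])
  }

  seeds <- spawn_seeds(seed, n_iterations)
  iter_rows <- list()
  direct_acc <- list()
  rand_total <- numeric(n_iterations)
  rand_direct <- list()
  for (it in seq_len(n_iterations)) {
    sub <- spawn_seeds(seeds[it], length(link_classes) + 1L)
    rr <- measure_reduction(target, draw_random_absent(sub[1]))
    rand_total[it] <- rr$total_reduction
    rand_direct[[it]] <- rr$direct_reduction_counts
    for (ci in seq_along(link_classes)) {
      cl <- link_classes[[ci]]
      pick <- withr::with_seed(sub[ci + 1L], sample.int(nrow(cl), n_add))
      mr <- measure_reduction(target, cl[pick, c("word_a", "word_b"), drop = FALSE])
      iter_rows[[length(iter_rows) + 1L]] <- tibble::tibble(
        class = names(link_classes)[ci], iteration = it,
        total_reduction = mr$total_reduction
      )
      direct_acc[[length(direct_acc) + 1L]] <-
        tibble::tibble(class = names(link_classes)[ci], iteration = it,
                       original_distance = as.integer(names(mr$direct_reduction_counts)),
                       count = unname(mr$direct_reduction_counts))
    }
  }
  list(
    per_iteration = dplyr::bind_rows(iter_rows),
    direct = dplyr::bind_rows(direct_acc),
    random_total = rand_total,
    random_direct = dplyr::bind_rows(lapply(seq_len(n_iterations), function(it) {
      dc <- rand_direct[[it]]
      if (!length(dc)) return(NULL)
      tibble::tibble(iteration = it,
                     original_distance = as.integer(names(dc)),
                     count = unname(dc))
    }))
  )
}

#' Distance-reduction ratio of class link addition versus random addition
#'
#' Per iteration and link class, adds `n_add` sampled class links to
#' `target`, measures the total distance reduction, and normalises by the
#' mean total reduction of adding `n_add` uniformly random absent pairs
#' (drawn from the theoretical fully connected layer, excluding existing
#' edges and all class links; the baseline mean is pooled over the same
#' number of random iterations). A ratio near 1 means the class adds no more
#' shortening than chance.
#'
#' @param target lexical network receiving the links (for the forward
#'   analysis: the top-fraction filtered unweighted semantic layer).
#' @param link_classes named list of edge tibbles (e.g. phonological
#'   distance classes 1-6 restricted to non-overlapping links, or semantic
#'   strength groups); each must hold at least `n_add` links.
#' @param n_add links added per iteration. The study adds half the
#'   non-overlapping phonological links (4,439) to the semantic layer, and
#'   scales the reverse direction proportionally
#'   (`round(|target edges| * 4439 / 100000)`, giving roughly 800).
#' @param n_iterations Monte-Carlo iterations (study scale: 100).
#' @param seed master seed.
#' @return tibble: `class`, `iteration`, `total_reduction`, `ratio`.
#' @export
reduction_ratio_experiment <- function(target, link_classes, n_add,
                                       n_iterations = 25L, seed = 1L) {
  runs <- run_link_addition(target, link_classes, n_add, n_iterations, seed)
  base <- mean(runs$random_total)
  out <- runs$per_iteration
  out$ratio <- if (base > 0) out$total_reduction / base else NA_real_
  out
}

#' Proportional link budget for the reverse (semantic-to-phonological) run
#'
#' @param target lexical network receiving the links.
#' @return `round(|target edges| * 4439 / 100000)`, at least 1.
#' @export
proportional_n_add <- function(target) {
  max(1L, as.integer(round(igraph::ecount(target) * 4439 / 100000)))
}

#' Ratio of Path Shortening (RPS) table
#'
#' For each link class and original distance `k`, the mean count (over
#' iterations) of node pairs reduced from distance `k` directly to 1 by the
#' class additions, divided by the mean count under random additions. Cells
#' with a zero random denominator are flagged undefined (`defined = FALSE`).
#'
#' @inheritParams reduction_ratio_experiment
#' @return tibble: `class`, `original_distance`, `rps`, `defined`.
#' @export
rps_table <- function(target, link_classes, n_add, n_iterations = 25L, seed = 1L) {
  runs <- run_link_addition(target, link_classes, n_add, n_iterations, seed)
  all_k <- sort(unique(c(runs$direct$original_distance,
                         runs$random_direct$original_distance)))
  rand_mean <- vapply(all_k, function(k) {
    sum(runs$random_direct$count[runs$random_direct$original_distance == k]) / n_iterations
  }, numeric(1))
  names(rand_mean) <- as.character(all_k)
  rows <- list()
  for (cls in names(link_classes)) {
    dsub <- runs$direct[runs$direct$class == cls, , drop = FALSE]
    for (k in all_k) {
      num <- sum(dsub$count[dsub$original_distance == k]) / n_iterations
      den <- rand_mean[[as.character(k)]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = cls, original_distance = k,
        rps = if (den > 0) num / den else NA_real_,
        defined = den > 0
      )
    }
  }
  dplyr::bind_rows(rows)
}
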