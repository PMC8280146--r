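# Link overlap between the semantic and phonological layers, against nulls.
#
# Two complementary views: (i) per semantic-strength window, the ratio of
# the fraction of sampled semantic links lying at phonological distance d to
# the same fraction in a freshly shuffled phonological null (normalised by
# the number of distance-d links in each network); (ii) per phonological
# distance class, the fraction of sampled pairs that are weak / medium /
# strong semantic links, with a shuffled-semantic fourth series.

# distance-class sizes (counts of unordered pairs at exactly d) from a
# precomputed hop-count distance matrix
class_sizes_from_matrix <- function(d, distances) {
  ut <- d[upper.tri(d)]
  vapply(distances, function(k) sum(ut == k), numeric(1))
}

#' Phonological-overlap ratio per semantic strength window
#'
#' For each strength window and phonological distance `d`, samples
#' `sample_size` semantic links (restricted to pairs whose endpoints both lie
#' in the phonological network), measures the fraction at phonological
#' distance exactly `d` normalised by the number of distance-`d` pairs, and
#' divides by the same quantity measured against a freshly drawn null
#' phonological network per iteration. A ratio above 1 means semantic links
#' in that window co-occur with distance-`d` phonological proximity more
#' than chance.
#'
#' Per-iteration ratios are formed against the mean null fraction across
#' iterations (the ratio-of-averages convention); `ratio_mean`/`ratio_sd`
#' are their mean and standard deviation. Windows containing no pair present
#' in the phonological network are flagged `empty` rather than erroring.
#'
#' @param sem_windows list of strength windows from [sort_and_window()].
#' @param phono_net connected unweighted phonological network.
#' @param distances integer vector of phonological distance classes
#'   (default `1:3`).
#' @param sample_size semantic links sampled per iteration (capped at the
#'   number of eligible links in the window).
#' @param n_iterations Monte-Carlo iterations (study scale: 100).
#' @param seed master seed; spawns one seed per iteration.
#' @param null null model for the phonological layer: degree-preserving
#'   shuffle (default, retains every node's degree) or edge permutation.
#' @return tibble: `window_id`, `distance`, `ratio_mean`, `ratio_sd`,
#'   `n_iterations`, `sample_size`, `empty`.
#' @export
window_overlap_ratio <- function(sem_windows, phono_net, distances = 1:3,
                                 sample_size = 100L, n_iterations = 25L,
                                 seed = 1L,
                                 null = c("degree_preserving", "edge_permutation")) {
  null <- match.arg(null)
  stopifnot(n_iterations >= 1, sample_size >= 1)
  if (!igraph::is_connected(phono_net)) {
    stop("phonological network must be connected; apply giant_component() first")
  }
  nm <- igraph::V(phono_net)$name
  D <- igraph::distances(phono_net, weights = NA)
  obs_sizes <- class_sizes_from_matrix(D, distances)

  # per-window eligible pairs as vertex-index matrices
  win_pairs <- lapply(sem_windows, function(w) {
    lk <- w$links
    keep <- lk$word_a %in% nm & lk$word_b %in% nm
    cbind(match(lk$word_a[keep], nm), match(lk$word_b[keep], nm))
  })
  win_ids <- vapply(sem_windows, function(w) w$window_id, character(1))
  n_avail <- vapply(win_pairs, nrow, integer(1))

  seeds <- spawn_seeds(seed, n_iterations)
  nW <- length(sem_windows); nD <- length(distances)
  obs <- array(NA_real_, c(n_iterations, nW, nD))
  nul <- array(NA_real_, c(n_iterations, nW, nD))

  for (it in seq_len(n_iterations)) {
    sub <- spawn_seeds(seeds[it], 2L)
    null_net <- switch(null,
      degree_preserving = degree_preserving_shuffle(phono_net, seed = sub[1]),
      edge_permutation = edge_permutation_null(phono_net, seed = sub[1])
    )
    Dn <- igraph::distances(null_net, weights = NA)
    # align null matrix to observed vertex order
    Dn <- Dn[nm, nm]
    null_sizes <- class_sizes_from_matrix(Dn, distances)
    samp_seeds <- spawn_seeds(sub[2], max(nW, 1L))
    for (w in seq_len(nW)) {
      if (n_avail[w] == 0) next
      k <- min(sample_size, n_avail[w])
      idx <- withr::with_seed(samp_seeds[w], sample.int(n_avail[w], k))
      pr <- win_pairs[[w]][idx, , drop = FALSE]
      dv <- D[pr]
      dvn <- Dn[pr]
      for (j in seq_len(nD)) {
        d <- distances[j]
        obs[it, w, j] <- if (obs_sizes[j] > 0) mean(dv == d) / obs_sizes[j] else NA_real_
        nul[it, w, j] <- if (null_sizes[j] > 0) mean(dvn == d) / null_sizes[j] else NA_real_
      }
    }
  }

  res <- expand.grid(w = seq_len(nW), j = seq_len(nD))
  rows <- lapply(seq_len(nrow(res)), function(r) {
    w <- res$w[r]; j <- res$j[r]
    empty <- n_avail[w] == 0
    if (empty) {
      return(tibble::tibble(window_id = win_ids[w], distance = distances[j],
                            ratio_mean = NA_real_, ratio_sd = NA_real_,
                            n_iterations = n_iterations,
                            sample_size = 0L, empty = TRUE))
    }
    nullbar <- mean(nul[, w, j], na.rm = TRUE)
    ratio <- if (is.finite(nullbar) && nullbar > 0) obs[, w, j] / nullbar else rep(NA_real_, n_iterations)
    tibble::tibble(
      window_id = win_ids[w], distance = distances[j],
      ratio_mean = mean(ratio), ratio_sd = sd(ratio),
      n_iterations = n_iterations,
      sample_size = min(sample_size, n_avail[w]),
      empty = FALSE
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$window_id, .data$distance)
}

#' Semantic-overlap fraction per phonological distance class
#'
#' For each phonological distance class, samples `sample_size` pairs and
#' measures the fraction that are weak / medium / strong semantic links; a
#' fourth `random` series replaces the strength group with a shuffled
#' semantic edge set of matching size (permuting the semantic links destroys
#' any node-link relation while keeping node and edge counts).
#'
#' @param phono_classes named list of distance-class pair tibbles from
#'   [distance_class_pairs()]; each class must be nonempty.
#' @param sem_groups named list `weak`, `medium`, `strong` of edge tibbles
#'   from [strength_groups()]; empty groups are an error.
#' @param sample_size phonological pairs sampled per class per iteration
#'   (capped at the class size).
#' @param n_iterations Monte-Carlo iterations (study scale: 100).
#' @param seed master seed.
#' @param null null model for the shuffled-semantic series.
#' @return tibble: `distance`, `group` (weak/medium/strong/random),
#'   `frac_mean`, `frac_sd`, `n_iterations`, `sample_size`.
#' @export
distance_class_overlap <- function(phono_classes, sem_groups,
                                   sample_size = 50L, n_iterations = 25L,
                                   seed = 1L,
                                   null = c("edge_permutation", "degree_preserving")) {
  null <- match.arg(null)
  stopifnot(n_iterations >= 1, sample_size >= 1)
  if (any(vapply(sem_groups, nrow, integer(1)) == 0)) {
    stop("empty semantic strength group")
  }
  group_keys <- lapply(sem_groups, function(g) edge_keys(g$word_a, g$word_b))
  all_group_edges <- do.call(rbind, lapply(sem_groups, function(g) g[, c("word_a", "word_b")]))
  all_group_edges <- unique(all_group_edges)
  nodes <- sort(unique(c(all_group_edges$word_a, all_group_edges$word_b,
                         unlist(lapply(phono_classes, function(p) c(p$word_a, p$word_b))))))
  union_net <- lexical_network(all_group_edges, nodes = nodes)
  null_size <- round(mean(vapply(sem_groups, nrow, integer(1))))

  class_pairs <- lapply(phono_classes, function(p) {
    if (nrow(p) == 0) stop("empty phonological distance class")
    edge_keys(p$word_a, p$word_b)
  })
  dists <- as.integer(names(phono_classes))

  seeds <- spawn_seeds(seed, n_iterations)
  groups <- c(names(sem_groups), "random")
  acc <- array(NA_real_, c(n_iterations, length(dists), length(groups)))

  for (it in seq_len(n_iterations)) {
    sub <- spawn_seeds(seeds[it], 2L)
    # group-size shuffled semantic edge set
    null_keys <- if (null == "edge_permutation") {
      ed <- withr::with_seed(sub[1], {
        n <- length(nodes)
        m <- null_size
        picked <- sample.int(n * (n - 1) / 2, m)
        idx_to_pair(picked, n)
      })
      edge_keys(nodes[ed[, 1]], nodes[ed[, 2]])
    } else {
      shuf <- degree_preserving_shuffle(union_net, seed = sub[1])
      ed <- network_edges(shuf)
      keep <- withr::with_seed(sub[1] + 1L, sample.int(nrow(ed), min(null_size, nrow(ed))))
      edge_keys(ed$word_a[keep], ed$word_b[keep])
    }
    samp_seeds <- spawn_seeds(sub[2], length(dists))
    for (di in seq_along(dists)) {
      keys <- class_pairs[[di]]
      k <- min(sample_size, length(keys))
      pick <- withr::with_seed(samp_seeds[di], sample(keys, k))
      for (gi in seq_along(sem_groups)) {
        acc[it, di, gi] <- mean(pick %in% group_keys[[gi]])
      }
      acc[it, di, length(groups)] <- mean(pick %in% null_keys)
    }
  }

  res <- expand.grid(di = seq_along(dists), gi = seq_along(groups))
  rows <- lapply(seq_len(nrow(res)), function(r) {
    di <- res$di[r]; gi <- res$gi[r]
    tibble::tibble(
      distance = dists[di], group = groups[gi],
      frac_mean = mean(acc[, di, gi]), frac_sd = sd(acc[, di, gi]),
      n_iterations = n_iterations,
      sample_size = min(sample_size, length(class_pairs[[di]]))
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$distance, .data$group)
}

# map linear indices over the upper triangle (column-major over unordered
# pairs 1 <= i < j <= n) back to (i, j) pairs
idx_to_pair <- function(idx, n) {
  # pair t-th with i < j; enumerate j from 2..n, i from 1..j-1
  cum <- cumsum(seq_len(n - 1))
  j <- findInterval(idx - 1L, cum) + 2L
  i <- idx - c(0, cum)[j - 1L]
  cbind(i, j)
}
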