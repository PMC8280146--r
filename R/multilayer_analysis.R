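# Degree-matched semantic / phonological / multilayer / random quadruples,
# distance sweeps over semantic-strength windows, Louvain communities and
# inter-link fractions, and the semantic-fraction sweep.

#' Merge two layers into a multilayer network
#'
#' Union graph over the union of node sets; every edge is tagged with its
#' layer of origin (`semantic`, `phonological`, or `both` when present in
#' both layers).
#'
#' @param sem,phono lexical networks.
#' @return unweighted lexical network with edge attribute `origin`.
#' @export
multilayer_merge <- function(sem, phono) {
  se <- network_edges(sem)[, c("word_a", "word_b")]
  pe <- network_edges(phono)[, c("word_a", "word_b")]
  sk <- edge_keys(se$word_a, se$word_b)
  pk <- edge_keys(pe$word_a, pe$word_b)
  all_e <- unique(rbind(se, pe))
  ak <- edge_keys(all_e$word_a, all_e$word_b)
  origin <- ifelse(ak %in% sk & ak %in% pk, "both",
                   ifelse(ak %in% sk, "semantic", "phonological"))
  nodes <- sort(union(igraph::V(sem)$name, igraph::V(phono)$name))
  g <- lexical_network(all_e, nodes = nodes)
  igraph::E(g)$origin <- origin
  g
}

# semantic candidate edges among `nodes`, strongest first
ranked_semantic_edges <- function(sem, nodes) {
  ed <- sorted_semantic_edges(sem, decreasing = TRUE)
  ed[ed$word_a %in% nodes & ed$word_b %in% nodes, , drop = FALSE]
}

# grow an edge list to `target_m` edges by walking `pool` in order,
# skipping edges already present
top_up <- function(current_keys, pool, target_m) {
  take <- integer(0)
  keys <- current_keys
  pk <- edge_keys(pool$word_a, pool$word_b)
  for (i in seq_len(nrow(pool))) {
    if (length(keys) >= target_m) break
    if (!pk[i] %in% keys) {
      take <- c(take, i)
      keys <- c(keys, pk[i])
    }
  }
  pool[take, c("word_a", "word_b"), drop = FALSE]
}

#' Build a degree-matched semantic / phonological / multilayer / random quadruple
#'
#' All four networks share one node set (the phonological giant component
#' restricted to words also present in the semantic layer) and the same edge
#' count, hence the same mean degree. The semantic member starts from a
#' spanning connector over the shared nodes (preferring stronger links) and
#' fills up with the strongest links from the requested strength window,
#' walking towards weaker links as needed. The multilayer member merges the
#' semantic and phonological members, prunes to a spanning connector, then
#' refills alternately with the strongest remaining semantic link and a
#' seeded-random phonological link until the target edge count, so its
#' composition is close to half/half. The random member redraws all edges
#' uniformly (edge permutation).
#'
#' @param sem weighted semantic lexical network.
#' @param phono unweighted phonological lexical network.
#' @param window_start fraction in `[0, 1)` of strongest semantic links
#'   skipped before filling: 0 fills from the very strongest links; 0.1
#'   starts at the 90th strength percentile.
#' @param seed integer seed.
#' @return object of class `matched_quadruple`: list with `semantic`,
#'   `phonological`, `multilayer`, `random` networks plus `window_start`,
#'   `n_nodes`, `n_edges`.
#' @export
build_matched_quadruple <- function(sem, phono, window_start = 0, seed = 1L) {
  stopifnot(window_start >= 0, window_start < 1)
  phono_g <- giant_component(phono)
  shared <- intersect(igraph::V(phono_g)$name, igraph::V(sem)$name)
  if (length(shared) < 3) stop("layers share fewer than three nodes")
  P <- igraph::induced_subgraph(phono_g, shared)
  m_target <- igraph::ecount(P)
  seeds <- spawn_seeds(seed, 4L)

  cand <- ranked_semantic_edges(sem, shared)
  if (nrow(cand) < m_target) {
    stop("insufficient semantic links among shared nodes: have ", nrow(cand),
         ", need ", m_target)
  }
  # semantic member: connector from all candidates, then strongest window links
  forest <- spanning_connector(shared, cand, seed = seeds[1])
  fkeys <- edge_keys(forest$word_a, forest$word_b)
  start_idx <- min(nrow(cand), floor(window_start * nrow(cand)) + 1L)
  pool <- cand[seq(start_idx, nrow(cand)), , drop = FALSE]
  if (start_idx > 1L) {
    # wrap round to stronger links if the tail cannot reach the target
    pool <- rbind(pool, cand[seq_len(start_idx - 1L), , drop = FALSE])
  }
  fill <- top_up(fkeys, pool, m_target)
  if (length(fkeys) + nrow(fill) < m_target) {
    stop("cannot reach ", m_target, " semantic links; achievable: ",
         length(fkeys) + nrow(fill))
  }
  S <- lexical_network(rbind(forest, fill[, c("word_a", "word_b")]), nodes = shared)

  # multilayer member: merge, prune to connector, refill half/half
  Mfull <- multilayer_merge(S, P)
  med <- network_edges(Mfull)
  med$origin <- igraph::E(Mfull)$origin
  mforest <- spanning_connector(shared, med[, c("word_a", "word_b")], seed = seeds[2])
  mkeys <- edge_keys(mforest$word_a, mforest$word_b)
  sem_pool <- med[med$origin %in% c("semantic", "both"), c("word_a", "word_b")]
  ph_pool <- med[med$origin %in% c("phonological", "both"), c("word_a", "word_b")]
  # semantic pool ordered strongest-first; phonological pool seeded-random
  spk <- edge_keys(sem_pool$word_a, sem_pool$word_b)
  ck <- edge_keys(cand$word_a, cand$word_b)
  sem_pool <- sem_pool[order(match(spk, ck)), , drop = FALSE]
  ph_pool <- ph_pool[withr::with_seed(seeds[3], sample.int(nrow(ph_pool))), , drop = FALSE]
  m_edges <- mforest
  si <- 1L; pi <- 1L; turn_sem <- TRUE
  while (nrow(m_edges) < m_target && (si <= nrow(sem_pool) || pi <= nrow(ph_pool))) {
    added <- FALSE
    if (turn_sem) {
      while (si <= nrow(sem_pool)) {
        k <- edge_keys(sem_pool$word_a[si], sem_pool$word_b[si])
        si <- si + 1L
        if (!k %in% mkeys) {
          m_edges <- rbind(m_edges, sem_pool[si - 1L, , drop = FALSE])
          mkeys <- c(mkeys, k); added <- TRUE; break
        }
      }
    } else {
      while (pi <= nrow(ph_pool)) {
        k <- edge_keys(ph_pool$word_a[pi], ph_pool$word_b[pi])
        pi <- pi + 1L
        if (!k %in% mkeys) {
          m_edges <- rbind(m_edges, ph_pool[pi - 1L, , drop = FALSE])
          mkeys <- c(mkeys, k); added <- TRUE; break
        }
      }
    }
    turn_sem <- !turn_sem
  }
  M <- lexical_network(m_edges, nodes = shared)
  R <- edge_permutation_null(M, seed = seeds[4])

  structure(
    list(semantic = S, phonological = P, multilayer = M, random = R,
         window_start = window_start, n_nodes = length(shared),
         n_edges = m_target),
    class = "matched_quadruple"
  )
}

#' @export
print.matched_quadruple <- function(x, ...) {
  cat("Degree-matched quadruple:", x$n_nodes, "nodes,", x$n_edges,
      "edges per network; window start", x$window_start, "\n")
  invisible(x)
}

#' Mean-distance sweep over semantic strength windows
#'
#' Builds a matched quadruple for each window start from the strongest links
#' downward and records the four mean distances. The phonological member
#' does not depend on the window, so its value is constant across rows.
#'
#' @inheritParams build_matched_quadruple
#' @param percentile_resolution step between window starts (the study uses
#'   0.005, i.e. half a percent).
#' @param max_start last window start (study: 0.1, the 90th percentile).
#' @param policy disconnected-pair policy for [mean_distance_summary()].
#' @return tibble: `window_start`, `network`, `mean_distance`, `n_pairs_used`.
#' @export
distance_sweep <- function(sem, phono, percentile_resolution = 0.005,
                           seed = 1L, max_start = 0.1,
                           policy = "exclude") {
  stopifnot(percentile_resolution > 0, percentile_resolution < 1)
  starts <- seq(0, max_start, by = percentile_resolution)
  seeds <- spawn_seeds(seed, length(starts))
  rows <- lapply(seq_along(starts), function(i) {
    quad <- build_matched_quadruple(sem, phono, window_start = starts[i],
                                    seed = seeds[i])
    dplyr::bind_rows(lapply(c("semantic", "phonological", "multilayer", "random"),
                            function(nw) {
      ms <- mean_distance_summary(quad[[nw]], policy = policy, label = nw)
      tibble::tibble(window_start = starts[i], network = nw,
                     mean_distance = ms$mean_distance,
                     n_pairs_used = ms$n_pairs_used)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Louvain community detection
#'
#' Runs the Louvain modularity-maximisation procedure at resolution `gamma`
#' (the study uses `gamma = 1`). Louvain is order-dependent, so the
#' algorithm is restarted `n_restarts` times under seeded vertex
#' permutations and the highest-modularity partition is kept.
#'
#' @param net connected lexical network.
#' @param gamma resolution parameter.
#' @param seed master seed.
#' @param n_restarts restarts (default 5).
#' @return object of class `community_partition`: list with `assignment`
#'   (named integer vector, one community id per node), `gamma`,
#'   `modularity`.
#' @export
detect_communities <- function(net, gamma = 1, seed = 1L, n_restarts = 5L) {
  if (igraph::vcount(net) == 0) stop("empty network")
  seeds <- spawn_seeds(seed, n_restarts)
  best <- NULL
  for (s in seeds) {
    res <- withr::with_seed(s, {
      perm <- sample.int(igraph::vcount(net))
      g2 <- igraph::permute(net, perm)
      igraph::cluster_louvain(g2, weights = NA, resolution = gamma)
    })
    q <- max(res$modularity)
    if (is.null(best) || q > best$modularity) {
      memb <- igraph::membership(res)
      best <- list(assignment = setNames(as.integer(memb), names(memb)),
                   gamma = gamma, modularity = q)
    }
  }
  # stable order and ids
  best$assignment <- best$assignment[order(names(best$assignment))]
  structure(best, class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Louvain partition: ", length(unique(x$assignment)), " communities over ",
      length(x$assignment), " nodes (gamma = ", x$gamma,
      ", modularity = ", round(x$modularity, 4), ")\n", sep = "")
  invisible(x)
}

#' Fraction of inter-community links
#'
#' Share of edges whose endpoints fall in different communities of a
#' partition. For a uniformly random edge set this converges to
#' `1 - sum((n_c / n)^2)` as the number of edges grows.
#'
#' @param partition a `community_partition` (or named community id vector).
#' @param edges nonempty edge data frame (`word_a`, `word_b`), all endpoints
#'   assigned in the partition.
#' @return number in `[0, 1]`.
#' @export
interlink_fraction <- function(partition, edges) {
  assignment <- if (inherits(partition, "community_partition")) partition$assignment else partition
  if (nrow(edges) == 0) stop("empty edge set")
  miss <- setdiff(c(edges$word_a, edges$word_b), names(assignment))
  if (length(miss)) stop("unassigned endpoint(s): ", paste(unique(miss), collapse = ", "))
  mean(assignment[edges$word_a] != assignment[edges$word_b])
}

#' Mean multilayer distance as a function of the semantic link fraction
#'
#' For each semantic fraction `f`, builds a multilayer network with
#' `floor(f * E)` semantic and `E - floor(f * E)` phonological links at a
#' fixed total edge count `E` (spanning connector over the union candidates
#' first, then a seeded top-up per layer: strongest-first for semantic
#' links, random for phonological), and records its mean distance. The
#' study sweeps fractions 0.2 to 0.76. Unrealizable fractions (the
#' connector alone overshoots a layer budget, or a layer pool is too small)
#' are skipped with a warning.
#'
#' @param sem_window_edges semantic candidate edge tibble (`word_a`,
#'   `word_b`, optional `weight` used for strongest-first ordering),
#'   typically one strength window or a top-percentile filter.
#' @param phono unweighted phonological lexical network (already restricted
#'   to the shared giant component); its edge count sets the total `E`.
#' @param fractions numeric vector of semantic link fractions in (0, 1).
#' @param seed integer seed.
#' @param policy disconnected-pair policy for the distance summary.
#' @return tibble: `fraction`, `mean_distance`, `n_semantic`,
#'   `n_phonological` (skipped fractions are absent).
#' @export
fraction_sweep <- function(sem_window_edges, phono, fractions, seed = 1L,
                           policy = "exclude") {
  stopifnot(all(fractions > 0), all(fractions < 1))
  nodes <- igraph::V(phono)$name
  pe <- network_edges(phono)[, c("word_a", "word_b")]
  se <- tibble::as_tibble(sem_window_edges)
  se <- se[se$word_a %in% nodes & se$word_b %in% nodes, , drop = FALSE]
  if ("weight" %in% names(se)) {
    se <- se[order(-se$weight, se$word_a, se$word_b), , drop = FALSE]
  }
  E_target <- nrow(pe)
  pk <- edge_keys(pe$word_a, pe$word_b)
  sk <- edge_keys(se$word_a, se$word_b)
  seeds <- spawn_seeds(seed, 2L * length(fractions))
  union_cand <- unique(rbind(se[, c("word_a", "word_b")], pe))
  uk <- edge_keys(union_cand$word_a, union_cand$word_b)

  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    n_sem <- floor(f * E_target)
    n_ph <- E_target - n_sem
    # connector biased towards the requested mixture: edges of the layer
    # with the larger budget get lower cost, so the forest composition
    # tracks the fraction instead of exhausting one layer's budget
    cost <- ifelse(uk %in% sk & !uk %in% pk, 1 + (1 - f),
                   ifelse(uk %in% pk & !uk %in% sk, 1 + f, 1))
    forest <- spanning_connector(nodes, cbind(union_cand, weight = max(cost) - cost + 1),
                                 seed = seeds[2L * i - 1L])
    fk <- edge_keys(forest$word_a, forest$word_b)
    f_sem <- fk %in% sk & !fk %in% pk
    f_ph <- fk %in% pk & !fk %in% sk
    f_flex <- fk %in% pk & fk %in% sk
    # assign flexible forest edges to whichever budget has room
    base_sem <- sum(f_sem); base_ph <- sum(f_ph)
    flex <- sum(f_flex)
    give_sem <- min(flex, max(0, n_sem - base_sem))
    base_sem <- base_sem + give_sem
    base_ph <- base_ph + (flex - give_sem)
    if (base_sem > n_sem || base_ph > n_ph) {
      warning("fraction ", f, " unrealizable with the spanning connector; skipped")
      next
    }
    sem_add <- top_up(fk, se[!sk %in% fk, , drop = FALSE], length(fk) + (n_sem - base_sem))
    ph_rest <- pe[!pk %in% fk & !pk %in% edge_keys(sem_add$word_a, sem_add$word_b), , drop = FALSE]
    if (nrow(sem_add) < n_sem - base_sem || nrow(ph_rest) < n_ph - base_ph) {
      warning("fraction ", f, " unrealizable: layer pool too small; skipped")
      next
    }
    ph_add <- ph_rest[withr::with_seed(seeds[2L * i], sample.int(nrow(ph_rest), n_ph - base_ph)), ,
                      drop = FALSE]
    g <- lexical_network(rbind(forest,
                               sem_add[, c("word_a", "word_b")],
                               ph_add[, c("word_a", "word_b")]),
                         nodes = nodes)
    ms <- mean_distance_summary(g, policy = policy, label = sprintf("f=%.2f", f))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fraction = f, mean_distance = ms$mean_distance,
      n_semantic = base_sem + nrow(sem_add) - 0L, n_phonological = base_ph + nrow(ph_add)
    )
  }
  dplyr::bind_rows(rows)
}
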