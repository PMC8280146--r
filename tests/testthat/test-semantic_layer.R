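toy_table <- function() {
  tibble::tibble(
    cue = c("A", "A", "B", "B"),
    response = c("x", "y", "x", "y"),
    participant_count = c(3L, 1L, 2L, 5L)
  )
}

test_that("link_strength sums per-response minima above the shared-participant filter", {
  tab <- toy_table()
  # min(3,2)=2 kept; min(1,5)=1 filtered by the >1-participant rule
  expect_equal(link_strength(tab, "A", "B"), 2)
  expect_equal(link_strength(tab, "A", "B", min_shared_participants = 1), 3)

  disjoint <- tibble::tibble(cue = c("A", "B"), response = c("p", "q"),
                             participant_count = c(5L, 5L))
  expect_equal(link_strength(disjoint, "A", "B"), 0)

  one <- tibble::tibble(cue = c("A", "B"), response = c("x", "x"),
                        participant_count = c(4L, 4L))
  expect_equal(link_strength(one, "A", "B"), 4)

  expect_error(link_strength(tab, "A", "nope"), "nope")
  expect_error(link_strength(tab, "A", "A"), "distinct")
})

test_that("link_strength is symmetric, bounded by cue totals, and matches the double-loop oracle", {
  for (s in 1:25) {
    tab <- rand_assoc_table(seed = s)
    cues <- unique(tab$cue)
    pair <- withr::with_seed(s, sample(cues, 2))
    ls <- link_strength(tab, pair[1], pair[2])
    expect_equal(ls, link_strength(tab, pair[2], pair[1]))
    expect_equal(ls, bf_link_strength(tab, pair[1], pair[2]))
    expect_lte(ls, min(sum(tab$participant_count[tab$cue == pair[1]]),
                       sum(tab$participant_count[tab$cue == pair[2]])))
  }
})

test_that("build_semantic_network matches the oracle edgewise and is monotone in the filter", {
  for (s in 1:15) {
    tab <- rand_assoc_table(seed = s + 200)
    cues <- sort(unique(tab$cue))
    if (length(cues) < 2) next
    net <- build_semantic_network(tab)
    ed <- network_edges(net)
    got <- if (nrow(ed)) setNames(ed$weight, paste(ed$word_a, ed$word_b)) else numeric()
    pairs <- t(combn(cues, 2))
    for (r in seq_len(nrow(pairs))) {
      expected <- bf_link_strength(tab, pairs[r, 1], pairs[r, 2])
      key <- paste(pairs[r, 1], pairs[r, 2])
      if (expected > 0) {
        expect_equal(unname(got[key]), expected)
      } else {
        expect_false(key %in% names(got))
      }
    }
    # looser filter never removes weight
    net1 <- build_semantic_network(tab, min_shared_participants = 1)
    ed1 <- network_edges(net1)
    if (nrow(ed)) {
      w1 <- setNames(ed1$weight, paste(ed1$word_a, ed1$word_b))
      expect_true(all(paste(ed$word_a, ed$word_b) %in% names(w1)))
      expect_true(all(w1[paste(ed$word_a, ed$word_b)] >= ed$weight))
    }
  }
})

test_that("semantic nodes are cues only; non-cue responses contribute weight anonymously", {
  tab <- tibble::tibble(cue = c("A", "B"), response = c("shared", "shared"),
                        participant_count = c(3L, 2L))
  net <- build_semantic_network(tab)
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(network_edges(net)$weight, 2)
  expect_error(build_semantic_network(tab[1, ]), "two cues")
})

test_that("filter_top_fraction keeps the strongest ceiling(f*E) edges, unweighted", {
  withr::with_seed(3, {
    nodes <- sprintf("w%03d", 1:40)
    prs <- t(combn(nodes, 2))
    pick <- sample(nrow(prs), 200)
    ed <- data.frame(word_a = prs[pick, 1], word_b = prs[pick, 2],
                     weight = sample(1000, 200))
  })
  net <- lexical_network(ed)
  top <- filter_top_fraction(net, 0.01)
  expect_equal(igraph::ecount(top), 2)
  expect_false("weight" %in% igraph::edge_attr_names(top))
  expect_setequal(paste(network_edges(top)$word_a, network_edges(top)$word_b),
                  paste(ed$word_a, ed$word_b)[order(-ed$weight)[1:2]])

  all_of_it <- filter_top_fraction(net, 1.0)
  expect_equal(igraph::ecount(all_of_it), 200)
  expect_error(filter_top_fraction(net, 0), "fraction")
  expect_error(filter_top_fraction(net, 1.2), "fraction")

  # monotone: smaller fraction's edges are a subset of a larger fraction's
  k1 <- network_edges(filter_top_fraction(net, 0.10))
  k2 <- network_edges(filter_top_fraction(net, 0.25))
  expect_true(all(paste(k1$word_a, k1$word_b) %in% paste(k2$word_a, k2$word_b)))
})

test_that("filter_top_fraction resolves boundary ties deterministically", {
  ed <- data.frame(word_a = c("a", "b", "c", "d"), word_b = c("b", "c", "d", "e"),
                   weight = c(5, 4, 4, 1))
  net <- lexical_network(ed)
  kept <- network_edges(filter_top_fraction(net, 0.5))
  expect_equal(nrow(kept), 2)
  expect_true("a b" %in% paste(kept$word_a, kept$word_b))  # the weight-5 edge
  # second kept edge is one of the weight-4 tie pair, and the same every time
  expect_identical(kept, network_edges(filter_top_fraction(net, 0.5)))
})

test_that("strength_groups cuts sorted links into weak/medium/strong", {
  mk <- function(n) {
    lexical_network(data.frame(word_a = sprintf("a%02d", 1:n),
                               word_b = sprintf("b%02d", 1:n), weight = seq_len(n)))
  }
  g9 <- strength_groups(mk(9), "terciles")
  expect_equal(vapply(g9, nrow, integer(1)), c(weak = 3L, medium = 3L, strong = 3L))
  expect_lte(max(g9$weak$weight), min(g9$medium$weight))
  expect_lte(max(g9$medium$weight), min(g9$strong$weight))

  g10 <- strength_groups(mk(10), "terciles")
  expect_equal(unname(vapply(g10, nrow, integer(1))), c(4L, 3L, 3L))

  s10 <- strength_groups(mk(10), "separated")
  expect_equal(unname(vapply(s10, nrow, integer(1))), c(2L, 2L, 2L))
  expect_equal(s10$weak$weight, 1:2)
  expect_equal(s10$medium$weight, 5:6)
  expect_equal(s10$strong$weight, 9:10)

  expect_error(strength_groups(mk(2), "terciles"), "3 edges")
})

test_that("sort_and_window yields ascending, disjoint, covering windows", {
  withr::with_seed(8, {
    nodes <- sprintf("w%03d", 1:60)
    prs <- t(combn(nodes, 2))
    pick <- sample(nrow(prs), 250)
    ed <- data.frame(word_a = prs[pick, 1], word_b = prs[pick, 2],
                     weight = sample(10000, 250))
  })
  net <- lexical_network(ed)
  wins <- sort_and_window(net, 100)
  expect_equal(vapply(wins, function(w) nrow(w$links), integer(1)), c(100L, 100L, 50L))
  expect_equal(vapply(wins, function(w) w$window_id, character(1)), c("w001", "w002", "w003"))
  # strictly increasing strengths here, so window maxima precede next minima
  expect_lt(max(wins[[1]]$links$weight), min(wins[[2]]$links$weight))
  expect_lt(max(wins[[2]]$links$weight), min(wins[[3]]$links$weight))
  keys <- unlist(lapply(wins, function(w) paste(w$links$word_a, w$links$word_b)))
  expect_equal(anyDuplicated(keys), 0L)
  expect_setequal(keys, paste(ed$word_a, ed$word_b))
})

test_that("normalize_associations lowercases, trims, applies the hook, and re-aggregates", {
  tab <- tibble::tibble(cue = c("Dog", "dog "), response = c(" Cats", "cats"),
                        participant_count = c(2L, 3L))
  out <- normalize_associations(tab)
  expect_equal(nrow(out), 1)
  expect_equal(out$participant_count, 5L)
  out2 <- normalize_associations(tab, merge_fn = function(x) sub("s$", "", x))
  expect_equal(out2$response, "cat")
})

test_that("association tables reject non-positive counts and duplicate records", {
  expect_error(build_semantic_network(tibble::tibble(
    cue = c("a", "b"), response = c("x", "x"), participant_count = c(0L, 2L))), ">= 1")
  expect_error(build_semantic_network(tibble::tibble(
    cue = c("a", "a"), response = c("x", "x"), participant_count = c(1L, 2L))), "duplicate")
})
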