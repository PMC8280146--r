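test_that("shortest_path_distance handles chains, identity, disconnection and unknown words", {
  g <- lexical_network(path_graph(c("intend", "intent", "invent", "invest")))
  expect_equal(shortest_path_distance(g, "intend", "invest"), 3)
  expect_equal(shortest_path_distance(g, "intent", "intent"), 0)

  g2 <- lexical_network(path_graph(c("a", "b", "c", "d")), nodes = c("a", "b", "c", "d", "e"))
  expect_equal(shortest_path_distance(g2, "a", "e"), Inf)
  expect_error(shortest_path_distance(g2, "a", "zzz"), "zzz")
})

test_that("hop distances ignore semantic weights and satisfy the triangle inequality", {
  ed <- data.frame(word_a = c("a", "b", "a"), word_b = c("b", "c", "c"),
                   weight = c(100, 100, 1))
  g <- lexical_network(ed)
  expect_equal(shortest_path_distance(g, "a", "b"), 1)

  for (s in 1:5) {
    rg <- rand_graph_edges(8, 12, seed = s)
    g <- lexical_network(rg$edges, nodes = rg$nodes)
    d <- igraph::distances(g, weights = NA)
    bf <- bf_distances(rg$nodes, rg$edges)
    expect_equal(unname(d[rg$nodes, rg$nodes]), unname(bf))
    trips <- withr::with_seed(s, replicate(20, sample(rg$nodes, 3), simplify = FALSE))
    for (t in trips) {
      expect_lte(bf[t[1], t[3]], bf[t[1], t[2]] + bf[t[2], t[3]])
    }
  }
})

test_that("giant_component picks the largest component with lexicographic tie-break", {
  tri <- lexical_network(data.frame(word_a = c("a", "b", "c"), word_b = c("b", "c", "a")))
  expect_equal(sort(igraph::V(giant_component(tri))$name), c("a", "b", "c"))

  mix <- lexical_network(rbind(data.frame(word_a = c("a", "b", "c"), word_b = c("b", "c", "a")),
                               data.frame(word_a = "d", word_b = "e")))
  expect_equal(sort(igraph::V(giant_component(mix))$name), c("a", "b", "c"))

  iso <- lexical_network(NULL, nodes = c("zeta", "alpha"))
  expect_equal(igraph::V(giant_component(iso))$name, "alpha")
  expect_error(giant_component(lexical_network(NULL, nodes = character())), "empty")
})

test_that("degree_preserving_shuffle keeps the exact degree multiset and is seed-stable", {
  tri <- lexical_network(data.frame(word_a = c("a", "b", "c"), word_b = c("b", "c", "a")))
  expect_equal(network_edges(degree_preserving_shuffle(tri, seed = 42)),
               network_edges(tri))

  star <- lexical_network(data.frame(word_a = rep("hub", 3), word_b = c("x", "y", "z")))
  shuf_star <- degree_preserving_shuffle(star, seed = 9)
  expect_equal(sort(igraph::degree(shuf_star)), sort(igraph::degree(star)))
  expect_equal(igraph::ecount(shuf_star), 3)

  for (s in 1:5) {
    rg <- rand_graph_edges(10, 18, seed = s)
    g <- lexical_network(rg$edges, nodes = rg$nodes)
    h <- degree_preserving_shuffle(g, seed = s + 100)
    expect_equal(sort(unname(igraph::degree(h)[rg$nodes])),
                 sort(unname(igraph::degree(g)[rg$nodes])))
    expect_false(igraph::any_multiple(h))
    expect_false(any(igraph::which_loop(h)))
    h2 <- degree_preserving_shuffle(g, seed = s + 100)
    expect_identical(network_edges(h), network_edges(h2))
  }
})

test_that("degree_preserving_shuffle drops weights for the null", {
  g <- lexical_network(data.frame(word_a = c("a", "b", "c", "d"),
                                  word_b = c("b", "c", "d", "a"), weight = 1:4))
  expect_false("weight" %in% igraph::edge_attr_names(degree_preserving_shuffle(g, seed = 1)))
})

test_that("edge_permutation_null keeps node set and edge count but not the wiring", {
  empty <- lexical_network(NULL, nodes = c("a", "b", "c"))
  expect_equal(igraph::ecount(edge_permutation_null(empty, seed = 1)), 0)

  k4 <- lexical_network(as.data.frame(setNames(as.data.frame(t(combn(letters[1:4], 2))),
                                               c("word_a", "word_b"))))
  expect_equal(network_edges(edge_permutation_null(k4, seed = 3)), network_edges(k4))

  for (s in 1:5) {
    rg <- rand_graph_edges(9, 14, seed = s)
    g <- lexical_network(rg$edges, nodes = rg$nodes)
    h <- edge_permutation_null(g, seed = s)
    expect_setequal(igraph::V(h)$name, rg$nodes)
    expect_equal(igraph::ecount(h), igraph::ecount(g))
    expect_identical(network_edges(edge_permutation_null(g, seed = s)), network_edges(h))
  }
})

test_that("spanning_connector returns a spanning tree per candidate component", {
  cyc <- data.frame(word_a = c("a", "b", "c", "d"), word_b = c("b", "c", "d", "a"))
  out <- spanning_connector(c("a", "b", "c", "d"), cyc, seed = 1)
  expect_equal(nrow(out), 3)
  g <- lexical_network(out, nodes = c("a", "b", "c", "d"))
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_forest(g))

  tree <- path_graph(c("a", "b", "c"))
  expect_setequal(paste(spanning_connector(c("a", "b", "c"), tree, seed = 5)$word_a,
                        spanning_connector(c("a", "b", "c"), tree, seed = 5)$word_b),
                  paste(tree$word_a, tree$word_b))

  two <- rbind(data.frame(word_a = c("a", "b", "c"), word_b = c("b", "c", "a")),
               data.frame(word_a = "x", word_b = "y"))
  out2 <- spanning_connector(c("a", "b", "c", "x", "y", "lone"), two, seed = 2)
  expect_equal(nrow(out2), 3)
  comp_in <- igraph::components(lexical_network(two, nodes = c("a", "b", "c", "x", "y", "lone")))
  comp_out <- igraph::components(lexical_network(out2, nodes = c("a", "b", "c", "x", "y", "lone")))
  expect_equal(comp_out$membership, comp_in$membership)
})

test_that("mean_distance_summary averages finite pairs under the chosen policy", {
  tri <- lexical_network(data.frame(word_a = c("a", "b", "c"), word_b = c("b", "c", "a")))
  expect_equal(mean_distance_summary(tri)$mean_distance, 1.0)

  p3 <- lexical_network(path_graph(c("a", "b", "c")))
  expect_equal(mean_distance_summary(p3)$mean_distance, 4 / 3)

  p3i <- lexical_network(path_graph(c("a", "b", "c")), nodes = c("a", "b", "c", "d"))
  s <- mean_distance_summary(p3i, policy = "exclude")
  expect_equal(s$mean_distance, 4 / 3)
  expect_equal(s$n_pairs_used, 3)
  expect_equal(mean_distance_summary(p3i, policy = "giant_component_only")$mean_distance, 4 / 3)
  expect_error(mean_distance_summary(lexical_network(NULL, nodes = c("a", "b"))), "finite")
})

test_that("layer-union mean distance never exceeds either layer's (brute-force check)", {
  for (s in 1:10) {
    ra <- rand_graph_edges(7, 8, seed = s)
    rb <- rand_graph_edges(7, 8, seed = s + 50)
    un <- unique(rbind(ra$edges, rb$edges))
    da <- bf_distances(ra$nodes, ra$edges)
    db <- bf_distances(ra$nodes, rb$edges)
    du <- bf_distances(ra$nodes, un)
    both <- is.finite(da) & is.finite(db) & upper.tri(da)
    if (!any(both)) next
    ga <- lexical_network(ra$edges, nodes = ra$nodes)
    gu <- lexical_network(un, nodes = ra$nodes)
    expect_lte(mean(du[both]), mean(da[both]))
    expect_lte(mean(du[both]), mean(db[both]))
    expect_equal(mean_distance_summary(gu)$mean_distance,
                 mean(du[upper.tri(du) & is.finite(du)]))
    expect_equal(mean_distance_summary(ga)$mean_distance,
                 mean(da[upper.tri(da) & is.finite(da)]))
  }
})

test_that("edge-list TSV round-trips weighted and unweighted networks", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  g <- lexical_network(data.frame(word_a = c("cat", "mat"), word_b = c("mat", "hat"),
                                  weight = c(2.5, 7)))
  write_edge_tsv(g, tmp)
  expect_equal(readLines(tmp)[1], "#source\ttarget\tweight")
  g2 <- read_edge_tsv(tmp)
  expect_equal(network_edges(g2), network_edges(g))

  u <- lexical_network(path_graph(c("a", "b", "c")), nodes = c("a", "b", "c", "iso"))
  write_edge_tsv(u, tmp)
  u2 <- read_edge_tsv(tmp, nodes = c("a", "b", "c", "iso"))
  expect_setequal(igraph::V(u2)$name, igraph::V(u)$name)
  expect_equal(network_edges(u2), network_edges(u))
})

test_that("lexical_network rejects self-loops and duplicate edges", {
  expect_error(lexical_network(data.frame(word_a = "a", word_b = "a")), "self-loop")
  expect_error(lexical_network(data.frame(word_a = c("a", "b"), word_b = c("b", "a"))),
               "duplicate")
  expect_error(lexical_network(data.frame(word_a = "a", word_b = "b", weight = -1)),
               "positive")
})

test_that("spawn_seeds is deterministic and bounded below 2^31", {
  expect_identical(spawn_seeds(7, 5), spawn_seeds(7, 5))
  expect_false(identical(spawn_seeds(7, 5), spawn_seeds(8, 5)))
  expect_true(all(spawn_seeds(1, 1000) < 2^31))
  expect_true(all(spawn_seeds(1, 1000) >= 1))
})
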