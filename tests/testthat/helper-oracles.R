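# Independent brute-force oracles and small fixtures. These deliberately do
# not share code with the package implementation.

# all-pairs hop distances by Floyd-Warshall over an edge data frame
bf_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$word_a[r], nodes)
    j <- match(edges$word_b[r], nodes)
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k]
      if (is.finite(dk)) {
        cand <- dk + d[k, ]
        upd <- cand < d[i, ]
        d[i, upd] <- cand[upd]
      }
    }
  }
  d
}

# token-level Levenshtein distance by the textbook dynamic programme
bf_levenshtein <- function(a, b) {
  ta <- strsplit(trimws(a), "\\s+")[[1]]
  tb <- strsplit(trimws(b), "\\s+")[[1]]
  la <- length(ta); lb <- length(tb)
  m <- matrix(0L, la + 1, lb + 1)
  m[, 1] <- 0:la
  m[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      m[i + 1, j + 1] <- min(
        m[i, j + 1] + 1L,
        m[i + 1, j] + 1L,
        m[i, j] + (ta[i] != tb[j])
      )
    }
  }
  m[la + 1, lb + 1]
}

# naive double-loop link strength: iterate every response string produced
# to either cue
bf_link_strength <- function(table, ci, cj, min_shared = 2L) {
  s <- 0L
  for (resp in unique(table$response)) {
    ni <- table$participant_count[table$cue == ci & table$response == resp]
    nj <- table$participant_count[table$cue == cj & table$response == resp]
    if (length(ni) == 1 && length(nj) == 1) {
      lo <- min(ni, nj)
      if (lo >= min_shared) s <- s + lo
    }
  }
  s
}

# random simple graph as an edge data frame over letter-ish node names
rand_graph_edges <- function(n, m, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(combn(nodes, 2))
  withr::with_seed(seed, {
    pick <- sample.int(nrow(all_pairs), min(m, nrow(all_pairs)))
  })
  list(nodes = nodes,
       edges = data.frame(word_a = all_pairs[pick, 1], word_b = all_pairs[pick, 2]))
}

# random association table with <= n_cues cues and <= n_resp response types
rand_assoc_table <- function(seed, n_cues = 6, n_resp = 12, max_count = 6) {
  withr::with_seed(seed, {
    cues <- sprintf("cue%02d", seq_len(sample(2:n_cues, 1)))
    resps <- sprintf("r%02d", seq_len(sample(3:n_resp, 1)))
    rows <- do.call(rbind, lapply(cues, function(cu) {
      rs <- sample(resps, sample(1:length(resps), 1))
      data.frame(cue = cu, response = rs,
                 participant_count = sample.int(max_count, length(rs), replace = TRUE))
    }))
    tibble::as_tibble(rows)
  })
}

# the worked four-word chain, transcribed orthographically (letters as
# phonemes); the edit-distance-1 chain is the same as with dictionary
# phonemes
intend_chain <- function() {
  data.frame(
    word = c("intend", "intent", "invent", "invest"),
    phonemes = c("i n t e n d", "i n t e n t", "i n v e n t", "i n v e s t")
  )
}

path_graph <- function(words) {
  data.frame(word_a = words[-length(words)], word_b = words[-1])
}
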