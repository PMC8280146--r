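# Phonological layer: Levenshtein edit distance 1 over phoneme tokens.
#
# Transcriptions are word -> ordered phoneme token sequences; any whitespace-
# separated token counts as one phoneme (ARPAbet, IPA or synthetic alphabets
# all work; stress/syllable preprocessing is left to the caller).

split_phonemes <- function(phonemes) {
  toks <- strsplit(trimws(phonemes), "\\s+")
  bad <- lengths(toks) == 0
  if (any(bad)) stop("empty phoneme sequence(s)")
  toks
}

# recode token sequences as compact strings over a private unicode page so
# that utils::adist computes token-level Levenshtein distances
encode_tokens <- function(token_list) {
  alphabet <- unique(unlist(token_list, use.names = FALSE))
  vapply(token_list, function(t) {
    intToUtf8(match(t, alphabet) + 0x100L)
  }, character(1))
}

#' Levenshtein edit distance between two phoneme transcriptions
#'
#' Unit costs for insertion, deletion and substitution of a single phoneme
#' token. Two words are phonological neighbours when this distance is
#' exactly 1.
#'
#' @param t1,t2 character scalars of space-separated phoneme tokens.
#' @return non-negative integer edit distance.
#' @export
phoneme_edit_distance <- function(t1, t2) {
  toks <- split_phonemes(c(t1, t2))
  enc <- encode_tokens(toks)
  as.integer(adist(enc[1], enc[2]))
}

#' Read a phoneme transcription table
#'
#' TSV with two columns: `word<TAB>phoneme phoneme ...`.
#'
#' @param path file path.
#' @return tibble with columns `word`, `phonemes`.
#' @export
read_transcriptions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("word", "phonemes"),
                          colClasses = "character", comment.char = "#",
                          fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}

#' Build the unweighted phonological network
#'
#' Nodes are all input words; edges are exactly the pairs at phoneme edit
#' distance 1 (one phoneme added, deleted, or substituted). Homophones
#' (identical transcriptions, distance 0) get no edge. A length-bucketing
#' prefilter compares only words whose token counts differ by at most one;
#' this cannot change the result since the edit distance is bounded below by
#' the length gap.
#'
#' @param transcriptions data frame with columns `word`, `phonemes`. Words
#'   must be unique; a duplicated word with a conflicting transcription is an
#'   error (exact duplicates are collapsed).
#' @return unweighted lexical network over all input words. Isolated words
#'   (no neighbour at distance 1) are listed in the graph attribute
#'   `isolates`; downstream analyses typically consume
#'   [giant_component()] of this network.
#' @export
build_phonological_network <- function(transcriptions) {
  stopifnot(all(c("word", "phonemes") %in% names(transcriptions)))
  tr <- unique(tibble::as_tibble(transcriptions)[, c("word", "phonemes")])
  if (nrow(tr) == 0) stop("at least one transcription required")
  dup <- tr$word[duplicated(tr$word)]
  if (length(dup)) {
    stop("conflicting transcriptions for word(s): ",
         paste(unique(dup), collapse = ", "))
  }
  toks <- split_phonemes(tr$phonemes)
  enc <- encode_tokens(toks)
  len <- lengths(toks)
  words <- tr$word

  pairs_a <- character(0); pairs_b <- character(0)
  for (L in sort(unique(len))) {
    i <- which(len == L)
    # same length: substitutions
    if (length(i) >= 2) {
      dm <- adist(enc[i])
      hit <- which(dm == 1 & upper.tri(dm), arr.ind = TRUE)
      if (nrow(hit)) {
        pairs_a <- c(pairs_a, words[i[hit[, 1]]])
        pairs_b <- c(pairs_b, words[i[hit[, 2]]])
      }
    }
    # length L vs L+1: insertions/deletions
    j <- which(len == L + 1L)
    if (length(i) && length(j)) {
      dm <- adist(enc[i], enc[j])
      hit <- which(dm == 1, arr.ind = TRUE)
      if (nrow(hit)) {
        pairs_a <- c(pairs_a, words[i[hit[, 1]]])
        pairs_b <- c(pairs_b, words[j[hit[, 2]]])
      }
    }
  }
  edges <- data.frame(word_a = pairs_a, word_b = pairs_b)
  g <- lexical_network(edges, nodes = sort(words))
  g <- igraph::set_graph_attr(g, "isolates",
                              sort(words[!words %in% c(pairs_a, pairs_b)]))
  g
}

#' Classify connected word pairs by shortest-path distance
#'
#' For each distance `d` in `1..max_distance`, the set of unordered pairs at
#' shortest-path distance exactly `d`. Classes are disjoint and, over
#' `d = 1..diameter`, partition the connected pairs.
#'
#' @param net connected lexical network (apply [giant_component()] first).
#' @param max_distance largest distance class; defaults to 3 as used for the
#'   overlap analyses (link-addition analyses typically use 6).
#' @return named list (`"1"`, `"2"`, ...) of tibbles with `word_a`, `word_b`.
#' @export
distance_class_pairs <- function(net, max_distance = 3L) {
  stopifnot(max_distance >= 1)
  if (!igraph::is_connected(net)) {
    stop("network must be connected; apply giant_component() first")
  }
  d <- igraph::distances(net, weights = NA)
  nm <- rownames(d)
  out <- vector("list", max_distance)
  names(out) <- as.character(seq_len(max_distance))
  for (k in seq_len(max_distance)) {
    hit <- which(d == k & upper.tri(d), arr.ind = TRUE)
    out[[k]] <- tibble::tibble(
      word_a = pmin(nm[hit[, 1]], nm[hit[, 2]]),
      word_b = pmax(nm[hit[, 1]], nm[hit[, 2]])
    )
  }
  out
}
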