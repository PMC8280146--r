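# Synthetic lexicons with the statistical structure the analyses assume:
# phoneme-level word inventories whose edit-distance-1 graph has a giant
# component, association tables with a tunable coupling between phonological
# proximity and shared-response strength, planted topic communities, and
# reaction times increasing with path length.
#
# Coupling is injected through shared response pools of phonological
# neighbours — not by wiring the semantic graph directly — so the planted
# signal has to pass through the association-overlap link-strength
# estimator to become a semantic link.

#' Configuration for the synthetic lexicon generator
#'
#' @param n_words number of words (desk-scale default 500).
#' @param phoneme_alphabet_size phoneme inventory size (single letters up to
#'   26, synthetic tokens beyond).
#' @param word_length_range integer range of phonemes per word.
#' @param n_participants_per_cue participants responding to each cue.
#' @param n_responses_per_participant associative responses per participant
#'   (default 3, as in large free-association collections).
#' @param coupling_rho probability in `[0, 1]` that a response is drawn from
#'   a phonological neighbour's preferred response pool; 0 decouples the
#'   layers (null), larger values plant phonology-semantics overlap.
#' @param n_communities number of planted topic communities.
#' @param intra_community_boost odds weight of drawing from the cue's own
#'   topic rather than any single other topic (>= 1).
#' @param responses_per_topic size of each topic's response pool.
#' @param preferred_set_size preferred responses per word (drawn from its
#'   topic pool); sharing of preferred responses is what creates strong
#'   semantic links.
#' @param mutation_prob probability that a new word is a one-phoneme
#'   mutation of an existing word (controls phonological neighbourhood
#'   density) rather than a fresh random string.
#' @param rt_intercept_ms,rt_slope_ms,rt_noise_sd_ms reaction-time model:
#'   `rt = intercept + slope * path_length + N(0, sd)`.
#' @param seed master seed; one integer fixes lexicon, associations and RTs.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_words = 500L,
                             phoneme_alphabet_size = 10L,
                             word_length_range = c(3L, 6L),
                             n_participants_per_cue = 50L,
                             n_responses_per_participant = 3L,
                             coupling_rho = 0,
                             n_communities = 4L,
                             intra_community_boost = 8,
                             responses_per_topic = 40L,
                             preferred_set_size = 5L,
                             mutation_prob = 0.6,
                             rt_intercept_ms = 650,
                             rt_slope_ms = 40,
                             rt_noise_sd_ms = 30,
                             seed = 1L) {
  cfg <- list(
    n_words = as.integer(n_words),
    phoneme_alphabet_size = as.integer(phoneme_alphabet_size),
    word_length_range = as.integer(word_length_range),
    n_participants_per_cue = as.integer(n_participants_per_cue),
    n_responses_per_participant = as.integer(n_responses_per_participant),
    coupling_rho = coupling_rho,
    n_communities = as.integer(n_communities),
    intra_community_boost = intra_community_boost,
    responses_per_topic = as.integer(responses_per_topic),
    preferred_set_size = as.integer(preferred_set_size),
    mutation_prob = mutation_prob,
    rt_intercept_ms = rt_intercept_ms,
    rt_slope_ms = rt_slope_ms,
    rt_noise_sd_ms = rt_noise_sd_ms,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_words >= 2, cfg$phoneme_alphabet_size >= 2,
    length(cfg$word_length_range) == 2,
    cfg$word_length_range[1] >= 1,
    cfg$word_length_range[2] >= cfg$word_length_range[1],
    cfg$n_participants_per_cue >= 1, cfg$n_responses_per_participant >= 1,
    cfg$coupling_rho >= 0, cfg$coupling_rho <= 1,
    cfg$n_communities >= 1, cfg$intra_community_boost >= 1,
    cfg$responses_per_topic >= 1, cfg$preferred_set_size >= 1,
    cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
    cfg$rt_noise_sd_ms >= 0
  )
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic lexicon config:", x$n_words, "words, alphabet",
      x$phoneme_alphabet_size, ", lengths", x$word_length_range[1], "-",
      x$word_length_range[2], ", rho =", x$coupling_rho, ",",
      x$n_communities, "communities, seed", x$seed, "\n")
  invisible(x)
}

phoneme_tokens <- function(k) {
  if (k <= 26) letters[seq_len(k)] else sprintf("p%02d", seq_len(k))
}

#' Generate a synthetic phoneme lexicon
#'
#' Produces `n_words` unique words as phoneme sequences, mixing uniform
#' random strings with one-phoneme mutations (substitution, insertion,
#' deletion) of already-generated words so the edit-distance-1 graph has a
#' nontrivial giant component.
#'
#' @param config a [synthetic_config()].
#' @return tibble with columns `word` (identifier, the concatenated
#'   phonemes) and `phonemes` (space-separated tokens).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  toks <- phoneme_tokens(config$phoneme_alphabet_size)
  lo <- config$word_length_range[1]; hi <- config$word_length_range[2]
  joiner <- if (config$phoneme_alphabet_size <= 26) "" else "-"
  withr::with_seed(spawn_seeds(config$seed, 3L)[1], {
    words <- list()
    seen <- character(0)
    attempts <- 0L
    max_attempts <- 1000L * config$n_words
    while (length(words) < config$n_words) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("cannot generate ", config$n_words,
             " unique words within the length range; got ", length(words))
      }
      cand <- if (length(words) > 0 && runif(1) < config$mutation_prob) {
        base <- words[[sample.int(length(words), 1)]]
        op <- sample(c("sub", "ins", "del"), 1)
        L <- length(base)
        if (op == "del" && L - 1 < lo) op <- "sub"
        if (op == "ins" && L + 1 > hi) op <- "sub"
        switch(op,
          sub = { i <- sample.int(L, 1); base[i] <- sample(toks, 1); base },
          ins = { i <- sample.int(L + 1, 1); append(base, sample(toks, 1), after = i - 1) },
          del = { base[-sample.int(L, 1)] }
        )
      } else {
        L <- sample(seq(lo, hi), 1)
        sample(toks, L, replace = TRUE)
      }
      key <- paste(cand, collapse = joiner)
      if (!key %in% seen) {
        seen <- c(seen, key)
        words[[length(words) + 1L]] <- cand
      }
    }
    tibble::tibble(
      word = seen,
      phonemes = vapply(words, paste, character(1), collapse = " ")
    )
  })
}

#' Generate a synthetic free-association table
#'
#' Words are partitioned into planted topic communities, each with its own
#' response pool; every word prefers a small subset of its topic pool.
#' Each of `n_participants_per_cue` participants produces
#' `n_responses_per_participant` responses per cue: with probability
#' `coupling_rho` (when the cue has a phonological neighbour) from a random
#' neighbour's preferred set — coupling phonological proximity to shared
#' responses — otherwise from the cue's own preferred set with odds
#' `intra_community_boost` against a uniform draw from another topic's
#' pool. Counts are aggregated per (cue, response).
#'
#' @param config a [synthetic_config()].
#' @param lexicon transcriptions from [generate_lexicon()].
#' @return association table tibble (`cue`, `response`,
#'   `participant_count`), with the planted topic assignment attached as
#'   attribute `"topics"` (named integer vector).
#' @export
generate_associations <- function(config, lexicon) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- spawn_seeds(config$seed, 3L)
  words <- lexicon$word
  n <- length(words)
  K <- config$n_communities
  phono <- build_phonological_network(lexicon)
  adj <- igraph::as_adj_list(phono)
  nbrs <- lapply(adj, function(v) igraph::V(phono)$name[as.integer(v)])
  names(nbrs) <- igraph::V(phono)$name

  withr::with_seed(seeds[2], {
    topic <- sample(rep_len(seq_len(K), n))
    names(topic) <- words
    pools <- lapply(seq_len(K), function(t) {
      sprintf("t%d_r%02d", t, seq_len(config$responses_per_topic))
    })
    preferred <- lapply(seq_len(n), function(i) {
      sample(pools[[topic[i]]], min(config$preferred_set_size,
                                    config$responses_per_topic))
    })
    names(preferred) <- words

    total <- config$n_participants_per_cue * config$n_responses_per_participant
    p_own <- config$intra_community_boost / (config$intra_community_boost + K - 1)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      w <- words[i]
      nb <- nbrs[[w]]
      u <- runif(total)
      resp <- character(total)
      from_nb <- u < config$coupling_rho & length(nb) > 0
      n_nb <- sum(from_nb)
      if (n_nb > 0) {
        pick_nb <- sample(nb, n_nb, replace = TRUE)
        resp[from_nb] <- vapply(pick_nb, function(v) sample(preferred[[v]], 1),
                                character(1))
      }
      rest <- which(!from_nb)
      if (length(rest)) {
        own <- runif(length(rest)) < p_own
        resp[rest[own]] <- sample(preferred[[w]], sum(own), replace = TRUE)
        n_other <- sum(!own)
        if (n_other > 0) {
          if (K > 1) {
            ot <- sample(setdiff(seq_len(K), topic[i]), n_other, replace = TRUE)
          } else {
            ot <- rep(topic[i], n_other)
          }
          resp[rest[!own]] <- vapply(ot, function(t) sample(pools[[t]], 1),
                                     character(1))
        }
      }
      tab <- table(resp)
      recs[[i]] <- tibble::tibble(cue = w, response = names(tab),
                                  participant_count = as.integer(tab))
    }
    out <- dplyr::bind_rows(recs)
    attr(out, "topics") <- topic
    out
  })
}

#' Generate synthetic reaction times from a network
#'
#' Samples word pairs balanced over path lengths 1-4 in the (connected)
#' network and assigns `rt = rt_intercept_ms + rt_slope_ms * length +
#' N(0, rt_noise_sd_ms)`. Length classes with no pairs in the network are
#' skipped with a warning.
#'
#' @param config a [synthetic_config()].
#' @param net connected lexical network.
#' @param n_pairs total pairs to sample (split over the length classes).
#' @return RT tibble (`word_a`, `word_b`, `rt_ms`) with attribute
#'   `"path_length"` giving each pair's generating length.
#' @export
generate_rts <- function(config, net, n_pairs = 200L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!igraph::is_connected(net)) stop("network must be connected")
  classes <- distance_class_pairs(net, max_distance = 4L)
  per_class <- max(1L, n_pairs %/% 4L)
  # third child stream of the master seed (lexicon and associations use the
  # first two), re-split for the four classes plus the noise draw
  seeds <- spawn_seeds(spawn_seeds(config$seed, 3L)[3], 5L)
  rows <- list()
  for (k in 1:4) {
    cl <- classes[[as.character(k)]]
    if (nrow(cl) == 0) {
      warning("no pairs at path length ", k, "; class skipped")
      next
    }
    take <- min(per_class, nrow(cl))
    pick <- withr::with_seed(seeds[k], sample.int(nrow(cl), take))
    sub <- cl[pick, , drop = FALSE]
    sub$path_length <- k
    rows[[length(rows) + 1L]] <- sub
  }
  out <- dplyr::bind_rows(rows)
  noise <- withr::with_seed(seeds[5],
                            rnorm(nrow(out), 0, config$rt_noise_sd_ms))
  rt <- config$rt_intercept_ms + config$rt_slope_ms * out$path_length + noise
  res <- tibble::tibble(word_a = out$word_a, word_b = out$word_b,
                        rt_ms = pmax(rt, 1))
  attr(res, "path_length") <- out$path_length
  res
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `transcriptions.tsv` (word, phonemes), `associations.tsv`
#' (cue, response, participant_count), `rts.tsv` (word_a, word_b, rt_ms)
#' and `config.tsv` (resolved parameter values, including the seed).
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if missing).
#' @param n_rt_pairs pairs for the RT table.
#' @return invisibly, a list with the generated `lexicon`, `associations`,
#'   `rts` and the phonological giant component used for RT sampling.
#' @export
write_synthetic_dataset <- function(config, outdir, n_rt_pairs = 200L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lex <- generate_lexicon(config)
  assoc <- generate_associations(config, lex)
  phono <- giant_component(build_phonological_network(lex))
  rts <- generate_rts(config, phono, n_pairs = n_rt_pairs)
  write_tsv_plain <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  write_tsv_plain(lex, file.path(outdir, "transcriptions.tsv"))
  write_tsv_plain(assoc, file.path(outdir, "associations.tsv"))
  write_tsv_plain(rts, file.path(outdir, "rts.tsv"))
  cfg <- data.frame(parameter = names(unclass(config)),
                    value = vapply(unclass(config), function(v)
                      paste(v, collapse = ","), character(1)))
  write_tsv_plain(cfg, file.path(outdir, "config.tsv"))
  invisible(list(lexicon = lex, associations = assoc, rts = rts, phono = phono))
}
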