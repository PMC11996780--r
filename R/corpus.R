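# Narrative preprocessing, skip-gram embedding training and the similar-term
# machinery used to expand AE dictionaries with corpus-specific synonyms,
# misspellings and abbreviations.

default_protected_abbrev <- c("e.g.", "i.e.", "q.d.", "b.i.d.", "t.i.d.",
                              "s.i.d.", "q.i.d.", "approx.")

#' Preprocess clinical narratives into a tokenized corpus
#'
#' Splits each narrative into sentences (on `.`, `!`, `?`, `;` and newlines,
#' protecting common clinical abbreviations), lowercases, tokenizes into
#' alphanumeric tokens (dropping punctuation), and joins frequently
#' co-occurring adjacent token pairs into single `a_b` bigram tokens. The
#' bigram score is `(count(ab) - min_count) * corpus_size / (count(a) *
#' count(b))` with `corpus_size` the total token count; pairs scoring at or
#' above `bigram_threshold` are joined greedily left to right in a single
#' pass (no trigrams).
#'
#' @param narratives character vector of free-text narratives.
#' @param bigram_min_count minimum pair count considered for joining.
#' @param bigram_threshold score threshold for joining.
#' @param protected abbreviations whose full stops must not split sentences.
#' @return object of class `tokenized_corpus`: `sentences` (list of lowercase
#'   token vectors) and `phrases` (data.frame of joined bigrams with scores).
#' @export
preprocess_narratives <- function(narratives, bigram_min_count = 5,
                                  bigram_threshold = 10,
                                  protected = default_protected_abbrev) {
  txt <- tolower(as.character(narratives))
  txt[is.na(txt)] <- ""
  for (ab in protected) {
    txt <- gsub(regex_escape(ab), gsub(".", "", ab, fixed = TRUE), txt, perl = TRUE)
  }
  sent_txt <- unlist(strsplit(txt, "[.!?;\n]+"), use.names = FALSE)
  toks <- regmatches(sent_txt, gregexpr("[a-z0-9]+", sent_txt))
  toks <- toks[lengths(toks) > 0]

  phrases <- data.frame(bigram = character(), score = numeric(),
                        count = integer(), stringsAsFactors = FALSE)
  if (length(toks)) {
    flat <- unlist(toks, use.names = FALSE)
    uni <- table(flat)
    total <- length(flat)
    lead <- unlist(lapply(toks, function(w) if (length(w) > 1) w[-length(w)] else character()),
                   use.names = FALSE)
    trail <- unlist(lapply(toks, function(w) if (length(w) > 1) w[-1] else character()),
                    use.names = FALSE)
    if (length(lead)) {
      pair <- paste(lead, trail)
      pc <- table(pair)
      cand <- pc[pc >= bigram_min_count]
      if (length(cand)) {
        parts <- strsplit(names(cand), " ", fixed = TRUE)
        a <- vapply(parts, `[`, character(1), 1)
        b <- vapply(parts, `[`, character(1), 2)
        score <- (as.numeric(cand) - bigram_min_count) * total /
          (as.numeric(uni[a]) * as.numeric(uni[b]))
        keep <- score >= bigram_threshold
        if (any(keep)) {
          phrases <- data.frame(bigram = names(cand)[keep], score = score[keep],
                                count = as.integer(cand)[keep],
                                stringsAsFactors = FALSE)
          phrase_set <- phrases$bigram
          toks <- lapply(toks, function(w) {
            if (length(w) < 2) return(w)
            is_pair <- paste(w[-length(w)], w[-1]) %in% phrase_set
            out <- character(length(w))
            i <- 1L; j <- 0L
            while (i <= length(w)) {
              j <- j + 1L
              if (i < length(w) && is_pair[i]) {
                out[j] <- paste0(w[i], "_", w[i + 1]); i <- i + 2L
              } else {
                out[j] <- w[i]; i <- i + 1L
              }
            }
            out[seq_len(j)]
          })
        }
      }
    }
  }
  structure(list(sentences = toks, phrases = phrases), class = "tokenized_corpus")
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("Tokenized corpus: %d sentences, %d tokens, %d joined bigrams\n",
              length(x$sentences), sum(lengths(x$sentences)), nrow(x$phrases)))
  invisible(x)
}

#' Train skip-gram word embeddings
#'
#' Trains skip-gram-with-negative-sampling embeddings on a tokenized corpus.
#' Training is single-threaded with an internal deterministic RNG: two runs
#' with the same corpus, parameters and seed give bit-identical vectors. The
#' defaults (300 dimensions, window 5, minimum count 8, 15 iterations) suit a
#' large clinical corpus; tests use smaller values.
#'
#' @param corpus a [preprocess_narratives()] result, or a list of token
#'   vectors.
#' @param vector_size embedding dimension.
#' @param window maximum context window (dynamically reduced per position).
#' @param min_count tokens occurring fewer times are dropped from the
#'   vocabulary.
#' @param iterations training epochs.
#' @param negative negative samples per positive pair.
#' @param alpha,min_alpha initial and floor learning rate.
#' @param seed integer seed for the internal RNG.
#' @param workers must be 1; only the deterministic single-worker contract is
#'   provided.
#' @return object of class `embedding_model` with `vectors` (vocabulary x
#'   dimension matrix, rownames are tokens), `counts` and `params`.
#' @export
train_embeddings <- function(corpus, vector_size = 300, window = 5,
                             min_count = 8, iterations = 15, negative = 5,
                             alpha = 0.025, min_alpha = 1e-4, seed = 1,
                             workers = 1) {
  if (inherits(corpus, "tokenized_corpus")) corpus <- corpus$sentences
  if (!length(corpus)) stopf("corpus is empty")
  if (workers != 1) {
    stopf("only single-worker (deterministic) training is provided; set workers = 1")
  }
  stopifnot(vector_size >= 1, window >= 1, min_count >= 1, iterations >= 1)
  flat <- unlist(corpus, use.names = FALSE)
  counts <- table(flat)
  counts <- counts[counts >= min_count]
  if (!length(counts)) stopf("no tokens meet min_count = %d; vocabulary is empty", min_count)
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  counts <- as.integer(counts)[ord]
  idx <- seq_along(vocab); names(idx) <- vocab
  sents <- lapply(corpus, function(w) {
    i <- idx[w]
    as.integer(i[!is.na(i)] - 1L)
  })
  sents <- sents[lengths(sents) > 0]
  p <- counts^0.75
  noise_cdf <- cumsum(p / sum(p))
  noise_cdf[length(noise_cdf)] <- 1.0
  vec <- sgns_train_cpp(sents, length(vocab), noise_cdf,
                        as.integer(vector_size), as.integer(window),
                        as.integer(negative), as.integer(iterations),
                        alpha, min_alpha, as.numeric(seed))
  stopifnot(all(is.finite(vec)))
  rownames(vec) <- vocab
  structure(list(vectors = vec, counts = stats::setNames(counts, vocab),
                 params = list(vector_size = vector_size, window = window,
                               min_count = min_count, iterations = iterations,
                               negative = negative, alpha = alpha, seed = seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Skip-gram embedding model: %d tokens x %d dims ",
                     "(window %d, min_count %d, %d iterations, seed %s)\n"),
              nrow(x$vectors), p$vector_size, p$window, p$min_count,
              p$iterations, format(p$seed)))
  invisible(x)
}

check_in_vocab <- function(model, word) {
  if (!word %in% rownames(model$vectors)) {
    stopf("token '%s' is not in the model vocabulary", word)
  }
}

#' Most similar terms by cosine similarity
#'
#' Ranks every other vocabulary token by cosine similarity to `input_word`,
#' descending, with ties broken lexicographically. The list can be truncated
#' at a minimum cosine and/or a maximum number of terms.
#'
#' @param model an [train_embeddings()] model.
#' @param input_word query token (must be in vocabulary).
#' @param min_cosine keep terms with cosine `>= min_cosine`.
#' @param top_n keep at most the first `top_n` terms.
#' @return data.frame with columns `term` and `cosine`.
#' @export
similar_terms <- function(model, input_word, min_cosine = NULL, top_n = NULL) {
  check_in_vocab(model, input_word)
  v <- model$vectors
  norms <- sqrt(rowSums(v^2))
  norms[norms == 0] <- 1
  q <- v[input_word, ] / norms[input_word]
  cos <- as.numeric(v %*% q) / norms
  cos <- pmin(1, pmax(-1, cos))
  out <- data.frame(term = rownames(v), cosine = cos, stringsAsFactors = FALSE)
  out <- out[out$term != input_word, , drop = FALSE]
  out <- out[order(-out$cosine, out$term), , drop = FALSE]
  if (!is.null(min_cosine)) out <- out[out$cosine >= min_cosine, , drop = FALSE]
  if (!is.null(top_n)) out <- head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Relevance oracle
#'
#' A deterministic stand-in for manual review of candidate terms: a lookup
#' from term to relevant/irrelevant, with unseen terms irrelevant by default.
#' A term already present in a dictionary should be marked irrelevant (not
#' novel) in the oracle file.
#'
#' @param terms character vector.
#' @param relevant logical vector of the same length.
#' @return object of class `relevance_oracle`.
#' @export
relevance_oracle <- function(terms, relevant) {
  stopifnot(length(terms) == length(relevant), !anyDuplicated(terms))
  structure(stats::setNames(as.logical(relevant), terms), class = "relevance_oracle")
}

#' Read a relevance oracle from a two-column delimited file
#'
#' @param path file with columns `term` and `relevant` (yes/no, true/false or
#'   1/0), comma- or tab-separated with a header row.
#' @return a [relevance_oracle()].
#' @export
read_oracle <- function(path) {
  x <- read.csv(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                stringsAsFactors = FALSE)
  if (!all(c("term", "relevant") %in% names(x))) {
    stopf("oracle file must have columns 'term' and 'relevant'")
  }
  rel <- tolower(as.character(x$relevant)) %in% c("yes", "y", "true", "1")
  relevance_oracle(x$term, rel)
}

#' Is a term relevant according to an oracle?
#'
#' @param oracle a [relevance_oracle()].
#' @param terms character vector; unseen terms are irrelevant.
#' @return logical vector.
#' @export
oracle_relevant <- function(oracle, terms) {
  r <- unclass(oracle)[terms]
  r[is.na(r)] <- FALSE
  unname(r)
}

#' Cosine cut-off from an explicit ranking
#'
#' Walks a similarity ranking from the top. Every oracle-relevant term resets
#' the streak and records its cosine; the walk stops after `patience`
#' consecutive irrelevant (or non-novel) terms, or at the end of the ranking.
#' The cut-off is the cosine of the last relevant term seen; if no term was
#' relevant, a "no cut-off" sentinel is returned (`found = FALSE`).
#'
#' @param terms,cosines the ranking, descending by cosine.
#' @param oracle a [relevance_oracle()].
#' @param patience streak length that stops the walk (default 10).
#' @return list with `cutoff` (numeric or `NA`), `term`, `found`,
#'   `n_reviewed`.
#' @export
cutoff_from_ranking <- function(terms, cosines, oracle, patience = 10) {
  stopifnot(length(terms) == length(cosines), patience >= 1)
  streak <- 0L
  cutoff <- NA_real_
  cut_term <- NA_character_
  i <- 0L
  for (i in seq_along(terms)) {
    if (oracle_relevant(oracle, terms[i])) {
      cutoff <- cosines[i]
      cut_term <- terms[i]
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) break
    }
  }
  list(cutoff = cutoff, term = cut_term, found = !is.na(cutoff),
       n_reviewed = i)
}

#' Determine the cosine cut-off for a preferred term
#'
#' Applies [cutoff_from_ranking()] to the full similarity ranking of a
#' preferred term (PT): the ranking is reviewed from the highest cosine until
#' `patience` consecutive terms are irrelevant, and the cosine of the last
#' relevant term becomes the cut-off used for the PT's lower-level terms.
#'
#' @inheritParams similar_terms
#' @param pt_term the preferred term (must be in vocabulary).
#' @param oracle a [relevance_oracle()].
#' @param patience stop after this many consecutive irrelevant terms.
#' @return as [cutoff_from_ranking()].
#' @export
determine_cutoff <- function(model, pt_term, oracle, patience = 10) {
  check_in_vocab(model, pt_term)
  rk <- similar_terms(model, pt_term)
  cutoff_from_ranking(rk$term, rk$cosine, oracle, patience)
}

#' Sweep embedding hyper-parameters against a probe term
#'
#' Trains one model per grid entry, queries the `top_n` nearest neighbours of
#' the probe term and scores them with the oracle. Entries are ranked by most
#' relevant then fewest irrelevant neighbours, ties broken by grid order.
#' Entries where the probe falls below `min_count` are flagged, not dropped.
#'
#' @param corpus a [preprocess_narratives()] result.
#' @param grid list of named lists overriding [train_embeddings()] arguments
#'   (`vector_size`, `window`, `min_count`, ...).
#' @param probe_term probe token (the worked example uses "diarrhoea").
#' @param oracle a [relevance_oracle()].
#' @param top_n neighbours reviewed per entry (default 30).
#' @param ... passed to [train_embeddings()] as shared settings.
#' @return data.frame with one row per entry: the parameters, `relevant`,
#'   `irrelevant`, `rank` and `note`.
#' @export
sweep_parameters <- function(corpus, grid, probe_term, oracle, top_n = 30, ...) {
  if (inherits(corpus, "tokenized_corpus")) sentences <- corpus$sentences
  else sentences <- corpus
  probe_n <- sum(unlist(sentences, use.names = FALSE) == probe_term)
  shared <- list(...)
  rows <- lapply(seq_along(grid), function(i) {
    prm <- utils::modifyList(shared, grid[[i]])
    mc <- if (!is.null(prm$min_count)) prm$min_count else 8
    base <- data.frame(entry = i,
                       vector_size = if (!is.null(prm$vector_size)) prm$vector_size else 300,
                       window = if (!is.null(prm$window)) prm$window else 5,
                       min_count = mc, stringsAsFactors = FALSE)
    if (probe_n < mc) {
      return(cbind(base, relevant = NA_integer_, irrelevant = NA_integer_,
                   note = sprintf("probe '%s' below min_count (%d < %d)",
                                  probe_term, probe_n, mc)))
    }
    model <- do.call(train_embeddings, c(list(corpus = sentences), prm))
    nb <- similar_terms(model, probe_term, top_n = top_n)
    rel <- oracle_relevant(oracle, nb$term)
    cbind(base, relevant = sum(rel), irrelevant = sum(!rel), note = "")
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$relevant)
  rk <- rep(NA_integer_, nrow(out))
  rk[ok][order(-out$relevant[ok], out$irrelevant[ok], out$entry[ok])] <-
    seq_len(sum(ok))
  out$rank <- rk
  out[order(is.na(out$rank), out$rank), , drop = FALSE]
}
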