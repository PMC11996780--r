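# Independent oracles and small fixture builders shared across tests.

# Brute-force restricted Damerau-Levenshtein distance (substitution,
# insertion, deletion, adjacent transposition each cost 1).
dl_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Embedding model with hand-set vectors, for exercising the query layer
# independently of training.
toy_model <- function(vectors) {
  structure(list(vectors = vectors,
                 counts = stats::setNames(rep(10L, nrow(vectors)), rownames(vectors)),
                 params = list(vector_size = ncol(vectors), window = 5,
                               min_count = 1, iterations = 1, negative = 5,
                               alpha = 0.025, seed = 1)),
            class = "embedding_model")
}

# Narratives assembled from known words joined by single spaces, with the
# expected 0-based spans of every occurrence of `terms` computed from word
# offsets - an independent span oracle for the matcher.
random_word_narrative <- function(terms, filler, n_words) {
  words <- sample(c(terms, filler), n_words, replace = TRUE,
                  prob = c(rep(2, length(terms)), rep(1, length(filler))))
  starts <- cumsum(c(0L, nchar(words[-length(words)]) + 1L))
  hits <- which(words %in% terms)
  list(narrative = paste(words, collapse = " "),
       spans = data.frame(start0 = starts[hits],
                          end0 = starts[hits] + nchar(words[hits]),
                          term = words[hits], stringsAsFactors = FALSE))
}

# A small, fast generator configuration for property tests.
quick_config <- function(n_animals, seed, ...) {
  synth_config(n_animals = n_animals, rng_seed = seed, ...)
}
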