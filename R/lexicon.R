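# AE dictionaries: seed terms, embedding-based expansion, expert overrides,
# stem consolidation, context-aware matcher compilation and evaluation.

COMPONENTS <- c("disease_mention", "test_result", "diet_treatment")

#' Seed AE dictionary
#'
#' The starting dictionary for one adverse event: the specific lower-level
#' terms (LLTs) used to phrase individual clinical signs, and the broader
#' preferred terms (PTs) used as probes when determining cosine cut-offs.
#'
#' @param ae_name adverse event name.
#' @param llt_terms,pt_terms non-empty character vectors; lowercase, unique.
#' @return object of class `seed_dictionary`.
#' @export
seed_dictionary <- function(ae_name, llt_terms, pt_terms) {
  for (nm in c("llt_terms", "pt_terms")) {
    x <- get(nm)
    if (!length(x)) stopf("%s must be non-empty", nm)
    if (anyDuplicated(x)) stopf("%s must be unique", nm)
    if (any(x != tolower(x))) stopf("%s must be lowercase", nm)
  }
  structure(list(ae_name = ae_name, llt_terms = llt_terms, pt_terms = pt_terms),
            class = "seed_dictionary")
}

#' Read a seed dictionary from JSON
#'
#' @param path JSON file with fields `ae_name`, `llt_terms`, `pt_terms`.
#' @return a [seed_dictionary()].
#' @export
read_seed_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed_dictionary(x$ae_name, x$llt_terms, x$pt_terms)
}

#' @export
print.seed_dictionary <- function(x, ...) {
  cat(sprintf("Seed dictionary '%s': %d LLTs, %d PTs\n", x$ae_name,
              length(x$llt_terms), length(x$pt_terms)))
  invisible(x)
}

new_expanded_dictionary <- function(ae_name, entries) {
  stopifnot(all(c("term", "provenance", "component") %in% names(entries)))
  if (anyDuplicated(entries$term)) stopf("dictionary terms must be unique")
  stopifnot(all(entries$provenance %in% c("seed", "embedding", "expert")),
            all(entries$component %in% COMPONENTS))
  rownames(entries) <- NULL
  structure(list(ae_name = ae_name, entries = entries),
            class = "expanded_dictionary")
}

#' Expand a seed dictionary with embedding neighbours
#'
#' For every in-vocabulary LLT, vocabulary terms with cosine similarity at or
#' above the LLT's cut-off that the relevance oracle marks relevant are added
#' with provenance `"embedding"`. Seed entries are always retained;
#' out-of-vocabulary LLTs are kept as seed entries and recorded in the
#' `oov_terms` attribute.
#'
#' @param seed a [seed_dictionary()].
#' @param model an [train_embeddings()] model.
#' @param cutoffs a single cosine cut-off, or a named vector with one value
#'   per LLT (required for every in-vocabulary LLT).
#' @param oracle a [relevance_oracle()].
#' @param component component tag given to all entries (seed dictionaries
#'   describe disease mentions; test-result and diet/treatment terms arrive
#'   via [add_expert_terms()]).
#' @return object of class `expanded_dictionary` whose `entries` data.frame
#'   has columns `term`, `provenance`, `component`.
#' @export
expand_dictionary <- function(seed, model, cutoffs, oracle,
                              component = "disease_mention") {
  stopifnot(inherits(seed, "seed_dictionary"))
  vocab <- rownames(model$vectors)
  in_vocab <- seed$llt_terms[seed$llt_terms %in% vocab]
  if (length(cutoffs) == 1 && is.null(names(cutoffs))) {
    cutoffs <- stats::setNames(rep(unname(cutoffs), length(in_vocab)), in_vocab)
  }
  missing_cut <- setdiff(in_vocab, names(cutoffs))
  if (length(missing_cut)) {
    stopf("no cut-off defined for in-vocabulary LLT(s): %s",
          paste(missing_cut, collapse = ", "))
  }
  entries <- data.frame(term = seed$llt_terms, provenance = "seed",
                        component = component, stringsAsFactors = FALSE)
  for (llt in in_vocab) {
    nb <- similar_terms(model, llt, min_cosine = cutoffs[[llt]])
    add <- nb$term[oracle_relevant(oracle, nb$term) & !(nb$term %in% entries$term)]
    if (length(add)) {
      entries <- rbind(entries, data.frame(term = add, provenance = "embedding",
                                           component = component,
                                           stringsAsFactors = FALSE))
    }
  }
  out <- new_expanded_dictionary(seed$ae_name, entries)
  attr(out, "oov_terms") <- setdiff(seed$llt_terms, vocab)
  out
}

#' Add expert-review terms to a dictionary
#'
#' Incorporates terms suggested by domain experts (provenance `"expert"`),
#' e.g. test-result analyte names or disease-specific diets and treatments.
#' Terms already present are left untouched.
#'
#' @param dict an `expanded_dictionary`.
#' @param terms lowercase terms to add.
#' @param component one of `"disease_mention"`, `"test_result"`,
#'   `"diet_treatment"`.
#' @return the updated `expanded_dictionary`.
#' @export
add_expert_terms <- function(dict, terms, component = "disease_mention") {
  stopifnot(inherits(dict, "expanded_dictionary"),
            component %in% COMPONENTS)
  add <- setdiff(tolower(terms), dict$entries$term)
  if (!length(add)) return(dict)
  entries <- rbind(dict$entries,
                   data.frame(term = add, provenance = "expert",
                              component = component, stringsAsFactors = FALSE))
  out <- new_expanded_dictionary(dict$ae_name, entries)
  attr(out, "oov_terms") <- attr(dict, "oov_terms")
  out
}

#' @export
print.expanded_dictionary <- function(x, ...) {
  tab <- table(x$entries$provenance)
  cat(sprintf("Expanded dictionary '%s': %d terms (%s)\n", x$ae_name,
              nrow(x$entries),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  oov <- attr(x, "oov_terms")
  if (length(oov)) cat("  out-of-vocabulary LLTs:", paste(oov, collapse = ", "), "\n")
  invisible(x)
}

# Longest common prefix of a character vector.
longest_common_prefix <- function(xs) {
  mn <- min(nchar(xs))
  i <- 0L
  while (i < mn && length(unique(substr(xs, i + 1, i + 1))) == 1) i <- i + 1L
  substr(xs[1], 1, i)
}

#' Consolidate terms into prefix stems
#'
#' Groups terms sharing their first `min_prefix` characters; each group of
#' two or more terms is replaced by the group's longest common prefix, to be
#' matched as a prefix pattern. All other terms stay whole terms. On the
#' original terms, prefix-matching the stems covers exactly the union of the
#' grouped terms' matches.
#'
#' @param terms character vector (at least one term).
#' @param min_prefix minimum shared-prefix length to form a group (default 5).
#' @return list with sorted `stems` and `whole_terms`.
#' @export
consolidate_stems <- function(terms, min_prefix = 5) {
  if (!length(terms)) stopf("at least one term is required")
  terms <- unique(terms)
  long <- terms[nchar(terms) >= min_prefix]
  short <- setdiff(terms, long)
  groups <- split(long, substr(long, 1, min_prefix))
  stems <- character()
  whole <- short
  for (g in groups) {
    if (length(g) >= 2) stems <- c(stems, longest_common_prefix(g))
    else whole <- c(whole, g)
  }
  list(stems = sort(stems), whole_terms = sort(whole))
}

# Build one PCRE pattern. Word boundaries are alphanumeric/non-alphanumeric
# transitions (hyphens are boundaries); stems match as prefixes; exception
# phrases become fixed-width negative lookbehinds / variable-width negative
# lookaheads.
build_pattern <- function(term, is_stem, before = character(), after = character()) {
  gap <- "[ _]"
  body <- gsub(" +", paste0(gap, "+"), regex_escape(term))
  lb <- paste(vapply(before, function(p) {
    sprintf("(?<!%s%s)", gsub(" +", gap, regex_escape(p)), gap)
  }, character(1)), collapse = "")
  la <- paste(vapply(after, function(p) {
    sprintf("(?!%s+%s)", gap, gsub(" +", paste0(gap, "+"), regex_escape(p)))
  }, character(1)), collapse = "")
  paste0("(?i)", lb, "(?<![a-z0-9])", body,
         if (is_stem) "[a-z0-9]*" else "(?![a-z0-9])", la)
}

#' Compile a dictionary into a context-aware matcher
#'
#' Turns dictionary terms into case-insensitive word-boundary patterns with
#' negative-context exceptions: a pattern only matches when none of its
#' forbidden left-context phrases immediately precede it (fixed-width
#' negative lookbehind) and none of its forbidden right-context phrases
#' immediately follow it (negative lookahead). Optionally consolidates terms
#' into prefix-matched stems per component first.
#'
#' @param dict an `expanded_dictionary`, or a character vector of terms
#'   (tagged `disease_mention`).
#' @param exceptions named list: `exceptions[[term]] = list(before = ...,
#'   after = ...)` of forbidden context phrases. Phrases must be non-empty.
#' @param consolidate if `TRUE`, apply [consolidate_stems()] within each
#'   component.
#' @param stem_min_prefix passed to [consolidate_stems()].
#' @return object of class `compiled_matcher` with a `patterns` data.frame
#'   (`term`, `is_stem`, `component`, `regex`).
#' @export
compile_matcher <- function(dict, exceptions = NULL, consolidate = FALSE,
                            stem_min_prefix = 5) {
  if (is.character(dict)) {
    if (!length(dict)) stopf("dictionary is empty")
    dict <- new_expanded_dictionary("adhoc", data.frame(
      term = tolower(dict), provenance = "seed", component = "disease_mention",
      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(dict, "expanded_dictionary"))
  if (!nrow(dict$entries)) stopf("dictionary is empty")
  for (ex in exceptions) {
    phr <- c(ex$before, ex$after)
    if (length(phr) && any(!nzchar(phr))) stopf("exception phrases must be non-empty")
  }
  pats <- list()
  for (comp in unique(dict$entries$component)) {
    terms <- dict$entries$term[dict$entries$component == comp]
    if (consolidate) {
      cs <- consolidate_stems(terms, min_prefix = stem_min_prefix)
      tab <- data.frame(term = c(cs$stems, cs$whole_terms),
                        is_stem = rep(c(TRUE, FALSE),
                                      c(length(cs$stems), length(cs$whole_terms))),
                        stringsAsFactors = FALSE)
    } else {
      tab <- data.frame(term = terms, is_stem = FALSE, stringsAsFactors = FALSE)
    }
    tab$component <- comp
    pats[[comp]] <- tab
  }
  pats <- do.call(rbind, pats)
  pats$regex <- vapply(seq_len(nrow(pats)), function(i) {
    ex <- exceptions[[pats$term[i]]]
    build_pattern(pats$term[i], pats$is_stem[i],
                  before = if (is.null(ex)) character() else ex$before,
                  after = if (is.null(ex)) character() else ex$after)
  }, character(1))
  rownames(pats) <- NULL
  structure(list(ae_name = dict$ae_name, patterns = pats,
                 exceptions = exceptions),
            class = "compiled_matcher")
}

#' @export
print.compiled_matcher <- function(x, ...) {
  cat(sprintf("Compiled matcher '%s': %d patterns (%d stems), %d terms with exceptions\n",
              x$ae_name, nrow(x$patterns), sum(x$patterns$is_stem),
              length(x$exceptions)))
  invisible(x)
}

#' Export compiled patterns as plain regular expressions
#'
#' Writes one pattern per line (`component<TAB>regex`) so the final patterns
#' can be audited or reused outside R.
#'
#' @param matcher a [compile_matcher()] result.
#' @param path output text file.
#' @return the path, invisibly.
#' @export
export_patterns <- function(matcher, path) {
  writeLines(paste(matcher$patterns$component, matcher$patterns$regex, sep = "\t"),
             path)
  invisible(path)
}

#' Match a narrative against a compiled matcher
#'
#' Returns all non-overlapping hits left to right. Spans are 0-based
#' half-open character offsets into the narrative; `matched_text` is always
#' the corresponding slice. Overlapping candidate hits are resolved by
#' earliest start, then longest match.
#'
#' @param matcher a [compile_matcher()] result.
#' @param narrative a single character string.
#' @return data.frame with columns `start0`, `end0`, `matched_text`, `term`,
#'   `component` (zero rows when nothing matches).
#' @export
match_narrative <- function(matcher, narrative) {
  empty <- data.frame(start0 = integer(), end0 = integer(),
                      matched_text = character(), term = character(),
                      component = character(), stringsAsFactors = FALSE)
  if (is.na(narrative) || !nzchar(narrative)) return(empty)
  hits <- lapply(seq_len(nrow(matcher$patterns)), function(i) {
    m <- gregexpr(matcher$patterns$regex[i], narrative, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    data.frame(start0 = as.integer(m) - 1L, end0 = as.integer(m) - 1L + len,
               term = matcher$patterns$term[i],
               component = matcher$patterns$component[i],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits <- hits[order(hits$start0, -(hits$end0 - hits$start0)), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start0[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end0[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$matched_text <- substring(narrative, hits$start0 + 1L, hits$end0)
  rownames(hits) <- NULL
  hits[, c("start0", "end0", "matched_text", "term", "component")]
}

# Vectorized presence test: does each narrative contain at least one hit of
# any pattern (optionally restricted to some components)? Used where only
# case status is needed - far cheaper than building full match tables.
narrative_match_flags <- function(matcher, narratives, components = NULL) {
  pats <- matcher$patterns
  if (!is.null(components)) pats <- pats[pats$component %in% components, , drop = FALSE]
  flags <- logical(length(narratives))
  ok <- !is.na(narratives) & nzchar(narratives)
  for (rx in pats$regex) {
    todo <- ok & !flags
    if (!any(todo)) break
    flags[todo] <- grepl(rx, narratives[todo], perl = TRUE)
  }
  flags
}

new_eval_report <- function(n_matches, n_confirmed, n_positive) {
  precision <- if (n_matches > 0) n_confirmed / n_matches else NA_real_
  recall <- if (n_positive > 0) n_confirmed / n_positive else NA_real_
  paper_ratio <- if (n_positive > 0) n_matches / n_positive else NA_real_
  structure(list(n_matches = n_matches, n_confirmed = n_confirmed,
                 n_positive = n_positive, precision = precision,
                 recall = recall, paper_ratio = paper_ratio),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("Matcher evaluation: %d matched, %d confirmed, %d gold-positive\n",
              x$n_matches, x$n_confirmed, x$n_positive))
  cat(sprintf("  precision %s  recall %s  (matches/positives ratio %s)\n",
              fmt(x$precision), fmt(x$recall), fmt(x$paper_ratio)))
  invisible(x)
}

#' Evaluate a matcher on a labelled sample
#'
#' The evaluation unit is the narrative (consultation): a narrative with at
#' least one hit counts once. Precision is confirmed matched narratives over
#' matched narratives; recall is confirmed matched narratives over
#' gold-positive narratives. Undefined quantities (no matches, or no
#' positives) are reported as `NA`, never as 0. The literal
#' matches-over-true-positives ratio is reported as a secondary field
#' `paper_ratio` (it can exceed 1 in the presence of false positives).
#'
#' @param matcher a [compile_matcher()] result.
#' @param sample data.frame with columns `narrative` and logical `gold`.
#' @return object of class `eval_report`.
#' @export
evaluate_matcher <- function(matcher, sample) {
  stopifnot(nrow(sample) > 0, all(c("narrative", "gold") %in% names(sample)))
  matched <- narrative_match_flags(matcher, sample$narrative)
  new_eval_report(sum(matched), sum(matched & sample$gold), sum(sample$gold))
}

#' Per-component matcher evaluation
#'
#' Evaluates each pattern component (disease mentions, test results,
#' diet/treatment references) separately and in union. The union's recall is
#' always at least each component's recall.
#'
#' @inheritParams evaluate_matcher
#' @return list with `components` (named list of `eval_report`) and
#'   `combined`.
#' @export
component_analysis <- function(matcher, sample) {
  stopifnot(nrow(sample) > 0)
  comps <- unique(matcher$patterns$component)
  reports <- lapply(comps, function(comp) {
    matched <- narrative_match_flags(matcher, sample$narrative, components = comp)
    new_eval_report(sum(matched), sum(matched & sample$gold), sum(sample$gold))
  })
  names(reports) <- comps
  list(components = reports, combined = evaluate_matcher(matcher, sample))
}
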