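# Case definitions: test-result threshold rules, parsing analyte values out
# of narratives, and the rule-based removal of matches that sit next to a
# normal test result.

#' Test-result threshold rule
#'
#' A case-definition rule of the form "analyte strictly above/below
#' threshold". Comparisons are strict: boundary values count as normal.
#' Thresholds are interpreted on the scales conventionally written in UK
#' small-animal records (creatinine in umol/l, ALT in iu/l, SDMA in ug/dl,
#' urine specific gravity unitless, UPC unitless); no unit conversion is
#' attempted.
#'
#' @param analyte analyte name.
#' @param direction `"above"` (abnormal when value > threshold) or
#'   `"below"` (abnormal when value < threshold).
#' @param threshold finite numeric threshold.
#' @param aliases lowercase surface forms found in narratives.
#' @return object of class `test_result_rule`.
#' @export
test_result_rule <- function(analyte, direction = c("above", "below"),
                             threshold, aliases = analyte) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (any(aliases != tolower(aliases))) stopf("aliases must be lowercase")
  structure(list(analyte = analyte, direction = direction,
                 threshold = threshold, aliases = aliases),
            class = "test_result_rule")
}

#' @export
print.test_result_rule <- function(x, ...) {
  cat(sprintf("%s %s %s (aliases: %s)\n", x$analyte,
              if (x$direction == "above") ">" else "<",
              format(x$threshold), paste(x$aliases, collapse = ", ")))
  invisible(x)
}

#' Default case-definition threshold rules
#'
#' Renal insufficiency: urine specific gravity < 1.030, creatinine > 125,
#' SDMA > 14, UPC > 0.5. Hepatopathy: ALT > 150 iu/l. The elevated-bile-acids
#' clause of the hepatopathy definition carries no numeric threshold and is
#' handled as a disease-mention term, not a threshold rule.
#'
#' @param ae `"renal_insufficiency"` or `"hepatopathy"`.
#' @return list of [test_result_rule()]s.
#' @export
default_test_rules <- function(ae = c("renal_insufficiency", "hepatopathy")) {
  ae <- match.arg(ae)
  if (ae == "renal_insufficiency") {
    list(
      test_result_rule("specific_gravity", "below", 1.030,
                       c("specific gravity", "usg", "sg")),
      test_result_rule("creatinine", "above", 125, c("creatinine", "creat")),
      test_result_rule("sdma", "above", 14, "sdma"),
      test_result_rule("upc", "above", 0.5, c("upc", "protein creatinine ratio"))
    )
  } else {
    list(test_result_rule("alt", "above", 150, c("alt", "alanine aminotransferase")))
  }
}

#' Extract analyte observations from a narrative
#'
#' For every alias occurrence (case-insensitive, on word boundaries) the
#' nearest number within `window` characters to the right is parsed (decimal
#' comma or point; trailing units ignored). Alias occurrences with no
#' parseable number yield no observation.
#'
#' @param narrative a single character string.
#' @param rules list of [test_result_rule()]s.
#' @param window characters scanned rightward of the alias (default 30).
#' @return data.frame with columns `analyte`, `alias`, `value`, `start0`,
#'   `end0` (0-based half-open span of the parsed number) and
#'   `alias_start0`, `alias_end0`.
#' @export
extract_test_results <- function(narrative, rules, window = 30) {
  out <- data.frame(analyte = character(), alias = character(),
                    value = numeric(), start0 = integer(), end0 = integer(),
                    alias_start0 = integer(), alias_end0 = integer(),
                    stringsAsFactors = FALSE)
  if (is.na(narrative) || !nzchar(narrative)) return(out)
  rows <- list()
  for (rule in rules) {
    for (alias in rule$aliases) {
      rx <- paste0("(?i)(?<![a-z0-9])",
                   gsub(" +", "[ _]+", regex_escape(alias)),
                   "(?![a-z0-9])")
      m <- gregexpr(rx, narrative, perl = TRUE)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (k in seq_along(m)) {
        a_start <- as.integer(m[k])             # 1-based
        a_end <- a_start + lens[k] - 1L
        right <- substr(narrative, a_end + 1L, a_end + window)
        num <- regexpr("[0-9]+([.,][0-9]+)?", right, perl = TRUE)
        if (num == -1) next
        txt <- substr(right, num, num + attr(num, "match.length") - 1L)
        val <- suppressWarnings(as.numeric(sub(",", ".", txt, fixed = TRUE)))
        if (is.na(val)) next
        n_start <- a_end + as.integer(num)      # 1-based start of the number
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = rule$analyte, alias = alias, value = val,
          start0 = n_start - 1L,
          end0 = n_start - 1L + attr(num, "match.length"),
          alias_start0 = a_start - 1L, alias_end0 = a_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  res <- res[order(res$alias_start0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Is an analyte observation abnormal?
#'
#' Strictly beyond the rule's threshold in the rule's direction; boundary
#' values are normal.
#'
#' @param obs a list/data.frame row with `analyte` and `value`.
#' @param rule a [test_result_rule()] for the same analyte.
#' @return logical.
#' @export
is_abnormal <- function(obs, rule) {
  if (!identical(as.character(obs$analyte), rule$analyte)) {
    stopf("observation analyte '%s' does not match rule analyte '%s'",
          obs$analyte, rule$analyte)
  }
  if (rule$direction == "above") obs$value > rule$threshold
  else obs$value < rule$threshold
}

#' Remove matches associated with normal test results
#'
#' A match with component `test_result` is removed if and only if an analyte
#' observation overlapping its span parses to a normal value; matches whose
#' value is abnormal, or has no parseable value, pass through (conservative).
#' Matches of other components are never touched; the output is always a
#' subset of the input.
#'
#' @param matches a [match_narrative()] result for this narrative.
#' @param narrative the narrative the matches came from.
#' @param rules list of [test_result_rule()]s.
#' @param window passed to [extract_test_results()].
#' @return the filtered matches data.frame.
#' @export
filter_normal_results <- function(matches, narrative, rules, window = 30) {
  if (!nrow(matches)) return(matches)
  is_test <- matches$component == "test_result"
  if (!any(is_test)) return(matches)
  obs <- extract_test_results(narrative, rules, window = window)
  rule_by_analyte <- stats::setNames(rules, vapply(rules, `[[`, "", "analyte"))
  drop <- logical(nrow(matches))
  for (i in which(is_test)) {
    ov <- obs[obs$alias_start0 < matches$end0[i] &
                obs$alias_end0 > matches$start0[i], , drop = FALSE]
    if (!nrow(ov)) next
    abnormal <- vapply(seq_len(nrow(ov)), function(j) {
      is_abnormal(ov[j, ], rule_by_analyte[[ov$analyte[j]]])
    }, logical(1))
    if (!any(abnormal)) drop[i] <- TRUE
  }
  out <- matches[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an animal as a case
#'
#' An animal is a case if at least one match survives windowing and
#' normal-result filtering across its consultations, counted once per
#' animal.
#'
#' @param consult_matches a match data.frame, or a list of match data.frames
#'   (one per consultation).
#' @return logical.
#' @export
classify_case <- function(consult_matches) {
  if (is.data.frame(consult_matches)) return(nrow(consult_matches) > 0)
  any(vapply(consult_matches, nrow, integer(1)) > 0)
}

# Case flags for a vector of narratives: a narrative is case-qualifying if it
# has a surviving match after normal-result filtering. Non-test components
# are decided by fast grepl; only narratives whose sole hits are test_result
# patterns need the full match + filter path.
narrative_case_flags <- function(matcher, narratives, rules = NULL, window = 30) {
  if (is.null(rules)) return(narrative_match_flags(matcher, narratives))
  comps <- unique(matcher$patterns$component)
  flags <- narrative_match_flags(matcher, narratives,
                                 components = setdiff(comps, "test_result"))
  if (!"test_result" %in% comps) return(flags)
  cand <- !flags & narrative_match_flags(matcher, narratives,
                                         components = "test_result")
  for (i in which(cand)) {
    m <- match_narrative(matcher, narratives[i])
    m <- filter_normal_results(m, narratives[i], rules, window = window)
    flags[i] <- classify_case(m)
  }
  flags
}
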