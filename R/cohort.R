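# Exposure identification, the staged exclusion cascade, follow-up windows
# and history truncation.

utils::globalVariables(c("animal_id", "index_date", "data_unavailable",
                         "narrative", "date", "active_substance", "..need"))

#' Exposure cohort specification
#'
#' @param product_label label of the product of interest.
#' @param active_substances mapped active substances identifying the product.
#' @param allowed_dosage_forms dosage forms belonging to this product (names
#'   from the dosage-form pattern set, e.g. `"tablet"`).
#' @param data_lock_date latest admissible index prescription date.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(product_label, active_substances, allowed_dosage_forms,
                        data_lock_date) {
  if (!length(active_substances)) stopf("active_substances must be non-empty")
  lock <- as.Date(data_lock_date)
  if (is.na(lock)) stopf("data_lock_date is not a valid date")
  structure(list(product_label = product_label,
                 active_substances = tolower(active_substances),
                 allowed_dosage_forms = allowed_dosage_forms,
                 data_lock_date = lock),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec '%s': substances %s; forms %s; lock %s\n",
              x$product_label, paste(x$active_substances, collapse = ", "),
              paste(x$allowed_dosage_forms, collapse = ", "),
              format(x$data_lock_date)))
  invisible(x)
}

#' Dosage-form classification patterns
#'
#' The raw product description is not a standardized field, so dosage forms
#' are recognised with editable regular-expression rules. The shipped
#' defaults cover the common UK small-animal presentation wordings; pass a
#' JSON file of `{form: pattern}` to customise.
#'
#' @param path optional JSON file; default uses the patterns shipped with the
#'   package.
#' @return named character vector of patterns.
#' @export
dosage_form_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dosage_form_patterns.json", package = "vetaemine")
  }
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Classify dosage forms from raw product descriptions
#'
#' @param descriptions character vector of raw product descriptions.
#' @param patterns named pattern vector, see [dosage_form_patterns()].
#' @return character vector: a form name, `"unknown"` (no pattern matched) or
#'   `"ambiguous"` (several matched).
#' @export
classify_dosage_form <- function(descriptions, patterns = dosage_form_patterns()) {
  d <- tolower(descriptions)
  hit <- vapply(patterns, function(p) grepl(p, d, perl = TRUE),
                logical(length(d)))
  if (length(d) == 1) hit <- matrix(hit, nrow = 1)
  nhit <- rowSums(hit)
  out <- rep("unknown", length(d))
  one <- nhit == 1
  out[one] <- names(patterns)[apply(hit[one, , drop = FALSE], 1, which.max)]
  out[nhit > 1] <- "ambiguous"
  out
}

#' Identify index prescriptions for a product
#'
#' Filters treatment records to the specification's active substances,
#' classifies each record's dosage form from the raw product description,
#' drops records of other or unrecognised forms, and removes animals with an
#' ambiguous-form qualifying record entirely (the specific product cannot be
#' identified). Each remaining animal's earliest event is its index
#' prescription; animals whose earliest event postdates the data lock date
#' are excluded.
#'
#' @param treatments data.frame with columns `animal_id`, `date`,
#'   `product_description`, `active_substance`.
#' @param spec a [cohort_spec()].
#' @param patterns dosage-form patterns, see [dosage_form_patterns()].
#' @return data.frame of exposure events: `animal_id`, `index_date`,
#'   `product_label` (one row per animal).
#' @export
identify_exposures <- function(treatments, spec, patterns = dosage_form_patterns()) {
  need <- c("animal_id", "date", "product_description", "active_substance")
  miss <- setdiff(need, names(treatments))
  if (length(miss)) stopf("treatments table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  tr <- data.table::as.data.table(treatments)[, ..need]
  tr <- tr[tolower(active_substance) %in% spec$active_substances]
  empty <- data.frame(animal_id = character(), index_date = as.Date(character()),
                      product_label = character(), stringsAsFactors = FALSE)
  if (!nrow(tr)) return(empty)
  form <- classify_dosage_form(tr$product_description, patterns)
  ambiguous_animals <- unique(tr$animal_id[form == "ambiguous"])
  tr <- tr[form %in% spec$allowed_dosage_forms & !(animal_id %in% ambiguous_animals)]
  if (!nrow(tr)) return(empty)
  idx <- tr[, .(index_date = min(date)), by = animal_id]
  idx <- idx[index_date <= spec$data_lock_date]
  if (!nrow(idx)) return(empty)
  out <- data.frame(animal_id = idx$animal_id, index_date = idx$index_date,
                    product_label = spec$product_label, stringsAsFactors = FALSE)
  out[order(out$animal_id), , drop = FALSE]
}

new_cascade_report <- function(label, index_count, data_unavailable,
                               no_post_exposure, pre_existing, crossover,
                               final_count) {
  counts <- c(index_count = index_count, data_unavailable = data_unavailable,
              no_post_exposure = no_post_exposure, pre_existing = pre_existing,
              crossover = crossover, final_count = final_count)
  if (any(counts < 0)) stopf("cascade counts must be non-negative")
  if (index_count != data_unavailable + no_post_exposure + pre_existing +
      crossover + final_count) {
    stopf("cascade counts do not add up for '%s'", label)
  }
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(c(list(label = label), counts), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Exclusion cascade (%s)\n", x$label))
  cat(sprintf("  index prescriptions     %8d\n", x$index_count))
  cat(sprintf("  - data unavailable      %8d\n", x$data_unavailable))
  cat(sprintf("  - no post-exposure data %8d\n", x$no_post_exposure))
  cat(sprintf("  - pre-existing signs    %8d\n", x$pre_existing))
  cat(sprintf("  - product crossover     %8d\n", x$crossover))
  cat(sprintf("  final cohort            %8d\n", x$final_count))
  invisible(x)
}

#' @export
as.data.frame.cascade_report <- function(x, ...) {
  data.frame(label = x$label, index_prescriptions = x$index_count,
             data_unavailable = x$data_unavailable,
             no_post_exposure_data = x$no_post_exposure,
             pre_existing_clinical_signs = x$pre_existing,
             product_crossover = x$crossover, final_cohort = x$final_count,
             stringsAsFactors = FALSE)
}

# Stages 1-3 for one arm; returns the per-stage animal sets.
run_cascade_stages <- function(expo, cons, matcher, rules, window) {
  consA <- cons[expo, on = "animal_id", nomatch = NULL]
  agg <- consA[, .(n = .N, all_unav = all(data_unavailable),
                   any_post = any(!data_unavailable & date > index_date)),
               by = animal_id]
  stage1 <- agg$animal_id[agg$all_unav]
  rem1 <- setdiff(expo$animal_id, stage1)
  has_post <- agg$animal_id[agg$any_post]
  no_post <- setdiff(rem1, has_post)
  rem2 <- setdiff(rem1, no_post)
  if (!is.null(matcher) && length(rem2)) {
    pre <- consA[animal_id %in% rem2 & !data_unavailable & date <= index_date &
                   nzchar(narrative)]
    if (nrow(pre)) {
      flags <- narrative_case_flags(matcher, pre$narrative, rules, window = window)
      pre_ex <- unique(pre$animal_id[flags])
    } else pre_ex <- character()
  } else pre_ex <- character()
  list(data_unavailable = stage1, no_post = no_post, pre_existing = pre_ex,
       survivors = setdiff(rem2, pre_ex))
}

#' Build final cohorts through the exclusion cascade
#'
#' Applies the four exclusion stages in fixed order to both arms: (1)
#' narratives unavailable (every consultation carries the
#' practice-management-system flag), (2) no post-exposure consultation, (3)
#' pre-existing signs (the matcher, plus optional normal-result filtering,
#' fires on a consultation dated on or before the index prescription), (4)
#' product crossover (animals surviving stages 1-3 in both arms are removed
#' from both, so both reports carry the same crossover count). Each animal is
#' counted at its earliest applicable stage or in the final cohort.
#'
#' @param exposed,comparator_exposed [identify_exposures()] results for the
#'   two arms.
#' @param consults consultations data.frame (`consult_id`, `animal_id`,
#'   `date`, `narrative`, `data_unavailable`).
#' @param matcher a [compile_matcher()] result used for the pre-existing
#'   screen; `NULL` skips stage 3.
#' @param rules optional [test_result_rule()] list for normal-result
#'   filtering during the pre-existing screen.
#' @param window character window for value association, see
#'   [extract_test_results()].
#' @return object of class `cohort_build`: per arm a `cohort` data.frame
#'   (`animal_id`, `index_date`) and a `cascade_report`, plus
#'   `crossover_ids`.
#' @export
build_cohort <- function(exposed, comparator_exposed, consults, matcher = NULL,
                         rules = NULL, window = 30) {
  if (anyDuplicated(exposed$animal_id) || anyDuplicated(comparator_exposed$animal_id)) {
    stopf("exposure sets must have one row per animal")
  }
  cons <- data.table::as.data.table(consults)
  ep <- data.table::as.data.table(exposed[, c("animal_id", "index_date")])
  ec <- data.table::as.data.table(comparator_exposed[, c("animal_id", "index_date")])
  sp <- run_cascade_stages(ep, cons, matcher, rules, window)
  sc <- run_cascade_stages(ec, cons, matcher, rules, window)
  crossover <- intersect(sp$survivors, sc$survivors)
  finish <- function(expo, st, label) {
    final_ids <- setdiff(st$survivors, crossover)
    report <- new_cascade_report(label, nrow(expo),
                                 length(st$data_unavailable), length(st$no_post),
                                 length(st$pre_existing), length(crossover),
                                 length(final_ids))
    cohort <- as.data.frame(expo[expo$animal_id %in% final_ids, ])
    list(cohort = cohort[order(cohort$animal_id), , drop = FALSE], report = report)
  }
  structure(list(product = finish(ep, sp, unique(exposed$product_label)[1]),
                 comparator = finish(ec, sc, unique(comparator_exposed$product_label)[1]),
                 crossover_ids = sort(crossover)),
            class = "cohort_build")
}

#' @export
print.cohort_build <- function(x, ...) {
  print(x$product$report)
  print(x$comparator$report)
  invisible(x)
}

#' Follow-up window specification
#'
#' Time-to-onset values (days) from previously submitted AE reports, plus
#' the drug's elimination half-life (days) from its product characteristics.
#' The onset list may be empty only when a half-life is given.
#'
#' @param onset_days non-negative numeric vector (may be empty).
#' @param half_life_days positive scalar or `NULL`.
#' @return object of class `followup_spec`.
#' @export
followup_spec <- function(onset_days = numeric(), half_life_days = NULL) {
  if (length(onset_days) && any(onset_days < 0)) {
    stopf("onset_days must be non-negative")
  }
  if (!is.null(half_life_days) && half_life_days <= 0) {
    stopf("half_life_days must be positive")
  }
  if (!length(onset_days) && is.null(half_life_days)) {
    stopf("either onset_days or half_life_days must be provided")
  }
  structure(list(onset_days = onset_days, half_life_days = half_life_days),
            class = "followup_spec")
}

#' Derive the post-exposure follow-up window
#'
#' The onset-based candidate is `ceiling(median + k * MAD)` of the
#' time-to-onset values (MAD is the raw median absolute deviation, unscaled;
#' the multiplier `k` defaults to 1 and is a package choice, exposed for
#' auditing). The elimination candidate is `ceiling(5 * half_life)`
#' (estimated total elimination). If the drug would remain in the system
#' longer than the median time-to-onset (elimination candidate > median),
#' the elimination candidate is used; otherwise the onset-based candidate.
#'
#' @param spec a [followup_spec()].
#' @param k MAD multiplier for the onset-based candidate.
#' @return object of class `followup_window`: `days` (integer >= 1) and
#'   `rule_used` (`"onset_based"` or `"five_half_lives"`).
#' @export
compute_followup_window <- function(spec, k = 1) {
  stopifnot(inherits(spec, "followup_spec"))
  elim <- if (!is.null(spec$half_life_days)) ceiling(5 * spec$half_life_days) else NULL
  if (!length(spec$onset_days)) {
    days <- elim
    rule <- "five_half_lives"
  } else {
    med <- median(spec$onset_days)
    onset_cand <- ceiling(med + k * median(abs(spec$onset_days - med)))
    if (!is.null(elim) && elim > med) {
      days <- elim
      rule <- "five_half_lives"
    } else {
      days <- onset_cand
      rule <- "onset_based"
    }
  }
  structure(list(days = max(1L, as.integer(days)), rule_used = rule),
            class = "followup_window")
}

#' @export
print.followup_window <- function(x, ...) {
  cat(sprintf("Follow-up window: %d days (%s)\n", x$days, x$rule_used))
  invisible(x)
}

#' Truncate histories to the follow-up window
#'
#' Keeps, per cohort animal, the consultations with `index_date <
#' consult_date <= index_date + days`. Consultations on the index date are
#' treated as pre-exposure (the prescribing visit's presenting signs are not
#' post-exposure AEs). Animals with no consultation in the window keep zero
#' rows but remain cohort members (they stay in the incidence denominator).
#'
#' @param cohort data.frame with `animal_id`, `index_date`.
#' @param consults consultations data.frame.
#' @param window a [compute_followup_window()] result, or an integer number
#'   of days.
#' @return data.frame of retained consultations with `animal_id`,
#'   `index_date`, `consult_id`, `date`, `narrative`, `data_unavailable`.
#' @export
window_histories <- function(cohort, consults, window) {
  days <- if (inherits(window, "followup_window")) window$days else as.integer(window)
  stopifnot(days >= 1)
  cons <- data.table::as.data.table(consults)
  co <- data.table::as.data.table(cohort[, c("animal_id", "index_date")])
  dt <- cons[co, on = "animal_id", nomatch = NULL]
  dt <- dt[date > index_date & date <= index_date + days]
  out <- as.data.frame(dt)
  out[order(out$animal_id, out$date), , drop = FALSE]
}
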