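# End-to-end orchestration: validated table IO, matcher spec files, the full
# exposure -> cascade -> window -> outcome -> risk pipeline, and the run
# manifest.

#' Read and validate EHR tables from a directory
#'
#' Expects `animals.csv`, `consults.csv` and `treatments.csv` with ISO-8601
#' dates. Narrative-unavailable flags are honoured (a missing
#' `data_unavailable` column is derived from empty narratives); duplicate
#' consultation ids are rejected.
#'
#' @param dir directory containing the three CSV files.
#' @return list of validated data.frames `animals`, `consults`,
#'   `treatments`.
#' @export
read_ehr_tables <- function(dir) {
  need <- list(
    animals = c("animal_id", "species", "birth_date"),
    consults = c("consult_id", "animal_id", "date", "narrative"),
    treatments = c("animal_id", "date", "product_description", "active_substance"))
  out <- list()
  for (nm in names(need)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stopf("missing input file: %s", path)
    x <- as.data.frame(data.table::fread(path, colClasses = "character"))
    miss <- setdiff(need[[nm]], names(x))
    if (length(miss)) stopf("%s.csv is missing column(s): %s", nm,
                            paste(miss, collapse = ", "))
    for (col in intersect(c("date", "birth_date"), names(x))) {
      parsed <- as.Date(x[[col]], format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & nzchar(x[[col]]))
      if (length(bad)) stopf("%s.csv: invalid ISO-8601 date in '%s' at row(s) %s",
                             nm, col, paste(head(bad, 5), collapse = ", "))
      x[[col]] <- parsed
    }
    out[[nm]] <- x
  }
  cons <- out$consults
  dup <- unique(cons$consult_id[duplicated(cons$consult_id)])
  if (length(dup)) stopf("consults.csv: duplicate consult_id(s): %s",
                         paste(head(dup, 5), collapse = ", "))
  if ("data_unavailable" %in% names(cons)) {
    cons$data_unavailable <- tolower(cons$data_unavailable) %in% c("true", "1", "yes")
  } else {
    cons$data_unavailable <- is.na(cons$narrative) | !nzchar(cons$narrative)
  }
  cons$narrative[is.na(cons$narrative)] <- ""
  out$consults <- cons
  out
}

#' Write EHR tables to a directory
#'
#' Writes the tables produced by [generate_ehr()] as UTF-8 CSV files with
#' header rows and ISO-8601 dates, the layout [read_ehr_tables()] expects.
#'
#' @param ehr list with `animals`, `consults`, `treatments` (and optionally
#'   `gold_labels`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(ehr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(c("animals", "consults", "treatments", "gold_labels"),
                       names(ehr))) {
    data.table::fwrite(ehr[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Write / read a matcher specification as JSON
#'
#' The JSON carries the AE name, the dictionary entries with provenance and
#' component, and the per-term negative-context exceptions, so the final
#' matcher is versionable and auditable.
#'
#' @param dict an `expanded_dictionary`.
#' @param exceptions exception list as for [compile_matcher()].
#' @param path JSON file path.
#' @return `write_matcher_spec` returns `path` invisibly;
#'   `read_matcher_spec` returns `list(dictionary, exceptions)`.
#' @export
write_matcher_spec <- function(dict, exceptions, path) {
  jsonlite::write_json(list(ae_name = dict$ae_name, entries = dict$entries,
                            exceptions = exceptions),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matcher_spec
#' @export
read_matcher_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(x$entries, stringsAsFactors = FALSE)
  exceptions <- lapply(x$exceptions, function(e) {
    list(before = unlist(e$before), after = unlist(e$after))
  })
  list(dictionary = new_expanded_dictionary(x$ae_name, entries),
       exceptions = exceptions)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full drug-event analysis pipeline
#'
#' Orchestrates: exposure identification for both arms, the exclusion
#' cascade, follow-up windowing, outcome matching with normal-result
#' filtering, case classification, incidence and relative risk (plus the
#' Mantel-Haenszel age-adjusted estimate when `age_breaks` is given). All
#' intermediate tables and a run manifest are persisted to `out_dir`; two
#' runs with the same configuration produce identical outputs apart from
#' manifest timestamps.
#'
#' @param config a named list (or YAML file path) with entries: `ehr_dir`;
#'   `matcher_spec` (path to a matcher JSON, see [write_matcher_spec()]);
#'   `product` and `comparator` ([cohort_spec()] field lists); one of
#'   `window_days` or `followup` (`onset_days`, `half_life_days`, optional
#'   `k`); optional `test_rules` (`"renal_insufficiency"` or
#'   `"hepatopathy"`); optional `age_breaks` (years, cut points for
#'   age-at-index strata); `alpha` (default 0.05); `seed` (default 1);
#'   `out_dir` (optional; no files written when absent).
#' @return object of class `pipeline_result`: cascade reports, case counts,
#'   incidences, `risk` (crude Katz), `risk_mh` (or `NULL`), the results
#'   table and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  started <- Sys.time()
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  ehr <- read_ehr_tables(config$ehr_dir)

  spec_of <- function(x) cohort_spec(x$product_label, x$active_substances,
                                     x$allowed_dosage_forms, x$data_lock_date)
  ms <- read_matcher_spec(config$matcher_spec)
  matcher <- compile_matcher(ms$dictionary, ms$exceptions)
  rules <- if (is.null(config$test_rules)) NULL else default_test_rules(config$test_rules)

  with_seed(seed, {
    expo_p <- identify_exposures(ehr$treatments, spec_of(config$product))
    expo_c <- identify_exposures(ehr$treatments, spec_of(config$comparator))
    cb <- build_cohort(expo_p, expo_c, ehr$consults, matcher, rules)

    window <- if (!is.null(config$window_days)) {
      structure(list(days = as.integer(config$window_days), rule_used = "override"),
                class = "followup_window")
    } else {
      fu <- config$followup
      compute_followup_window(followup_spec(fu$onset_days, fu$half_life_days),
                              k = if (is.null(fu$k)) 1 else fu$k)
    }

    count_cases <- function(cohort) {
      wh <- window_histories(cohort, ehr$consults, window)
      if (!nrow(wh)) return(list(cases = 0L, case_ids = character()))
      flags <- narrative_case_flags(matcher, wh$narrative, rules)
      ids <- unique(wh$animal_id[flags])
      list(cases = length(ids), case_ids = ids)
    }
    res_p <- count_cases(cb$product$cohort)
    res_c <- count_cases(cb$comparator$cohort)
    n_p <- nrow(cb$product$cohort)
    n_c <- nrow(cb$comparator$cohort)

    risk <- if (n_p > 0 && n_c > 0) {
      relative_risk(two_by_two(res_p$cases, n_p - res_p$cases,
                               res_c$cases, n_c - res_c$cases), alpha = alpha)
    } else NULL

    risk_mh <- NULL
    if (!is.null(config$age_breaks) && n_p > 0 && n_c > 0) {
      age_of <- function(cohort) {
        bd <- ehr$animals$birth_date[match(cohort$animal_id, ehr$animals$animal_id)]
        as.numeric(cohort$index_date - bd) / 365.25
      }
      breaks <- c(-Inf, config$age_breaks, Inf)
      strata_of <- function(cohort, case_ids) {
        grp <- cut(age_of(cohort), breaks)
        split(cohort$animal_id %in% case_ids, grp)
      }
      sp <- strata_of(cb$product$cohort, res_p$case_ids)
      sc <- strata_of(cb$comparator$cohort, res_c$case_ids)
      tabs <- lapply(names(sp), function(g) {
        two_by_two(sum(sp[[g]]), sum(!sp[[g]]), sum(sc[[g]]), sum(!sc[[g]]))
      })
      names(tabs) <- names(sp)
      ok <- vapply(tabs, function(tb) (tb$a + tb$b) > 0 && (tb$c + tb$d) > 0,
                   logical(1))
      if (any(ok)) risk_mh <- mh_relative_risk(stratum_set(tabs[ok]), alpha = alpha)
    }

    incidence <- c(product = if (n_p > 0) incidence_per_10k(res_p$cases, n_p) else NA_real_,
                   comparator = if (n_c > 0) incidence_per_10k(res_c$cases, n_c) else NA_real_)
    results_row <- if (!is.null(risk)) {
      format_results_row(res_p$cases, n_p, res_c$cases, n_c, risk)
    } else NULL

    manifest <- list(
      config_hash = config_hash(config),
      input_checksums = as.list(tools::md5sum(
        file.path(config$ehr_dir, c("animals.csv", "consults.csv", "treatments.csv")))),
      software_version = as.character(utils::packageVersion("vetaemine")),
      window_days = window$days, window_rule = window$rule_used,
      counts = list(
        input_rows = list(animals = nrow(ehr$animals), consults = nrow(ehr$consults),
                          treatments = nrow(ehr$treatments)),
        product = unclass(cb$product$report)[-1],
        comparator = unclass(cb$comparator$report)[-1],
        cases = list(product = res_p$cases, comparator = res_c$cases)),
      matches_per_1000 = local({
        narr <- ehr$consults$narrative
        comps <- unique(matcher$patterns$component)
        n <- max(1L, length(narr))
        vals <- lapply(comps, function(cm)
          1000 * sum(narrative_match_flags(matcher, narr, components = cm)) / n)
        stats::setNames(vals, comps)
      }),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

    out <- structure(list(
      cascade = list(product = cb$product$report, comparator = cb$comparator$report),
      crossover_ids = cb$crossover_ids,
      cohorts = list(product = cb$product$cohort, comparator = cb$comparator$cohort),
      cases = list(product = res_p$cases, comparator = res_c$cases),
      incidence = incidence, risk = risk, risk_mh = risk_mh,
      window = window, results = results_row, manifest = manifest),
      class = "pipeline_result")

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      cascade_df <- rbind(as.data.frame(cb$product$report),
                          as.data.frame(cb$comparator$report))
      write.csv(cascade_df, file.path(config$out_dir, "cascade.csv"), row.names = FALSE)
      write.csv(cb$product$cohort, file.path(config$out_dir, "cohort_product.csv"),
                row.names = FALSE)
      write.csv(cb$comparator$cohort, file.path(config$out_dir, "cohort_comparator.csv"),
                row.names = FALSE)
      if (!is.null(results_row)) {
        write.csv(results_row, file.path(config$out_dir, "results.csv"), row.names = FALSE)
      }
      write_json_atomic(manifest, file.path(config$out_dir, "manifest.json"))
    }
    out
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$cascade$product)
  print(x$cascade$comparator)
  cat(sprintf("Cases: product %d / %d, comparator %d / %d\n",
              x$cases$product, x$cascade$product$final_count,
              x$cases$comparator, x$cascade$comparator$final_count))
  cat(sprintf("Incidence per 10,000: product %s, comparator %s\n",
              format(round_half_up(x$incidence[["product"]], 1)),
              format(round_half_up(x$incidence[["comparator"]], 1))))
  if (!is.null(x$risk)) print(x$risk) else cat("Relative risk: undefined\n")
  if (!is.null(x$risk_mh)) print(x$risk_mh)
  invisible(x)
}
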