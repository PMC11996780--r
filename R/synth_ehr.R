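# Synthetic EHR generator: animals, consultations with free-text narratives,
# treatment records and gold labels for every planted adverse-event mention.
# Everything downstream (embedding expansion, matching, cohort building, risk
# estimation) is testable against this known ground truth.

#' Configuration for the synthetic EHR generator
#'
#' Defines the generative conditions: cohort sizes, exposure assignment,
#' planted adverse-event (AE) mention rates, narrative corruption and the
#' synthetic calendar. The defaults describe a mid-sized first-opinion
#' dataset with a moderately common AE; see the methods vignette for the
#' rationale behind each value.
#'
#' @param n_animals number of animals (non-negative integer).
#' @param species_mix named proportions summing to 1.
#' @param age_dist `c(mean, sd)` of age in years at the calendar start.
#' @param consults_per_animal Poisson mean for background consultations.
#' @param product_assignments named length-2 probability vector: the first
#'   element is the product of interest, the second the comparator; the
#'   remainder of animals are unexposed.
#' @param planted_ae_rate probability that an exposed, followed-up animal has
#'   a planted AE mention after exposure. A scalar applies to both arms; a
#'   named length-2 vector `c(product=, comparator=)` sets them separately.
#' @param pre_existing_rate probability of a planted AE mention before the
#'   index prescription.
#' @param misspelling_rate probability a planted term is corrupted by one
#'   character-level edit (see [corrupt_term()]).
#' @param confound_rate probability a narrative carries a benign homograph
#'   phrase such as "fit and well".
#' @param crossover_fraction probability an exposed animal also receives the
#'   other product.
#' @param dropout_fraction probability an exposed animal has no consultation
#'   after its index prescription (lost to follow-up).
#' @param unavailable_fraction probability an animal's practice management
#'   system does not share narratives (all its consultations flagged).
#' @param test_result_rate probability a narrative carries an incidental
#'   normal test-result sentence.
#' @param ae_name,ae_terms the AE being planted and its surface terms.
#' @param ae_analytes optional analyte names; when given, `ae_test_fraction`
#'   of planted AE mentions are rendered as abnormal test results instead of
#'   term mentions.
#' @param ae_test_fraction see `ae_analytes`.
#' @param test_result_dists per-analyte list of `list(normal=c(mean,sd),
#'   abnormal=c(mean,sd))` value distributions.
#' @param product_label,comparator_label product labels used in treatment
#'   records; active substances are derived from them.
#' @param calendar_start,calendar_end synthetic calendar bounds (ISO dates).
#' @param rng_seed integer seed; identical configs are byte-reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_animals = 1000,
                         species_mix = c(dog = 0.8, cat = 0.2),
                         age_dist = c(mean = 6, sd = 3),
                         consults_per_animal = 4,
                         product_assignments = c(product = 0.25, comparator = 0.35),
                         planted_ae_rate = 0.04,
                         pre_existing_rate = 0.01,
                         misspelling_rate = 0.15,
                         confound_rate = 0.05,
                         crossover_fraction = 0.02,
                         dropout_fraction = 0.2,
                         unavailable_fraction = 0.1,
                         test_result_rate = 0.05,
                         ae_name = "convulsions",
                         ae_terms = c("seizure", "convulsion", "fit", "collapse", "twitching"),
                         ae_analytes = NULL,
                         ae_test_fraction = 0.2,
                         test_result_dists = default_test_result_dists(),
                         product_label = "VMP-X",
                         comparator_label = "COMP-X",
                         calendar_start = "2015-01-01",
                         calendar_end = "2019-12-31",
                         rng_seed = 1L) {
  if (!is.numeric(n_animals) || length(n_animals) != 1 || n_animals < 0 ||
      n_animals != floor(n_animals)) {
    stopf("n_animals must be a non-negative integer")
  }
  if (abs(sum(species_mix) - 1) > 1e-9) stopf("species_mix must sum to 1")
  if (length(planted_ae_rate) == 1) {
    planted_ae_rate <- c(product = unname(planted_ae_rate),
                         comparator = unname(planted_ae_rate))
  }
  probs <- list(planted_ae_rate = planted_ae_rate,
                pre_existing_rate = pre_existing_rate,
                misspelling_rate = misspelling_rate,
                confound_rate = confound_rate,
                crossover_fraction = crossover_fraction,
                dropout_fraction = dropout_fraction,
                unavailable_fraction = unavailable_fraction,
                test_result_rate = test_result_rate,
                ae_test_fraction = ae_test_fraction,
                product_assignments = product_assignments,
                species_mix = species_mix)
  for (nm in names(probs)) {
    if (!is_probability(probs[[nm]])) stopf("%s must be a probability in [0, 1]", nm)
  }
  if (sum(product_assignments) > 1 + 1e-9) {
    stopf("product_assignments must sum to at most 1")
  }
  cfg <- list(n_animals = as.integer(n_animals), species_mix = species_mix,
              age_dist = age_dist, consults_per_animal = consults_per_animal,
              product_assignments = product_assignments,
              planted_ae_rate = planted_ae_rate,
              pre_existing_rate = pre_existing_rate,
              misspelling_rate = misspelling_rate, confound_rate = confound_rate,
              crossover_fraction = crossover_fraction,
              dropout_fraction = dropout_fraction,
              unavailable_fraction = unavailable_fraction,
              test_result_rate = test_result_rate, ae_name = ae_name,
              ae_terms = ae_terms, ae_analytes = ae_analytes,
              ae_test_fraction = ae_test_fraction,
              test_result_dists = test_result_dists,
              product_label = product_label, comparator_label = comparator_label,
              calendar_start = as.Date(calendar_start),
              calendar_end = as.Date(calendar_end),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Default per-analyte value distributions
#'
#' Normal/abnormal value distributions on the scales used in UK small-animal
#' practice: creatinine in umol/l, ALT in iu/l, urine specific gravity (usg),
#' SDMA in ug/dl and urine protein:creatinine ratio (upc).
#'
#' @return named list of `list(normal=c(mean,sd), abnormal=c(mean,sd))`.
#' @export
default_test_result_dists <- function() {
  list(
    creatinine = list(normal = c(90, 15), abnormal = c(250, 60)),
    alt        = list(normal = c(60, 25), abnormal = c(420, 150)),
    usg        = list(normal = c(1.042, 0.006), abnormal = c(1.014, 0.006)),
    sdma       = list(normal = c(10, 2), abnormal = c(24, 5)),
    upc        = list(normal = c(0.2, 0.1), abnormal = c(1.6, 0.6))
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic EHR configuration\n")
  cat(sprintf("  animals: %d  seed: %d  calendar: %s to %s\n", x$n_animals,
              x$rng_seed, format(x$calendar_start), format(x$calendar_end)))
  cat(sprintf("  exposure: %s %.3f / %s %.3f  crossover %.3f  dropout %.3f\n",
              x$product_label, x$product_assignments[1], x$comparator_label,
              x$product_assignments[2], x$crossover_fraction, x$dropout_fraction))
  cat(sprintf("  planted %s rate: product %.3f, comparator %.3f (pre-existing %.3f)\n",
              x$ae_name, x$planted_ae_rate[["product"]],
              x$planted_ae_rate[["comparator"]], x$pre_existing_rate))
  invisible(x)
}

#' Corrupt a term with a single character-level edit
#'
#' With probability `rate` applies exactly one edit, chosen among character
#' substitution, deletion, adjacent transposition and character doubling, at
#' a position drawn from R's RNG; otherwise returns the term unchanged. The
#' result is always non-empty and, when an edit is applied, differs from the
#' input and lies at (Damerau-Levenshtein) edit distance 1.
#'
#' @param term non-empty character scalar.
#' @param rate corruption probability in \[0, 1\].
#' @return character scalar.
#' @export
corrupt_term <- function(term, rate) {
  if (!is.character(term) || length(term) != 1 || nchar(term) < 1) {
    stopf("term must be a non-empty string")
  }
  if (rate <= 0 || runif(1) >= rate) return(term)
  chars <- strsplit(term, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ops <- c("substitution", "deletion", "transposition", "doubling")
  if (n == 1) ops <- c("substitution", "doubling")
  if (n >= 2 && !any(chars[-n] != chars[-1])) ops <- setdiff(ops, "transposition")
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  i <- if (n == 1) 1L else sample.int(n, 1)
  if (op == "substitution") {
    pool <- setdiff(letters, chars[i])
    chars[i] <- pool[sample.int(length(pool), 1)]
  } else if (op == "deletion") {
    chars <- chars[-i]
  } else if (op == "transposition") {
    idx <- which(chars[-n] != chars[-1])
    i <- idx[sample.int(length(idx), 1)]
    chars[c(i, i + 1)] <- chars[c(i + 1, i)]
  } else { # doubling
    chars <- append(chars, chars[i], after = i)
  }
  paste(chars, collapse = "")
}

# Load the shipped narrative templates, split by type.
narrative_templates <- function() {
  path <- system.file("extdata", "narrative_templates.tsv", package = "vetaemine")
  tpl <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  split(tpl$template, tpl$type)
}

draw_test_value <- function(dists, analyte, abnormal, n = 1) {
  d <- dists[[analyte]][[if (abnormal) "abnormal" else "normal"]]
  v <- rnorm(n, d[1], d[2])
  if (analyte == "usg") sprintf("%.3f", pmax(1.001, v)) else sprintf("%.1f", pmax(0, v))
}

#' Generate a synthetic EHR dataset
#'
#' Produces animals, consultations (with free-text narratives), treatment
#' records and a gold-label table recording every planted AE mention and
#' every planted benign confound, so that matcher precision/recall and
#' cohort-level incidence are checkable against ground truth.
#'
#' @param config a [synth_config()].
#' @return list with data.frames `animals` (animal_id, species, birth_date),
#'   `consults` (consult_id, animal_id, date, narrative, data_unavailable),
#'   `treatments` (animal_id, date, product_description, active_substance)
#'   and `gold_labels` (animal_id, consult_id, ae_name, is_true_mention,
#'   planted_term, phase).
#' @export
generate_ehr <- function(config) {
  if (!inherits(config, "synth_config")) stopf("config must be a synth_config")
  with_seed(config$rng_seed, generate_ehr_impl(config))
}

generate_ehr_impl <- function(cfg) {
  empty <- function() list(
    animals = data.frame(animal_id = character(), species = character(),
                         birth_date = as.Date(character())),
    consults = data.frame(consult_id = character(), animal_id = character(),
                          date = as.Date(character()), narrative = character(),
                          data_unavailable = logical()),
    treatments = data.frame(animal_id = character(), date = as.Date(character()),
                            product_description = character(),
                            active_substance = character()),
    gold_labels = data.frame(animal_id = character(), consult_id = character(),
                             ae_name = character(), is_true_mention = logical(),
                             planted_term = character(), phase = character()))
  n <- cfg$n_animals
  if (n == 0) return(empty())

  tpl <- narrative_templates()
  days <- as.integer(cfg$calendar_end - cfg$calendar_start)
  ids <- sprintf("A%06d", seq_len(n))
  species <- sample(names(cfg$species_mix), n, replace = TRUE, prob = cfg$species_mix)
  age <- pmax(0.1, rnorm(n, cfg$age_dist[["mean"]], cfg$age_dist[["sd"]]))
  birth <- cfg$calendar_start - round(age * 365.25)
  animals <- data.frame(animal_id = ids, species = species, birth_date = birth,
                        stringsAsFactors = FALSE)

  p1 <- cfg$product_assignments[[1]]
  p2 <- cfg$product_assignments[[2]]
  u <- runif(n)
  arm <- ifelse(u < p1, "product", ifelse(u < p1 + p2, "comparator", "none"))
  exposed <- arm != "none"
  index_off <- rep(NA_integer_, n)
  index_off[exposed] <- sample.int(days - 60L, sum(exposed), replace = TRUE) + 30L
  index_date <- cfg$calendar_start + index_off
  crossover <- exposed & runif(n) < cfg$crossover_fraction
  dropout <- exposed & runif(n) < cfg$dropout_fraction
  unavailable <- runif(n) < cfg$unavailable_fraction

  substance <- function(label) paste0(tolower(gsub("[^A-Za-z0-9]", "", label)), "_substance")
  labels <- c(product = cfg$product_label, comparator = cfg$comparator_label)
  other <- c(product = "comparator", comparator = "product")

  # Treatments: one index record per exposure; crossover animals also get the
  # other product at an independent date.
  tr_idx <- which(exposed)
  treatments <- data.frame(
    animal_id = ids[tr_idx],
    date = index_date[tr_idx],
    product_description = paste(labels[arm[tr_idx]], "50 mg tablets"),
    active_substance = substance(labels[arm[tr_idx]]),
    stringsAsFactors = FALSE)
  co_idx <- which(crossover)
  if (length(co_idx)) {
    co_date <- cfg$calendar_start + sample.int(days - 60L, length(co_idx), replace = TRUE) + 30L
    treatments <- rbind(treatments, data.frame(
      animal_id = ids[co_idx], date = co_date,
      product_description = paste(labels[other[arm[co_idx]]], "50 mg tablets"),
      active_substance = substance(labels[other[arm[co_idx]]]),
      stringsAsFactors = FALSE))
  }

  # Consultations: background visits at uniform dates, plus a prescribing
  # visit on the index date, plus (unless lost to follow-up) a post-exposure
  # visit at a geometric gap, plus a pre-exposure visit when a pre-existing
  # mention is planted.
  n_bg <- rpois(n, cfg$consults_per_animal)
  bg_animal <- rep.int(seq_len(n), n_bg)
  bg <- data.frame(animal = bg_animal,
                   off = sample.int(days + 1L, length(bg_animal), replace = TRUE) - 1L,
                   kind = "background", stringsAsFactors = FALSE)
  idx_rows <- data.frame(animal = which(exposed), off = index_off[exposed],
                         kind = "index", stringsAsFactors = FALSE)
  post_ids <- which(exposed & !dropout)
  post <- if (length(post_ids)) {
    data.frame(animal = post_ids,
               off = pmin(days, index_off[post_ids] + 1L + rgeom(length(post_ids), 0.2)),
               kind = "post", stringsAsFactors = FALSE)
  } else data.frame(animal = integer(), off = integer(), kind = character())
  pre_flag <- exposed & runif(n) < cfg$pre_existing_rate
  pre_ids <- which(pre_flag)
  pre <- if (length(pre_ids)) {
    data.frame(animal = pre_ids,
               off = pmax(0L, index_off[pre_ids] - 1L - rgeom(length(pre_ids), 0.2)),
               kind = "pre", stringsAsFactors = FALSE)
  } else data.frame(animal = integer(), off = integer(), kind = character())
  cons <- rbind(bg, idx_rows, post, pre)
  # dropout: no consultation after the index prescription
  drop_row <- dropout[cons$animal] & !is.na(index_off[cons$animal]) &
    cons$off > index_off[cons$animal]
  cons <- cons[!drop_row, , drop = FALSE]
  cons <- cons[order(cons$animal, cons$off, cons$kind), , drop = FALSE]
  rownames(cons) <- NULL
  m <- nrow(cons)
  cons$consult_id <- sprintf("C%07d", seq_len(m))

  # Narratives
  narrative <- sample(tpl$base, m, replace = TRUE)
  gl <- list()
  plant_rate <- cfg$planted_ae_rate[arm[post_ids]]
  plant <- runif(length(post_ids)) < plant_rate
  plant_rows <- match(post_ids[plant], ifelse(cons$kind == "post", cons$animal, NA))
  plant_mention <- function(rows, phase) {
    if (!length(rows)) return(NULL)
    use_test <- !is.null(cfg$ae_analytes) &
      runif(length(rows)) < cfg$ae_test_fraction
    out <- data.frame(row = rows, term = NA_character_, stringsAsFactors = FALSE)
    for (j in seq_along(rows)) {
      r <- rows[j]
      if (use_test[j]) {
        analyte <- sample(cfg$ae_analytes, 1)
        val <- draw_test_value(cfg$test_result_dists, analyte, abnormal = TRUE)
        sent <- sub("{analyte}", analyte, sample(tpl$test, 1), fixed = TRUE)
        sent <- sub("{value}", val, sent, fixed = TRUE)
        out$term[j] <- paste(analyte, val)
      } else {
        term <- corrupt_term(sample(cfg$ae_terms, 1), cfg$misspelling_rate)
        sent <- sub("{term}", term, sample(tpl$ae, 1), fixed = TRUE)
        out$term[j] <- term
      }
      narrative[r] <<- paste0(narrative[r], ". ", sent)
    }
    data.frame(animal_id = ids[cons$animal[rows]], consult_id = cons$consult_id[rows],
               ae_name = cfg$ae_name, is_true_mention = TRUE,
               planted_term = out$term, phase = phase, stringsAsFactors = FALSE)
  }
  gl$post <- plant_mention(plant_rows, "post")
  pre_rows <- which(cons$kind == "pre")
  gl$pre <- plant_mention(pre_rows, "pre")

  # benign confound phrases
  conf_rows <- which(runif(m) < cfg$confound_rate)
  if (length(conf_rows)) {
    phrases <- sample(tpl$confound, length(conf_rows), replace = TRUE)
    narrative[conf_rows] <- paste0(narrative[conf_rows], ". ", phrases)
    gl$confound <- data.frame(animal_id = ids[cons$animal[conf_rows]],
                              consult_id = cons$consult_id[conf_rows],
                              ae_name = cfg$ae_name, is_true_mention = FALSE,
                              planted_term = phrases, phase = "confound",
                              stringsAsFactors = FALSE)
  }

  # incidental normal test results
  tr_rows <- which(runif(m) < cfg$test_result_rate)
  if (length(tr_rows)) {
    analytes <- sample(names(cfg$test_result_dists), length(tr_rows), replace = TRUE)
    vals <- vapply(analytes, function(a) draw_test_value(cfg$test_result_dists, a, FALSE),
                   character(1))
    sents <- sample(tpl$test, length(tr_rows), replace = TRUE)
    sents <- mapply(function(s, a, v) sub("{value}", v, sub("{analyte}", a, s, fixed = TRUE),
                                          fixed = TRUE),
                    sents, analytes, vals, USE.NAMES = FALSE)
    narrative[tr_rows] <- paste0(narrative[tr_rows], ". ", sents)
    gl$test_normal <- data.frame(animal_id = ids[cons$animal[tr_rows]],
                                 consult_id = cons$consult_id[tr_rows],
                                 ae_name = cfg$ae_name, is_true_mention = FALSE,
                                 planted_term = paste(analytes, vals),
                                 phase = "test_normal", stringsAsFactors = FALSE)
  }

  unav_row <- unavailable[cons$animal]
  narrative[unav_row] <- ""
  consults <- data.frame(consult_id = cons$consult_id, animal_id = ids[cons$animal],
                         date = cfg$calendar_start + cons$off, narrative = narrative,
                         data_unavailable = unav_row, stringsAsFactors = FALSE)
  gold <- do.call(rbind, gl[!vapply(gl, is.null, logical(1))])
  if (is.null(gold)) gold <- empty()$gold_labels
  rownames(gold) <- NULL
  list(animals = animals, consults = consults,
       treatments = treatments[order(treatments$animal_id, treatments$date), ],
       gold_labels = gold)
}

#' Build EHR tables engineered to an exact exclusion cascade
#'
#' Constructs a minimal two-arm dataset in which every animal is designed to
#' fall at one specific cascade stage: flagged-unavailable narratives, no
#' post-exposure consultation, a pre-existing AE mention, product crossover,
#' or the final cohort. Feeding the result through [identify_exposures()] and
#' [build_cohort()] must reproduce the requested stage counts exactly, which
#' makes the cascade arithmetic auditable at any scale.
#'
#' @param product_counts,comparator_counts named lists/vectors with entries
#'   `unavailable`, `no_post`, `pre_existing`, `crossover`, `final`. The
#'   `crossover` entries must be equal (the same animals are removed from
#'   both arms).
#' @param ae_term the term planted in pre-existing narratives.
#' @param product_label,comparator_label product labels.
#' @param start ISO date used as the common index date.
#' @return list of `animals`, `consults`, `treatments` data.frames plus the
#'   two [cohort_spec()]s (`product_spec`, `comparator_spec`).
#' @export
make_cascade_fixture <- function(product_counts, comparator_counts,
                                 ae_term = "seizure",
                                 product_label = "VMP-X",
                                 comparator_label = "COMP-X",
                                 start = "2016-06-01") {
  need <- c("unavailable", "no_post", "pre_existing", "crossover", "final")
  pc <- as.list(product_counts); cc <- as.list(comparator_counts)
  if (!all(need %in% names(pc)) || !all(need %in% names(cc))) {
    stopf("counts must name: %s", paste(need, collapse = ", "))
  }
  if (pc$crossover != cc$crossover) stopf("crossover counts must be equal in both arms")
  d0 <- as.Date(start)
  substance <- function(label) paste0(tolower(gsub("[^A-Za-z0-9]", "", label)), "_substance")

  build_arm <- function(counts, prefix, label) {
    nm <- function(k, n) if (n > 0) sprintf("%s%07d", k, seq_len(n)) else character()
    id_unav <- nm(paste0(prefix, "U"), counts$unavailable)
    id_nop  <- nm(paste0(prefix, "N"), counts$no_post)
    id_pre  <- nm(paste0(prefix, "P"), counts$pre_existing)
    id_fin  <- nm(paste0(prefix, "F"), counts$final)
    own <- c(id_unav, id_nop, id_pre, id_fin)
    consults <- data.table::data.table(
      animal_id = c(id_unav, id_nop, id_pre, id_pre, id_fin),
      date = c(rep(d0 + 3, length(id_unav)), rep(d0, length(id_nop)),
               rep(d0 - 10, length(id_pre)), rep(d0 + 5, length(id_pre)),
               rep(d0 + 5, length(id_fin))),
      narrative = c(rep("", length(id_unav)),
                    rep("routine visit, no concerns", length(id_nop)),
                    rep(paste0("owner reports ", ae_term, " at home"), length(id_pre)),
                    rep("routine visit, no concerns", length(id_pre)),
                    rep("routine visit, no concerns", length(id_fin))),
      data_unavailable = c(rep(TRUE, length(id_unav)),
                           rep(FALSE, length(id_nop) + 2 * length(id_pre) + length(id_fin))))
    treatments <- data.table::data.table(
      animal_id = own, date = d0,
      product_description = paste(label, "50 mg tablets"),
      active_substance = substance(label))
    list(ids = own, consults = consults, treatments = treatments)
  }

  pa <- build_arm(pc, "P", product_label)
  ca <- build_arm(cc, "C", comparator_label)
  id_x <- if (pc$crossover > 0) sprintf("X%07d", seq_len(pc$crossover)) else character()
  x_consults <- data.table::data.table(
    animal_id = id_x, date = d0 + 5,
    narrative = rep("routine visit, no concerns", length(id_x)),
    data_unavailable = rep(FALSE, length(id_x)))
  x_treat <- data.table::rbindlist(list(
    data.table::data.table(animal_id = id_x, date = d0,
                           product_description = paste(product_label, "50 mg tablets"),
                           active_substance = substance(product_label)),
    data.table::data.table(animal_id = id_x, date = d0 + 1,
                           product_description = paste(comparator_label, "50 mg tablets"),
                           active_substance = substance(comparator_label))))
  consults <- as.data.frame(data.table::rbindlist(list(pa$consults, ca$consults, x_consults)))
  consults$consult_id <- sprintf("C%07d", seq_len(nrow(consults)))
  consults <- consults[, c("consult_id", "animal_id", "date", "narrative", "data_unavailable")]
  treatments <- as.data.frame(data.table::rbindlist(list(pa$treatments, ca$treatments, x_treat)))
  all_ids <- c(pa$ids, ca$ids, id_x)
  animals <- data.frame(animal_id = all_ids, species = "dog",
                        birth_date = as.Date("2010-01-01"), stringsAsFactors = FALSE)
  list(animals = animals, consults = consults, treatments = treatments,
       product_spec = cohort_spec(product_label, substance(product_label),
                                  "tablet", "2020-02-24"),
       comparator_spec = cohort_spec(comparator_label, substance(comparator_label),
                                     "tablet", "2020-02-24"))
}
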