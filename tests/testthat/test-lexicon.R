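test_that("seed dictionaries are validated", {
  expect_error(seed_dictionary("x", character(), "pt"), "non-empty")
  expect_error(seed_dictionary("x", c("a", "a"), "pt"), "unique")
  expect_error(seed_dictionary("x", "Fit", "pt"), "lowercase")
})

test_that("expansion adds oracle-relevant neighbours above the cut-off", {
  # planted vector geometry: "seizre" at cosine ~0.995 to "seizure",
  # "kennel" orthogonal
  v <- rbind(seizure = c(1, 0), seizre = c(0.995, 0.0999), kennel = c(0, 1),
             cough = c(0.1, 0.99))
  m <- toy_model(v)
  sd <- seed_dictionary("convulsions", "seizure", "convulsion")
  orc <- relevance_oracle(c("seizre", "cough"), c(TRUE, FALSE))
  ed <- expand_dictionary(sd, m, cutoffs = c(seizure = 0.75), oracle = orc)
  expect_identical(ed$entries$term, c("seizure", "seizre"))
  expect_identical(ed$entries$provenance, c("seed", "embedding"))
  # no neighbour above cut-off -> expansion is a no-op
  ed2 <- expand_dictionary(sd, m, cutoffs = c(seizure = 0.999), oracle = orc)
  expect_identical(ed2$entries$term, "seizure")
  # out-of-vocabulary LLT retained and logged
  sd3 <- seed_dictionary("convulsions", c("seizure", "opisthotonus"), "convulsion")
  ed3 <- expand_dictionary(sd3, m, cutoffs = 0.75, oracle = orc)
  expect_true("opisthotonus" %in% ed3$entries$term)
  expect_identical(attr(ed3, "oov_terms"), "opisthotonus")
})

test_that("end-to-end expansion on a synthetic corpus recovers planted misspellings", {
  cfg <- synth_config(n_animals = 2500, planted_ae_rate = 0.25,
                      misspelling_rate = 0.5, ae_terms = c("seizure", "convulsion"),
                      rng_seed = 5)
  e <- generate_ehr(cfg)
  # the template corpus is small and repetitive, so collocation scores run
  # high; a raised joining threshold keeps the planted unigrams intact
  corp <- preprocess_narratives(e$consults$narrative, bigram_threshold = 100)
  m <- train_embeddings(corp, vector_size = 64, min_count = 5, iterations = 10, seed = 2)
  variants <- setdiff(unique(e$gold_labels$planted_term[e$gold_labels$is_true_mention]),
                      cfg$ae_terms)
  orc <- relevance_oracle(variants, rep(TRUE, length(variants)))
  sd <- seed_dictionary("convulsions", c("seizure", "convulsion"), "convulsion")
  cut <- determine_cutoff(m, "seizure", orc)
  expect_true(cut$found)
  ed <- expand_dictionary(sd, m, cutoffs = 0.6, oracle = orc)
  emb <- ed$entries[ed$entries$provenance == "embedding", ]
  expect_gt(nrow(emb), 0)
  expect_true(all(emb$term %in% variants))
})

test_that("expert terms are added with their component and deduplicated", {
  v <- rbind(`kidney disease` = c(1, 0), other = c(0, 1))
  sd <- seed_dictionary("renal insufficiency", "kidney disease", "renal insufficiency")
  ed <- expand_dictionary(sd, toy_model(v), cutoffs = 0.99,
                          oracle = relevance_oracle("x", TRUE))
  ed <- add_expert_terms(ed, c("creatinine", "sdma"), component = "test_result")
  ed <- add_expert_terms(ed, c("renal diet", "ipakitine"), component = "diet_treatment")
  ed <- add_expert_terms(ed, "kidney disease")  # already present: no duplicate
  expect_identical(sum(ed$entries$term == "kidney disease"), 1L)
  expect_identical(ed$entries$component[ed$entries$term == "sdma"], "test_result")
  expect_identical(ed$entries$provenance[ed$entries$term == "renal diet"], "expert")
})

test_that("stems are longest common prefixes of groups sharing min_prefix chars", {
  cs <- consolidate_stems(c("epileptic", "epileptic type", "epileptiform"))
  expect_identical(cs$stems, "epilepti")
  expect_length(cs$whole_terms, 0)
  # prefix matching the stem covers exactly the originals' own matches
  expect_true(all(startsWith(c("epileptic", "epileptic type", "epileptiform"),
                             cs$stems)))
  # singleton stays whole
  cs <- consolidate_stems("blind")
  expect_identical(cs, list(stems = character(), whole_terms = "blind"))
  # shared prefix shorter than the minimum does not group
  cs <- consolidate_stems(c("renal", "rental"))
  expect_length(cs$stems, 0)
  expect_identical(cs$whole_terms, c("renal", "rental"))
  expect_error(consolidate_stems(character()), "at least one")
})

test_that("negative contexts suppress matches; plain uses still match", {
  m <- compile_matcher(c("fit", "seizure"),
                       exceptions = list(fit = list(before = c("good", "a good"),
                                                    after = "and well")))
  expect_identical(nrow(match_narrative(m, "dog is fit and well")), 0L)
  expect_identical(nrow(match_narrative(m, "harness is a good fit")), 0L)
  hit <- match_narrative(m, "had a fit overnight")
  expect_identical(hit$matched_text, "fit")
  expect_identical(hit$start0, 6L)
  expect_identical(hit$end0, 9L)
  # case-insensitive, word boundaries: "benefit" and "fitness" do not match
  expect_identical(match_narrative(m, "no benefit from fitness plan")$term, character(0))
  expect_identical(match_narrative(m, "a FIT was seen")$matched_text, "FIT")
  expect_error(compile_matcher("fit", exceptions = list(fit = list(before = ""))),
               "non-empty")
  expect_error(compile_matcher(character(0)), "empty|at least")
})

test_that("stems match as prefixes, whole terms on both boundaries", {
  dict <- structure(list(ae_name = "convulsions", entries = data.frame(
    term = c("epilep", "fit"), provenance = "seed", component = "disease_mention",
    stringsAsFactors = FALSE)), class = "expanded_dictionary")
  m <- compile_matcher(dict)
  m$patterns$is_stem[m$patterns$term == "epilep"] <- TRUE
  m$patterns$regex[m$patterns$term == "epilep"] <-
    vetaemine:::build_pattern("epilep", is_stem = TRUE)
  hits <- match_narrative(m, "epileptiform activity, known epileptic, had a fit")
  expect_identical(hits$matched_text, c("epileptiform", "epileptic", "fit"))
})

test_that("match spans reproduce matched text and agree with a word-offset oracle", {
  set.seed(123)
  terms <- c("seizure", "collapse", "twitching")
  filler <- c("owner", "reports", "today", "bright", "alert", "bloods", "normal",
              "recheck", "booked", "vaccination")
  m <- compile_matcher(terms)
  for (i in 1:200) {
    w <- random_word_narrative(terms, filler, n_words = sample(3:25, 1))
    got <- match_narrative(m, w$narrative)
    expect_identical(got$start0, w$spans$start0)
    expect_identical(got$end0, w$spans$end0)
    if (nrow(got)) {
      expect_identical(got$matched_text,
                       substring(w$narrative, got$start0 + 1, got$end0))
    }
  }
  expect_identical(nrow(match_narrative(m, "")), 0L)
})

test_that("evaluation counts narratives once and reports undefined as NA", {
  m <- compile_matcher("seizure")
  sample4 <- data.frame(
    narrative = c("seizure seen", "seizure suspected", "seizure mention", "seizure again"),
    gold = c(TRUE, TRUE, FALSE, FALSE))
  ev <- evaluate_matcher(m, sample4)
  expect_identical(ev$n_matches, 4L)
  expect_equal(ev$precision, 0.5)
  # matcher that matches nothing: precision undefined, recall 0
  none <- evaluate_matcher(compile_matcher("zzzz"), sample4)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  # engineered 3 TP, 1 FP, 1 FN
  s <- data.frame(
    narrative = c("seizure a", "seizure b", "seizure c", "seizure d", "collapse only"),
    gold = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  ev <- evaluate_matcher(m, s)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  # the literal matches/positives ratio is reported separately
  expect_equal(ev$paper_ratio, 1.0)
})

test_that("adding dictionary terms never decreases recall", {
  set.seed(7)
  narr <- replicate(120, random_word_narrative(
    c("seizure", "collapse"), c("owner", "today", "normal", "bright"), 8)$narrative)
  gold <- grepl("seizure|collapse", narr)
  s <- data.frame(narrative = narr, gold = gold)
  r1 <- evaluate_matcher(compile_matcher("seizure"), s)$recall
  r2 <- evaluate_matcher(compile_matcher(c("seizure", "collapse")), s)$recall
  expect_gte(r2, r1)
})

test_that("union recall dominates component recalls", {
  dict <- structure(list(ae_name = "renal insufficiency", entries = data.frame(
    term = c("kidney disease", "creatinine", "renal diet"),
    provenance = "seed",
    component = c("disease_mention", "test_result", "diet_treatment"),
    stringsAsFactors = FALSE)), class = "expanded_dictionary")
  m <- compile_matcher(dict)
  s <- data.frame(
    narrative = c("kidney disease suspected", "creatinine 250 noted",
                  "started renal diet", "kidney disease noted again",
                  "no findings", "azotaemia mentioned only"),
    gold = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  ca <- component_analysis(m, s)
  recalls <- vapply(ca$components, function(r) r$recall, numeric(1))
  expect_gte(ca$combined$recall, max(recalls))
  # disjoint coverage: union recall equals the sum of component recalls
  expect_equal(ca$combined$recall, 4 / 5)
  expect_equal(sum(recalls), 4 / 5)
  # single-component matcher: combined equals the component report
  m1 <- compile_matcher("seizure")
  s1 <- data.frame(narrative = c("seizure", "none"), gold = c(TRUE, FALSE))
  ca1 <- component_analysis(m1, s1)
  expect_identical(unclass(ca1$combined), unclass(ca1$components$disease_mention))
})

test_that("matcher specs round-trip through JSON and patterns export", {
  sd <- seed_dictionary("convulsions", c("seizure", "fit"), "convulsion")
  v <- rbind(seizure = c(1, 0), fit = c(0, 1))
  ed <- expand_dictionary(sd, toy_model(v), cutoffs = 0.9,
                          oracle = relevance_oracle("x", TRUE))
  ed <- add_expert_terms(ed, "renal diet", component = "diet_treatment")
  exc <- list(fit = list(before = "good", after = "and well"))
  path <- tempfile(fileext = ".json")
  write_matcher_spec(ed, exc, path)
  rt <- read_matcher_spec(path)
  expect_identical(rt$dictionary$entries, ed$entries)
  m1 <- compile_matcher(ed, exc)
  m2 <- compile_matcher(rt$dictionary, rt$exceptions)
  expect_identical(m1$patterns, m2$patterns)
  txt <- tempfile(fileext = ".txt")
  export_patterns(m1, txt)
  expect_identical(length(readLines(txt)), nrow(m1$patterns))
})
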