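make_treatments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(animal_id = r[[1]], date = as.Date(r[[2]]),
               product_description = r[[3]], active_substance = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("exposure identification filters substance, form and data lock", {
  spec <- cohort_spec("VMP-X", "examplinib", "tablet", "2020-02-24")
  tr <- make_treatments(
    list("a1", "2016-03-01", "VMP-X 50 mg injection", "examplinib"),
    list("a1", "2016-05-01", "VMP-X 50 mg tablets", "examplinib"),
    list("a1", "2016-04-01", "VMP-X 50 mg tablets", "examplinib"))
  ex <- identify_exposures(tr, spec)
  # injectable record ignored; index is the earliest tablet date
  expect_identical(ex$animal_id, "a1")
  expect_identical(ex$index_date, as.Date("2016-04-01"))

  # event after the data lock point excludes the animal
  tr <- make_treatments(list("a2", "2021-01-01", "VMP-X tablets", "examplinib"))
  expect_identical(nrow(identify_exposures(tr, spec)), 0L)

  # per-animal independence: two animals, two index events
  tr <- make_treatments(
    list("a3", "2016-01-10", "VMP-X tablets", "examplinib"),
    list("a4", "2017-02-20", "VMP-X tablets", "examplinib"))
  ex <- identify_exposures(tr, spec)
  expect_identical(ex$animal_id, c("a3", "a4"))
  expect_identical(ex$index_date, as.Date(c("2016-01-10", "2017-02-20")))

  # different substance filtered out
  tr <- make_treatments(list("a5", "2016-01-10", "Other tablets", "otherdrug"))
  expect_identical(nrow(identify_exposures(tr, spec)), 0L)

  # ambiguous dosage form removes the animal
  tr <- make_treatments(
    list("a6", "2016-01-10", "VMP-X tablets and injection pack", "examplinib"),
    list("a6", "2016-02-10", "VMP-X tablets", "examplinib"))
  expect_identical(nrow(identify_exposures(tr, spec)), 0L)

  expect_error(identify_exposures(data.frame(animal_id = "a", date = Sys.Date()), spec),
               "active_substance")
})

test_that("dosage forms are classified from raw descriptions", {
  forms <- classify_dosage_form(c("Drug 50 mg tablets", "drug inj 10 ml vial",
                                  "spot-on pipette", "mystery product",
                                  "tablets or injection"))
  expect_identical(forms, c("tablet", "injectable", "spot_on", "unknown", "ambiguous"))
})

test_that("cascade stages are applied in order and counts add up", {
  counts_p <- list(unavailable = 4, no_post = 3, pre_existing = 2, crossover = 2, final = 6)
  counts_c <- list(unavailable = 1, no_post = 2, pre_existing = 1, crossover = 2, final = 9)
  fx <- make_cascade_fixture(counts_p, counts_c)
  m <- compile_matcher("seizure")
  cb <- build_cohort(identify_exposures(fx$treatments, fx$product_spec),
                     identify_exposures(fx$treatments, fx$comparator_spec),
                     fx$consults, m)
  rp <- cb$product$report
  expect_identical(unclass(rp)[-1],
                   list(index_count = 17L, data_unavailable = 4L, no_post_exposure = 3L,
                        pre_existing = 2L, crossover = 2L, final_count = 6L))
  rc <- cb$comparator$report
  expect_identical(rc$final_count, 9L)
  # crossover symmetry
  expect_identical(rp$crossover, rc$crossover)
  expect_identical(length(cb$crossover_ids), 2L)
  # no crossover animal reaches either final cohort
  expect_false(any(cb$crossover_ids %in% cb$product$cohort$animal_id))
  expect_false(any(cb$crossover_ids %in% cb$comparator$cohort$animal_id))
})

test_that("a cascade with no applicable exclusions is the identity", {
  fx <- make_cascade_fixture(
    list(unavailable = 0, no_post = 0, pre_existing = 0, crossover = 0, final = 5),
    list(unavailable = 0, no_post = 0, pre_existing = 0, crossover = 0, final = 7))
  cb <- build_cohort(identify_exposures(fx$treatments, fx$product_spec),
                     identify_exposures(fx$treatments, fx$comparator_spec),
                     fx$consults, compile_matcher("seizure"))
  expect_identical(cb$product$report$final_count, cb$product$report$index_count)
  expect_identical(cb$comparator$report$final_count, 7L)
})

test_that("cascade additivity and crossover symmetry hold on random synthetic cohorts", {
  m <- compile_matcher("seizure")
  specs <- list(p = cohort_spec("VMP-X", "vmpx_substance", "tablet", "2020-02-24"),
                c = cohort_spec("COMP-X", "compx_substance", "tablet", "2020-02-24"))
  for (r in 1:500) {
    e <- generate_ehr(synth_config(
      n_animals = 60, planted_ae_rate = 0.3, pre_existing_rate = 0.2,
      crossover_fraction = 0.3, dropout_fraction = 0.3, unavailable_fraction = 0.2,
      ae_terms = "seizure", misspelling_rate = 0, rng_seed = 10000 + r))
    cb <- build_cohort(identify_exposures(e$treatments, specs$p),
                       identify_exposures(e$treatments, specs$c),
                       e$consults, m)
    for (arm in list(cb$product$report, cb$comparator$report)) {
      expect_identical(arm$index_count,
                       arm$data_unavailable + arm$no_post_exposure +
                         arm$pre_existing + arm$crossover + arm$final_count)
    }
    expect_identical(cb$product$report$crossover, cb$comparator$report$crossover)
  }
})

test_that("final-cohort membership is invariant to exclusion-stage order", {
  # The stage predicates are animal-intrinsic (given both arms' survivors for
  # crossover), so removing animals in any order must leave the same final
  # set; the staged counts only attribute each animal to its earliest stage.
  e <- generate_ehr(synth_config(
    n_animals = 400, planted_ae_rate = 0.3, pre_existing_rate = 0.2,
    crossover_fraction = 0.25, dropout_fraction = 0.3, unavailable_fraction = 0.2,
    ae_terms = "seizure", misspelling_rate = 0, rng_seed = 77))
  m <- compile_matcher("seizure")
  ep <- identify_exposures(e$treatments, cohort_spec("VMP-X", "vmpx_substance",
                                                     "tablet", "2020-02-24"))
  ec <- identify_exposures(e$treatments, cohort_spec("COMP-X", "compx_substance",
                                                     "tablet", "2020-02-24"))
  cb <- build_cohort(ep, ec, e$consults, m)

  # order-free reference: per-animal predicate flags
  flags_for <- function(expo) {
    sapply(seq_len(nrow(expo)), function(i) {
      id <- expo$animal_id[i]; idx <- expo$index_date[i]
      cons <- e$consults[e$consults$animal_id == id, ]
      unav <- nrow(cons) > 0 && all(cons$data_unavailable)
      post <- any(!cons$data_unavailable & cons$date > idx)
      pre <- cons[!cons$data_unavailable & cons$date <= idx & nzchar(cons$narrative), ]
      pre_ex <- nrow(pre) > 0 &&
        any(vetaemine:::narrative_match_flags(m, pre$narrative))
      c(unav = unav, no_post = !post, pre = pre_ex)
    })
  }
  fp <- flags_for(ep); fc <- flags_for(ec)
  surv_p <- ep$animal_id[!apply(fp, 2, any)]
  surv_c <- ec$animal_id[!apply(fc, 2, any)]
  cross <- intersect(surv_p, surv_c)
  expect_setequal(cb$product$cohort$animal_id, setdiff(surv_p, cross))
  expect_setequal(cb$comparator$cohort$animal_id, setdiff(surv_c, cross))
})

test_that("follow-up window combines onset statistics and half-life elimination", {
  # median 10, MAD 4, five half-lives 10 <= median -> onset-based 14 days
  w <- compute_followup_window(followup_spec(c(5, 8, 10, 14, 30), 2))
  expect_identical(w$days, 14L)
  expect_identical(w$rule_used, "onset_based")
  # elimination exceeds the median -> five half-lives
  w <- compute_followup_window(followup_spec(10, 12))
  expect_identical(w$days, 60L)
  expect_identical(w$rule_used, "five_half_lives")
  # zero dispersion
  w <- compute_followup_window(followup_spec(c(7, 7, 7), 1))
  expect_identical(w$days, 7L)
  # onset list empty: half-life drives the window
  w <- compute_followup_window(followup_spec(half_life_days = 3))
  expect_identical(w$days, 15L)
  expect_error(followup_spec(), "either")
  expect_error(followup_spec(c(-1, 3), 2), "non-negative")
})

test_that("history windowing keeps strictly-post consultations up to the bound", {
  cohort <- data.frame(animal_id = "a1", index_date = as.Date("2016-01-01"))
  consults <- data.frame(
    consult_id = sprintf("c%d", 1:4), animal_id = "a1",
    date = as.Date("2016-01-01") + c(0, 5, 28, 29),
    narrative = "x", data_unavailable = FALSE, stringsAsFactors = FALSE)
  wh <- window_histories(cohort, consults, 28)
  expect_identical(wh$consult_id, c("c2", "c3"))   # index-day dropped, day 28 kept
  # an animal with no consult in the window keeps zero rows
  cohort2 <- rbind(cohort, data.frame(animal_id = "a2", index_date = as.Date("2016-01-01")))
  wh2 <- window_histories(cohort2, consults, 28)
  expect_identical(sort(unique(wh2$animal_id)), "a1")
  # monotone: enlarging the window never removes a retained consultation
  for (d in c(5, 10, 28, 40)) {
    small <- window_histories(cohort, consults, d)$consult_id
    big <- window_histories(cohort, consults, d + 10)$consult_id
    expect_true(all(small %in% big))
  }
})
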