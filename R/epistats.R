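# Incidence, relative risk with Katz log confidence intervals,
# Mantel-Haenszel stratified (age-adjusted) relative risk, and
# prescription-exposure rates.

#' 2x2 contingency table
#'
#' Cell layout: `a` exposed cases, `b` exposed non-cases, `c` comparator
#' cases, `d` comparator non-cases; `a + b` and `c + d` are the cohort
#' sizes.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stopf("cell counts must be non-negative integers")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "comparator"), c("cases", "non-cases")))
  print(m)
  invisible(x)
}

#' Incidence per 10,000 animals
#'
#' @param cases case count.
#' @param total cohort size (must be positive).
#' @return incidence per 10,000 (unrounded; formatted output rounds to one
#'   decimal, half away from zero).
#' @export
incidence_per_10k <- function(cases, total) {
  if (total <= 0) stopf("incidence denominator must be positive")
  if (cases < 0 || cases > total) stopf("cases must lie in [0, total]")
  10000 * cases / total
}

new_risk_estimate <- function(rr, ci_low, ci_high, alpha, method, note = NULL) {
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high, alpha = alpha,
                 method = method, note = note),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  f <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.2f", round_half_up(v, 2))
  cat(sprintf("Relative risk (%s): %s, %d%% CI %s-%s\n", x$method, f(x$rr),
              round(100 * (1 - x$alpha)), f(x$ci_low), f(x$ci_high)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Relative risk with a Katz log confidence interval
#'
#' Point estimate `(a/(a+b)) / (c/(c+d))`; the confidence interval is the
#' Katz log method, `exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c -
#' 1/(c+d)))`. No continuity correction is applied by default; with
#' `correction = TRUE`, 0.5 is added to every cell when any cell is zero.
#' Zero numerators are signalled explicitly: `c = 0` with `a > 0` gives an
#' infinite relative risk, `a = 0` gives zero, both give `NA`, each with an
#' explanatory note and an undefined interval.
#'
#' @param table a [two_by_two()].
#' @param alpha two-sided significance level (default 0.05).
#' @param correction add 0.5 to all cells when a zero cell is present.
#' @return object of class `risk_estimate` with `rr`, `ci_low`, `ci_high`,
#'   `alpha`, `method = "crude_katz"`.
#' @export
relative_risk <- function(table, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n1 <- a + b; n0 <- cc + d
  if (n1 == 0 || n0 == 0) stopf("both cohorts must be non-empty")
  if (correction && (a == 0 || cc == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    n1 <- a + b; n0 <- cc + d
  }
  if (a == 0 && cc == 0) {
    return(new_risk_estimate(NA_real_, NA_real_, NA_real_, alpha, "crude_katz",
                             "no cases in either cohort; relative risk undefined"))
  }
  if (cc == 0) {
    return(new_risk_estimate(Inf, NA_real_, NA_real_, alpha, "crude_katz",
                             "no comparator cases; relative risk infinite"))
  }
  rr <- (a / n1) / (cc / n0)
  if (a == 0) {
    return(new_risk_estimate(0, NA_real_, NA_real_, alpha, "crude_katz",
                             "no exposed cases; interval undefined without correction"))
  }
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n0)
  new_risk_estimate(rr, exp(log(rr) - z * se), exp(log(rr) + z * se),
                    alpha, "crude_katz")
}

#' Stratum set for Mantel-Haenszel estimation
#'
#' @param strata named list of [two_by_two()] tables (unique labels).
#' @param stratifier name of the stratifying variable (e.g. `"age group"`).
#' @return object of class `stratum_set`.
#' @export
stratum_set <- function(strata, stratifier = "age group") {
  stopifnot(length(strata) >= 1,
            all(vapply(strata, inherits, logical(1), "two_by_two")))
  if (is.null(names(strata)) || anyDuplicated(names(strata))) {
    stopf("strata must have unique labels")
  }
  structure(list(strata = strata, stratifier = stratifier),
            class = "stratum_set")
}

#' Mantel-Haenszel stratified relative risk
#'
#' Pooled relative risk `sum(a_i (c_i+d_i) / T_i) / sum(c_i (a_i+b_i) /
#' T_i)` across strata with `T_i` the stratum total; the confidence interval
#' uses the Greenland-Robins variance of the log Mantel-Haenszel relative
#' risk. With a single stratum this reduces exactly to [relative_risk()].
#' Strata with an empty margin contribute nothing; if all strata are
#' degenerate an error is raised.
#'
#' @param strata a [stratum_set()], or a named list of [two_by_two()].
#' @param alpha two-sided significance level.
#' @return object of class `risk_estimate` with `method =
#'   "mantel_haenszel"`.
#' @export
mh_relative_risk <- function(strata, alpha = 0.05) {
  if (!inherits(strata, "stratum_set")) strata <- stratum_set(strata)
  R <- S <- P <- 0
  used <- 0L
  for (tb in strata$strata) {
    n1 <- tb$a + tb$b; n0 <- tb$c + tb$d; tt <- n1 + n0
    if (n1 == 0 || n0 == 0 || tt == 0) next
    used <- used + 1L
    R <- R + tb$a * n0 / tt
    S <- S + tb$c * n1 / tt
    P <- P + (n1 * n0 * (tb$a + tb$c) - tb$a * tb$c * tt) / tt^2
  }
  if (used == 0L || (R == 0 && S == 0)) {
    stopf("all strata are degenerate; Mantel-Haenszel estimate undefined")
  }
  if (S == 0) {
    return(new_risk_estimate(Inf, NA_real_, NA_real_, alpha, "mantel_haenszel",
                             "no comparator cases in any stratum"))
  }
  rr <- R / S
  if (R == 0) {
    return(new_risk_estimate(0, NA_real_, NA_real_, alpha, "mantel_haenszel",
                             "no exposed cases in any stratum"))
  }
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(P / (R * S))
  new_risk_estimate(rr, exp(log(rr) - z * se), exp(log(rr) + z * se),
                    alpha, "mantel_haenszel")
}

#' Prescription-exposure rate per 1,000 animal-days
#'
#' One prescription event equates to one exposure; the denominator is the
#' total observed animal-days.
#'
#' @param events non-negative prescription event count.
#' @param animal_days positive total animal-days.
#' @return object of class `exposure_rate` with `events`, `animal_days`,
#'   `rate_per_1000`.
#' @export
exposure_rate <- function(events, animal_days) {
  if (!is.finite(animal_days) || animal_days <= 0) {
    stopf("animal_days must be positive")
  }
  if (events < 0) stopf("events must be non-negative")
  structure(list(events = as.integer(events), animal_days = animal_days,
                 rate_per_1000 = 1000 * events / animal_days),
            class = "exposure_rate")
}

#' @export
print.exposure_rate <- function(x, ...) {
  cat(sprintf("%.2f prescriptions per 1,000 animal-days (%d events / %s animal-days)\n",
              round_half_up(x$rate_per_1000, 2), x$events,
              format(x$animal_days, big.mark = ",")))
  invisible(x)
}

#' Format a results row in the published table layout
#'
#' Rounds half away from zero to the printed precisions: incidence to one
#' decimal, relative risk and interval bounds to two.
#'
#' @param cases_exposed,total_exposed,cases_comparator,total_comparator
#'   cohort case counts and sizes.
#' @param estimate a `risk_estimate`.
#' @return data.frame with one row per arm plus formatted RR/CI columns.
#' @export
format_results_row <- function(cases_exposed, total_exposed, cases_comparator,
                               total_comparator, estimate) {
  inc <- function(k, n) round_half_up(incidence_per_10k(k, n), 1)
  data.frame(
    arm = c("exposed", "comparator"),
    cases = c(cases_exposed, cases_comparator),
    no_signs = c(total_exposed - cases_exposed, total_comparator - cases_comparator),
    total = c(total_exposed, total_comparator),
    incidence_per_10k = c(inc(cases_exposed, total_exposed),
                          inc(cases_comparator, total_comparator)),
    rr = c(round_half_up(estimate$rr, 2), NA),
    ci_low = c(round_half_up(estimate$ci_low, 2), NA),
    ci_high = c(round_half_up(estimate$ci_high, 2), NA),
    stringsAsFactors = FALSE)
}
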