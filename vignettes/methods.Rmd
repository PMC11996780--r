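---
title: "Methods: mining veterinary EHRs for adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining veterinary EHRs for adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vetaemine estimates the risk of an adverse event (AE) after exposure to a
veterinary medicinal product (VMP), using only what a first-opinion practice
database records: semi-structured treatment lines and the free-text clinical
narrative. This vignette is the package's account of how each stage works,
which knobs matter, and what the accompanying tests do and do not establish.

## Pipeline overview

1. **Lexicon building** — a seed dictionary of lower-level AE terms is
   expanded with corpus-specific synonyms, misspellings and abbreviations
   found by skip-gram word embeddings, then reviewed (here: a relevance
   oracle file standing in for a human reviewer) and compiled into
   context-aware regular-expression matchers.
2. **Cohort building** — animals with a qualifying index prescription enter
   an exposure arm; a fixed-order exclusion cascade removes animals with
   unavailable narratives, no post-exposure data, pre-existing signs, or
   exposure to both arms.
3. **Outcome ascertainment** — matchers run over post-exposure consultations
   inside a follow-up window; matches sitting next to normal test results
   are discarded; any surviving match makes the animal a case, once.
4. **Estimation** — incidence per 10,000 animals, relative risk with a Katz
   log confidence interval, and a Mantel-Haenszel age-adjusted relative risk
   when strata are configured.

A synthetic EHR generator with planted ground truth makes every stage
testable without access to clinical data.

## Narrative preprocessing and embeddings

Narratives are split into sentences on `.`, `!`, `?`, `;` and newlines
(protecting common clinical abbreviations such as `e.g.` and `q.d.`),
lowercased, and tokenized into alphanumeric runs, which removes punctuation.
A single bigram pass joins adjacent pairs whose co-occurrence score
`(count(ab) - min_count) * N / (count(a) * count(b))` (with `N` the corpus
token count) reaches a threshold; the defaults (`min_count` 5, threshold 10)
are the conventional settings of the phrase-detection method this score
comes from. No trigrams are formed. On small template-generated corpora,
collocation scores run high and a larger threshold may be appropriate; the
expansion tests do exactly that and say why.

Embeddings are trained with skip-gram and negative sampling, implemented in
C++ inside the package. Defaults mirror the settings that worked on a large
clinical corpus: vector size 300, window 5, minimum count 8, 15 iterations,
5 negative samples, initial learning rate 0.025. Training is deliberately
single-threaded with an internal deterministic RNG: the same corpus,
parameters and seed give bit-identical vectors, which the test suite relies
on. A multi-worker mode is *not* offered — `workers > 1` is rejected rather
than silently breaking the reproducibility contract. Tokens below the
minimum count are dropped; as a consequence the method cannot expand
dictionaries for terms rarer than that count, a known limitation for rare or
pathognomonically-described events.

`similar_terms()` ranks the vocabulary by cosine similarity (descending,
lexicographic tie-break). The review cut-off for a preferred term is found
by walking that ranking and stopping after 10 consecutive terms the oracle
marks irrelevant or not novel (`patience`, configurable); the cut-off is the
cosine of the last relevant term. Whether a previously-seen synonym resets
the streak is delegated entirely to the oracle: a term already in the
dictionary should be marked "irrelevant" there. If nothing is relevant, a
"no cut-off" sentinel is returned rather than a number.

`sweep_parameters()` reproduces the hyper-parameter search procedure: one
model per grid entry, the 30 nearest neighbours of a probe word scored
relevant/irrelevant, entries ranked by most relevant then fewest irrelevant,
ties by grid order. Entries where the probe falls under `min_count` are
flagged, never silently dropped.

## Matcher compilation

Dictionary terms become case-insensitive patterns on word boundaries, where
a boundary is any alphanumeric/non-alphanumeric transition (hyphens are
boundaries: clinical text is hyphen-heavy). Terms can be consolidated into
prefix-matched stems: terms sharing their first five characters (configurable)
are grouped and replaced by the group's longest common prefix. A human
lexicographer might trim further (e.g. a shorter stem for the epileptic /
epileptiform family); the algorithmic rule keeps the stem set auditable and
provably covers exactly the union of the grouped terms' own matches, which
is the property that matters downstream.

False-positive contexts are handled with per-term exception phrases:
forbidden left contexts compile to fixed-width negative lookbehinds,
forbidden right contexts to negative lookaheads. The canonical example is
"fit": `dog is fit and well` and `harness is a good fit` are suppressed
while `had a fit overnight` still matches. Exceptions live in versioned JSON
matcher-spec files; refining them is an iterative human activity, so the
package ships the file format and the compiled-pattern export for audit, not
an automated optimizer. Negation and uncertainty ("no seizures observed")
are *not* detected; that is a documented limitation, not an implicit
feature.

Evaluation counts narratives, not spans: a consultation with at least one
hit is one match. Precision is confirmed matches over matches; recall is
confirmed matches over gold positives. The literal matches-over-positives
ratio — which can exceed 1 — is reported as a separate secondary field
because published evaluations have used that wording; the package's
headline `recall` is always the standard definition. Undefined quantities
are `NA`, never 0.

## Case definitions and test results

Threshold rules encode the case definitions for test-result evidence:
specific gravity < 1.030, creatinine > 125, SDMA > 14, UPC > 0.5 for renal
insufficiency; ALT > 150 iu/l for hepatopathy. Comparisons are strict
exactly as printed, so boundary values are normal. Units are taken at face
value on the conventional scales; mixed-unit narratives are an acknowledged
failure mode. The elevated-bile-acids clause has no numeric threshold and is
treated as a disease-mention term, not a threshold rule.

A value is associated with an analyte alias by scanning a 30-character
window to the right of the alias for the nearest number (decimal comma or
point). A `test_result` match is removed only when an overlapping
observation parses to a normal value; unparseable values pass through,
conservatively, and matches of other components are never touched.

## Exposure cohorts and the exclusion cascade

Treatment records are filtered by mapped active substance; the dosage form
is classified from the raw product description with editable pattern rules,
because that field is not standardized. Records of other or unrecognised
forms are ignored; an ambiguous-form record (several patterns match) removes
the animal, since the specific product cannot be identified. The earliest
remaining event on or before the data lock date is the index prescription.

The cascade applies four stages in fixed order, each animal counted at its
earliest applicable stage: (1) *data unavailable* — at least one
consultation exists and all carry the narrative-unavailable flag (an animal
with no consultation rows at all falls to stage 2 instead); (2) *no
post-exposure data* — no available-narrative consultation after the index
date; (3) *pre-existing signs* — the matcher (with normal-result filtering)
fires on any consultation dated on or before the index date, using the full
prior history; (4) *product crossover* — animals surviving stages 1-3 in
both arms are removed from both, so the two reports always carry the same
crossover count. Stage order affects only the attribution of counts, never
final-cohort membership; the tests verify this against an order-free
reference.

## Follow-up windows

The onset-based window candidate is `ceiling(median + k * MAD)` of
historical time-to-onset values, with MAD the raw (unscaled) median absolute
deviation. How the two statistics combine into a window is genuinely open;
`k = 1` is this package's choice, exposed as a parameter and flagged here so
users can audit it. The elimination candidate is `ceiling(5 * half_life)`;
if the drug would remain in the system longer than the median time-to-onset
(elimination candidate > median), the elimination candidate is used. Since
the onset data behind published windows are typically unpublished, fixed
windows can also be supplied directly as configuration.

Within the window, consultations with `index < date <= index + days` are
retained. Index-day consultations count as pre-exposure — the prescribing
visit's presenting signs should not become post-exposure AEs. Animals with
no consultation in the window stay in the denominator.

## Estimation

Incidence is cases over cohort size, per 10,000 animals. The relative-risk
interval is the Katz log method with `z = qnorm(1 - alpha/2)`; this method
was chosen because it exactly reproduces the published interval from the
published counts, which no other standard interval does at those cell
sizes. No continuity correction is applied by default (the published
arithmetic has none); a 0.5-correction mode exists behind a flag. Zero
numerators are signalled explicitly (`Inf`, `0`, or `NA` with a note), never
as overflow. The Mantel-Haenszel relative risk uses stratum-total weights
and the Greenland-Robins variance for its interval; with one stratum both
the estimate and the interval reduce *exactly* to the crude Katz results,
and the pooled estimate always lies within the range of the finite stratum
risks. Formatted output rounds half away from zero to the printed
precisions (one decimal for incidence, two for risk ratios).

## The synthetic EHR generator

The generator emulates the features of first-opinion EHR data that the
pipeline must survive: template-based narratives (shipped as an editable
data file) with slots for planted AE terms; misspellings produced by exactly
one character edit (substitution, deletion, adjacent transposition or
doubling — one edit keeps planted variants recoverable as embedding
neighbours); benign homograph phrases ("fit and well", "good fit"); numeric
test-result sentences drawn from per-analyte normal/abnormal distributions;
multi-product treatment histories with index prescriptions; crossover
animals; animals lost to follow-up; and a practice-management-system flag
that withholds all narratives for a fraction of animals. Planted mentions on
flag-withheld consultations keep their gold label but have no visible text —
exactly the blind spot the real flag creates.

Defaults describe a mid-sized dataset with a moderately common AE: 1,000
animals, 80/20 dog/cat, ages ~N(6, 3) years, ~4 background consultations per
animal on a 2015-2019 calendar, exposure probabilities 0.25/0.35
(product/comparator), planted post-exposure AE rate 0.04 per exposed animal,
pre-existing rate 0.01, misspelling rate 0.15, confound rate 0.05, crossover
0.02, dropout 0.2, narrative-unavailable 0.1. Exclusion-stage fractions sit
inside the ranges seen across published attrition tables; the AE rate is set
well above the per-10,000 incidences of real signal-validation studies so
that cohort-level statistics are estimable at test-scale cohort sizes.
Dates use a fixed synthetic calendar with uniform exposure dates and
geometric post-exposure gaps, since no timing model is published for such
data.

What the generator does **not** emulate: real clinical language (templates
are boilerplate), negation ("no seizures"), inter-practice linkage, coding
drift between practice systems, or unit heterogeneity in test results.
Passing tests therefore demonstrate that the machinery is correct under
known ground truth — not that any particular precision/recall level carries
over to a real corpus, which is corpus-specific by the method's own
argument.

`make_cascade_fixture()` is the complement: it engineers minimal two-arm
tables in which every animal falls at one prescribed cascade stage, so the
cascade arithmetic can be audited at any published scale exactly.

## Problem sizes used by the tests

The suite trains embeddings at 8-100 dimensions on template corpora of a few
thousand sentences (the 300-dimension default is exercised once on a small
corpus); runs the cascade at the full published scales (up to ~290,000
animals per arm, a few seconds each); checks cascade additivity on 500
random 60-animal cohorts; measures Katz interval coverage on 2,000 simulated
tables at 500 animals per arm; and checks log-RR recovery at ~2,000 animals
per arm, 200 replicates for each true RR in {0.5, 1, 2, 4}, asking the mean
log estimate to sit within 3 standard errors of the truth. These sizes are
the package's choices for a fast, deterministic suite; the statistical
claims they test are size-free.

## Known limitations

- No negation or uncertainty handling in matching.
- Threshold rules assume the conventional unit scales; no conversion.
- Exposure is prescription-event based; no dosing duration or adherence.
- Animal counts, not animal-time, form the incidence denominator.
- Crossover removal discards animals who switched products after an AE,
  which can hide treatment-switching signals.
- Embedding expansion cannot see terms rarer than the minimum count.
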