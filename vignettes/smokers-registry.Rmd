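---
title: "Building a Smokers' Registry from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a Smokers' Registry from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokereg)
library(dplyr)
```

## The problem

Structured EHR fields usually record *whether* a patient smokes, but care
decisions — cessation referral, lung-cancer-screening eligibility — need
*how much* and *until when*: pack-year history and the most recent
cessation date. That information lives in free-text visit notes, often in
semi-structured sections such as "social history" or "impressions".
smokereg implements an informatics pipeline that turns a corpus of such
notes into a Smokers' Registry:

1. **Status classification.** Every note is assigned one of five classes:
   never smoker, former smoker, current smoker, smoker temporality unknown
   (a smoking history is documented but currency is not), or unknown (no
   status information).
2. **Gated behavior extraction.** Only notes classified former/current/
   smoker are searched for pack-year history and cessation dates. The
   gate is the pipeline's false-positive control: it keeps blood panels
   and service dates in never/unknown notes from ever being assessed.
3. **Registry assembly.** Each smoker-classified note yields a registry
   record; records are exported as a de-identified population table and
   an identified contact table, optionally aggregated per patient.

## The status classifier

### Hotspot windows

Classification does not see whole notes. Four word stems — `smok`, `cig`,
`tobac`, `nicoti` — act as *hotspots*: matched as substrings anywhere in
the lowercased text, so "nonsmoker", "smoking" and "cigarette" all hit.
Around each occurrence a context window of up to ±5 word tokens is taken,
truncated at sentence boundaries (sentences split on `.`, `!`, `?` and
newlines, which also isolates section-header lines). All windows of a
note are appended, separated by a non-alphanumeric boundary marker that
the tokenizer discards, and the result is the single string the learner
sees. The window is word-based rather than character-based because
English modifiers sit close to the word they modify, and a word window
keeps the feature vector human-readable. A six-stem, ±100-character
configuration is retained as `hotspot_config_legacy()` for comparison.

A note with *no* hotspot is labeled `unknown` by rule, without touching
the learner. The learner itself still trains on all classes present among
hotspot-bearing notes — including `unknown`, because text like "smoke
detector batteries replaced" carries a hotspot but no smoking status.

### Features and learner

Features are unigram counts over the appended windows: lowercase,
split on non-alphanumeric runs, digits kept (so `1`, `ppd`, `1995`
survive). Stop words come from a versioned list shipped with the package,
minus the five negations *neither, never, no, nor, not*, which must stay
as features — "no tobacco use" and "tobacco use" must not collapse to the
same vector. No tf-idf, no n-grams: counts keep the fitted weights
directly interpretable (`tidy()` on a fitted model returns per-class-pair
term weights).

The learner is a multi-class linear-kernel SVM (one-vs-one, via e1071/
libsvm) with inverse-class-frequency ("balanced") class weights
`n / (k * n_class)`, cost fixed at the conventional default 1 and recorded
in the configuration. Prediction takes the argmax of per-class sums of the
signed pairwise decision values; exact ties break by the fixed class order
never < former < current < smoker < unknown, so prediction is fully
deterministic. Inputs are never scaled (counts are already comparable and
scaling would break sparsity and reproducibility).

## Behavior extraction

Extraction is rule-based; the patterns are data (a versioned JSON file,
`inst/extdata/rules_v1.json`), so the rule set can be replaced without
code changes.

**Pack years** are evaluated in four tiers, in order: direct pack-year
expressions; packs per day; cigarettes per day; years smoked. A direct
match returns a `complete` finding and stops — lower tiers are never
consulted. Otherwise, if an intensity (packs/day, or cigarettes/day
converted at 20 cigarettes per pack) co-occurs with a duration, the total
is *computed* as `packs_per_day x years_smoked`, rounded to one decimal
(clinical convention); a lone quantity yields a `partial` finding. Word
numbers *one*–*ten*, *half* (0.5) and *a pack* (1) are understood; larger
word numbers are out of scope. When a tier matches several times, the
first match in document order is the note's finding and all matches are
kept in provenance. Durations followed by "ago" ("quit ten years ago")
are explicitly excluded from years-smoked — they are elapsed time, not
exposure.

**Cessation dates** require a cue (quit/stopped/cessation vocabulary)
and a parseable date expression in the *same sentence*; this mirrors the
classifier's same-sentence principle and blocks service-date false
positives. Negated cues ("denies quitting") do not anchor. Date formats:
`MM/DD/YYYY`, `M/D/YY`, `MM/YYYY`, `Month DD, YYYY`, `Month YYYY`, bare
`YYYY`, and `'YY`/`YY` years, each normalized with a precision of day,
month or year (placeholder components are flagged by the precision, not
guessed). Two-digit years pivot at 29 (00–29 are the 2000s). Decades,
seasons and ranges — "quit in the late 1980s" — are rejected by contract:
an approximate decade is not a calendar date, and fabricating one would
poison the registry.

### Numerical and tie-break choices

* Offsets everywhere are 0-based, half-open — unambiguous slicing.
* 20 cigarettes per pack (US standard); pack years rounded to 1 d.p.
* Date candidates in a sentence are tried leftmost-first, most-specific
  pattern first; a candidate that fails to parse simply yields to the
  next (so the year inside an unparseable "in 1995" phrase still parses).
* Empty or whitespace text produces no finding anywhere, never an error.

## Evaluation

`evaluate_predictions()` produces per-class one-vs-rest precision,
recall, F1 (harmonic mean, with `f1(0,0) = 0` by convention), sensitivity
(identical to recall by definition) and specificity, plus micro-F1.
Micro-F1 is computed from pooled true-positive/false-positive/false-
negative counts; in single-label multiclass classification it equals
overall accuracy, and a property test asserts that identity against the
`trace/total` oracle. Rates with zero denominators are reported as `NA`,
never 0 — an undefined rate is not a measured zero. `merge_ever()` pools
the three smoker categories into one *ever smoker* class, turning
cross-smoker confusion (the dominant error mode for this task) into
correct predictions, and reports the resulting two-by-two.
`two_by_two_eval()` scores binary extraction findings against annotation
flags with sensitivity and specificity.

Display rounding follows clinical-reporting convention (2 d.p. for
P/R/F1, one decimal on percentages); internal values keep full precision.

## The synthetic corpus

Real five-class smoking corpora are use-agreement restricted, so the
package ships a deterministic generator (`synth_corpus()`) whose defaults
*are* the study conditions the package is tested under:

* status mix 0.23 / 0.13 / 0.14 / 0.02 / 0.48 (never/former/current/
  smoker/unknown), the class balance of an annotated primary-care note
  sample in which about half the notes carry no status information;
* 60% of smoker-category notes carry consumption information, a quarter
  of which is partial only (one quantity, no derivable total);
* 75% of former-smoker notes record a quit date; 10% instead carry an
  unparseable decade phrase;
* 30% of notes get a distractor sentence (lab panel or service date).

Notes are assembled from section templates (VITALS, SOCIAL HISTORY,
HEALTH SUMMARY, IMPRESSIONS) and a versioned phrasing bank covering every
pipeline path: negated never-phrasings, all consumption tiers, every
supported date format, decade negatives, and hotspot-bearing non-tobacco
text ("smoke detector") for the unknown class. Gold annotations are
exactly what the templates embedded, including source sentences and
spans, so extraction can be scored with zero slack
(`template_coverage_report()` verifies every path is exercised at a given
size). Generation uses R's Mersenne-Twister with a fixed seed; the same
configuration and seed give a byte-identical corpus.

**What the generator does not emulate** — and what passing tests
therefore do not show about real notes: misspellings and typos (off by
default so acceptance floors are stable), creative abbreviation,
contradictory statements within a note, relative dates ("quit 10 years
ago"), copy-forward noise, and the long tail of phrasing variety in real
clinical text. Held-out micro-F1 near 1.0 on this corpus demonstrates
that the pipeline recovers what the templates embed; performance on real
notes will be lower and must be measured on real annotated data.

## Problem sizes and budgets

The shipped tests train on corpora of 80–500 synthetic notes and evaluate
on held-out splits of 100; cross-validation examples use 200 notes with
k = 5; the oracle equivalence for micro-F1 uses 10^4 random confusion
matrices. These sizes were chosen so the whole suite runs in a few
minutes on one core while every template class is still exercised
multiple times.

## Known limitations

* The status classifier can only predict classes it saw among
  hotspot-bearing training notes.
* Relative quit expressions are out of scope by design; only absolute
  date expressions are normalized.
* Registry aggregation (most recent note's status, maximum pack years) is
  one defensible policy among several; whole-record reconciliation of
  conflicting statuses is future work.
* The rule vocabulary is bounded (word numbers one–ten, a fixed cue
  list); it is versioned data precisely so it can be extended without
  touching code.
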