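# smokereg

Build a Smokers' Registry from free-text clinical notes.

Structured EHR fields typically capture *whether* a patient smokes, but
not the behaviors that drive care decisions — cumulative exposure
(pack-years) and, for former smokers, the cessation date. `smokereg`
implements an end-to-end informatics pipeline that recovers this
information from visit notes:

1. **Five-class smoking-status classification** — never, former,
   current, smoker temporality unknown, unknown — with a
   *hotspot-windowed* linear SVM. Four word stems (`smok`, `cig`,
   `tobac`, `nicoti`) mark text worth reading; the classifier sees only
   ±5 word tokens around each occurrence (truncated at sentence
   boundaries), all windows of a note appended. Notes with no hotspot
   are labeled `unknown` by rule. Features are unigram counts with the
   negations *neither/never/no/nor/not* kept out of the stop-word list,
   so "no tobacco use" stays negated. The learner is a linear-kernel
   SVM with balanced (inverse-class-frequency) weights.
2. **Gated rule-based extraction** — only notes classified
   former/current/smoker are searched (this keeps lab panels and
   service dates in other notes from ever being assessed). Pack-year
   tiers run in order: direct pack-year expressions (stop on match),
   then packs/day, cigarettes/day, years smoked. An intensity plus a
   duration yields a computed total,
   `pack_years = packs_per_day × years_smoked` (cigarettes convert at
   20/pack); a lone quantity is kept as partial information. Cessation
   dates require a quit/stopped cue and a parseable date in the same
   sentence; `MM/DD/YYYY`, `M/D/YY`, `Month DD, YYYY`, `Month YYYY`,
   `MM/YYYY`, bare `YYYY` and `'YY` are normalized with day/month/year
   precision, while vague decade phrases ("quit in the late 1980s") are
   rejected by contract.
3. **Registry assembly** — one record per smoker-classified note,
   exported as a de-identified population table and an identified
   contact table, with optional per-patient aggregation.

The package also ships the evaluation suite used throughout (per-class
precision/recall/F1, micro-F1 — which equals accuracy in single-label
multiclass classification — sensitivity/specificity, ever-smoker
merging, 2×2 extraction evaluation) and a deterministic synthetic-note
generator, since real five-class smoking corpora are
use-agreement-restricted.

## Worked example

```r
library(smokereg)
library(dplyr)

corpus <- synth_corpus(synth_config(n_notes = 500, seed = 42))
count(corpus, status)
#>   status      n
#> 1 never     104
#> 2 former     70
#> 3 current    71
#> 4 smoker      6
#> 5 unknown   249

train <- corpus[1:400, ]
test  <- corpus[401:500, ]
model <- fit_status_model(train, status_config(seed = 1))
model
#> <status_model>
#>   classes: never, former, current, smoker, unknown
#>   training notes (hotspot-bearing): 297
#>   vocabulary size: 134
#>   hotspots: smok,cig,tobac,nicoti; mode=words; window=5
```

103 of the 400 training notes contain no hotspot at all; they are
covered by the `unknown` rule, not the learner. Running the pipeline on
the held-out notes classifies every note and extracts behaviors from the
smoker-classified ones:

```r
result <- run_pipeline(test, model)
evaluate_predictions(test$status, result$predictions$status)
#> <smoke_eval> n = 100, micro-F1 = 1.00
#>    class  n precision recall f1 sensitivity specificity
#>    never 21         1      1  1      100.0%      100.0%
#>   former 13         1      1  1      100.0%      100.0%
#>  current 10         1      1  1      100.0%      100.0%
#>   smoker  1         1      1  1      100.0%      100.0%
#>  unknown 55         1      1  1      100.0%      100.0%
#> ever smoker (merged): sensitivity 100.0%, specificity 100.0%

head(select(result$records, note_id, status, pack_year_kind,
            pack_years, cessation_date), 4)
#>   note_id status  pack_year_kind pack_years cessation_date
#> 1 N0405   former  partial              NA   1992-07-01
#> 2 N0407   smoker  partial              NA   NA
#> 3 N0414   current computed             14.5 NA
#> 4 N0418   current <NA>                 NA   NA
```

Note N0414 had no stated pack-year total; the pipeline computed 14.5
from an intensity and a duration found in the text. The perfect held-out
scores reflect the clean synthetic phrasing bank, not expected
performance on real notes (see the vignette's discussion of what the
generator does and does not emulate). The fitted weights stay
human-readable:

```r
head(tidy(model), 3)
#>   pair          term    weight
#> 1 current/never never   -1.17
#> 2 current/never active   0.832
#> 3 current/never current  0.832
```

`build_registry_tables(result$records)` then yields the population and
contact tables, and `write_registry_tables()` writes them as CSV. A
command-line interface covering the same workflow
(`synth` / `train` / `predict` / `extract` / `run` / `evaluate`) is
installed at `inst/cli/smokereg` and exposed as `smokereg_main()`.

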