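# Fixtures are built in code: small corpora with the full corpus schema.

corpus_row <- function(note_id, text, status = NA_character_,
                       patient_id = NA_character_, visit_date = as.Date(NA),
                       pack_years = NA_real_, packs_per_day = NA_real_,
                       cigarettes_per_day = NA_real_, years_smoked = NA_real_,
                       cessation_date = as.Date(NA),
                       cessation_precision = NA_character_,
                       has_pack_year_info = NA) {
  tibble::tibble(
    note_id = note_id, text = text, visit_date = visit_date,
    patient_id = patient_id, status = parse_status(status),
    has_pack_year_info = has_pack_year_info,
    pack_years = pack_years, packs_per_day = packs_per_day,
    cigarettes_per_day = cigarettes_per_day, years_smoked = years_smoked,
    cessation_date = cessation_date,
    cessation_precision = cessation_precision,
    meta = list(list())
  )
}

make_corpus <- function(texts, statuses = rep(NA_character_, length(texts)),
                        ...) {
  dplyr::bind_rows(purrr::map(seq_along(texts), function(i) {
    corpus_row(sprintf("T%03d", i), texts[i], statuses[i], ...)
  }))
}

# linearly separable two-class toy corpus: disjoint vocabularies
toy_separable_corpus <- function() {
  current <- c(
    "Heavy smoker, smokes daily.", "Active smoking habit, smokes often.",
    "Smokes heavily, active habit.", "Daily smoking, heavy habit.",
    "Smokes daily, heavy active smoker.", "Smoking habit active daily.",
    "Heavy daily smoking continues.", "Active heavy smoker daily.",
    "Smokes, heavy habit continues.", "Daily active smoking habit."
  )
  never <- c(
    "Nonsmoker, zero tobacco lifetime.", "Zero tobacco exposure lifetime nonsmoker.",
    "Lifetime nonsmoker, tobacco zero.", "Tobacco zero, nonsmoker lifetime.",
    "Nonsmoker lifetime, zero tobacco.", "Zero lifetime tobacco, nonsmoker.",
    "Tobacco exposure zero, lifetime nonsmoker.", "Nonsmoker, lifetime zero tobacco.",
    "Lifetime zero tobacco nonsmoker.", "Zero tobacco nonsmoker lifetime."
  )
  make_corpus(c(current, never),
              c(rep("current", 10), rep("never", 10)))
}
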