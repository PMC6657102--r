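# End-to-end workflow: classify every note, gate behavior extraction on
# the smoker statuses, assemble registry records and tables.
#
# The gate is the pipeline's false-positive control: pack-year and
# cessation rules run ONLY on notes classified former/current/smoker, so
# lab panels and service dates in never/unknown notes are never assessed.

#' Run the full pipeline over a corpus
#'
#' Every note receives a status prediction (zero-hotspot notes are
#' `"unknown"` by rule). Behavior extraction ([extract_behaviors()]) runs
#' only on notes predicted into a smoker category (former, current,
#' smoker temporality unknown); each such note yields one registry
#' record.
#'
#' @param corpus Corpus tibble.
#' @param model A fitted `status_model`.
#' @param rules A [load_rules()] rule set.
#' @return List with `predictions` (one row per note: status, rule
#'   provenance, decision scores, findings for gated notes) and `records`
#'   (one registry record per smoker-classified note).
#' @export
run_pipeline <- function(corpus, model, rules = default_rules()) {
  predictions <- predict(model, corpus)
  gated <- predictions$status %in% smoker_statuses()
  findings <- purrr::map(seq_len(nrow(corpus)), function(i) {
    if (!gated[i]) return(no_behaviors())
    extract_behaviors(corpus$text[i], rules)
  })
  predictions <- dplyr::bind_cols(predictions, dplyr::bind_rows(findings))
  records <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = corpus$patient_id[gated],
      note_id = corpus$note_id[gated],
      note_date = corpus$visit_date[gated]
    ),
    predictions[gated, c(
      "status", "pack_year_kind", "pack_years", "packs_per_day",
      "cigarettes_per_day", "years_smoked", "pack_year_text",
      "cessation_date", "cessation_precision", "cessation_text"
    )]
  )
  list(predictions = predictions, records = records)
}

#' Build registry tables from registry records
#'
#' Produces the two registry tables: a de-identified population table
#' (no patient identifiers) and an identified contact table (patient_id
#' plus the same fields). Both derive row-for-row from the same record
#' list; empty input yields header-only (zero-row) tables.
#'
#' @param records Registry record tibble from [run_pipeline()].
#' @return List with `population` and `contact` tibbles.
#' @export
build_registry_tables <- function(records) {
  fields <- c("status", "pack_year_kind", "pack_years", "packs_per_day",
              "cigarettes_per_day", "years_smoked", "cessation_date",
              "cessation_precision", "note_date")
  fields <- intersect(fields, names(records))
  list(
    population = records[, fields, drop = FALSE],
    contact = records[, c("patient_id", "note_id", fields), drop = FALSE]
  )
}

#' Aggregate note-level registry records to one row per patient
#'
#' When a patient has several smoker-classified notes, the patient keeps
#' the most recent note's status (ties broken by note_id, undated notes
#' last) and the maximum pack-year total across notes; the most recent
#' non-missing cessation date is retained.
#'
#' @param records Registry record tibble from [run_pipeline()]; rows with
#'   missing `patient_id` are dropped.
#' @return One row per patient.
#' @export
aggregate_patients <- function(records) {
  records <- records[!is.na(records$patient_id), ]
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(!is.na(.data$note_date), .data$note_date, .data$note_id,
                   .by_group = TRUE) |>
    dplyr::summarise(
      status = dplyr::last(.data$status),
      note_id = dplyr::last(.data$note_id),
      note_date = dplyr::last(.data$note_date),
      pack_years = if (all(is.na(.data$pack_years))) NA_real_ else
        max(.data$pack_years, na.rm = TRUE),
      cessation_date = if (all(is.na(.data$cessation_date))) as.Date(NA) else
        dplyr::last(.data$cessation_date[!is.na(.data$cessation_date)]),
      n_notes = dplyr::n(),
      .groups = "drop"
    )
}

#' Write registry tables to CSV
#'
#' @param tables List from [build_registry_tables()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_registry_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- file.path(dir, "population_table.csv")
  con <- file.path(dir, "contact_table.csv")
  utils::write.csv(tables$population, pop, row.names = FALSE, na = "")
  utils::write.csv(tables$contact, con, row.names = FALSE, na = "")
  invisible(c(population = pop, contact = con))
}
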