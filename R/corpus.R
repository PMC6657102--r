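# Corpus I/O: JSON-lines native dialect plus an optional reader for the
# 2006 i2b2 smoking-challenge XML record format.
#
# JSONL schema (one UTF-8 JSON object per line; lines starting with '#'
# are comments and skipped):
#   note_id   string, required, unique within a file
#   text      string, required, non-empty after whitespace stripping
#   visit_date   optional ISO "YYYY-MM-DD"
#   patient_id   optional string
#   gold      optional object: status, has_pack_year_info, pack_years,
#             packs_per_day, cigarettes_per_day, years_smoked,
#             cessation_date (ISO), cessation_precision (day|month|year)
# Unknown fields are preserved in the `meta` list-column.

gold_cols <- function() {
  c("status", "has_pack_year_info", "pack_years", "packs_per_day",
    "cigarettes_per_day", "years_smoked", "cessation_date",
    "cessation_precision")
}

empty_corpus <- function() {
  tibble::tibble(
    note_id = character(), text = character(),
    visit_date = as.Date(character()), patient_id = character(),
    status = parse_status(character()),
    has_pack_year_info = logical(),
    pack_years = double(), packs_per_day = double(),
    cigarettes_per_day = double(), years_smoked = double(),
    cessation_date = as.Date(character()),
    cessation_precision = character(),
    meta = list()
  )
}

as_scalar <- function(x, default = NA) {
  if (is.null(x) || length(x) == 0) default else x[[1]]
}

parse_iso_date <- function(x) {
  if (is.na(x)) return(as.Date(NA))
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  d
}

#' Read a corpus of clinical notes
#'
#' Reads clinical notes (optionally carrying gold annotations) into a
#' tibble with one row per note. Two dialects are supported: the package's
#' native JSON-lines format, and the 2006 i2b2 smoking-challenge XML record
#' format (`ROOT/RECORD/SMOKING/TEXT`; its status strings, including
#' `"PAST SMOKER"`, are mapped onto the five canonical classes).
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (default) or `"i2b2_xml"`.
#' @return A tibble with columns `note_id`, `text`, `visit_date`,
#'   `patient_id`, the gold-annotation columns (`status`,
#'   `has_pack_year_info`, `pack_years`, `packs_per_day`,
#'   `cigarettes_per_day`, `years_smoked`, `cessation_date`,
#'   `cessation_precision`; `NA` where unannotated) and a `meta`
#'   list-column holding any unrecognized fields.
#' @export
read_corpus <- function(path, format = c("jsonl", "i2b2_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  corpus <- switch(format,
    jsonl = read_corpus_jsonl(path),
    i2b2_xml = read_corpus_i2b2(path)
  )
  validate_corpus(corpus)
  corpus
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_corpus())
  rows <- purrr::map2(lines[idx], seq_along(idx), function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        abort(sprintf("Record %d: not valid JSON (%s)", i, conditionMessage(e)))
      }
    )
    parse_jsonl_record(rec, i)
  })
  dplyr::bind_rows(rows)
}

parse_jsonl_record <- function(rec, i) {
  if (is.null(rec$note_id) || !nzchar(as.character(rec$note_id))) {
    abort(sprintf("Record %d: missing field 'note_id'", i))
  }
  txt <- as_scalar(rec$text, NA_character_)
  if (is.na(txt) || !nzchar(trimws(txt))) {
    abort(sprintf("Record %d (note_id=%s): field 'text' is empty",
                  i, rec$note_id))
  }
  gold <- rec$gold %||% list()
  known <- c("note_id", "text", "visit_date", "patient_id", "gold")
  meta <- rec[setdiff(names(rec), known)]
  tibble::tibble(
    note_id = as.character(rec$note_id),
    text = txt,
    visit_date = parse_iso_date(as_scalar(rec$visit_date, NA_character_)),
    patient_id = as.character(as_scalar(rec$patient_id, NA_character_)),
    status = parse_status(as_scalar(gold$status, NA_character_)),
    has_pack_year_info = as.logical(as_scalar(gold$has_pack_year_info, NA)),
    pack_years = as.double(as_scalar(gold$pack_years, NA_real_)),
    packs_per_day = as.double(as_scalar(gold$packs_per_day, NA_real_)),
    cigarettes_per_day = as.double(as_scalar(gold$cigarettes_per_day, NA_real_)),
    years_smoked = as.double(as_scalar(gold$years_smoked, NA_real_)),
    cessation_date = parse_iso_date(as_scalar(gold$cessation_date, NA_character_)),
    cessation_precision = as.character(as_scalar(gold$cessation_precision, NA_character_)),
    meta = list(meta)
  )
}

# i2b2 2006 smoking-challenge status strings -> canonical classes.
i2b2_status_map <- function(s) {
  key <- toupper(trimws(s))
  map <- c(
    "CURRENT SMOKER" = "current",
    "PAST SMOKER" = "former",
    "PAST" = "former",
    "FORMER SMOKER" = "former",
    "NON-SMOKER" = "never",
    "NEVER SMOKER" = "never",
    "NEVER" = "never",
    "SMOKER" = "smoker",
    "UNKNOWN" = "unknown",
    "CURRENT" = "current"
  )
  out <- unname(map[key])
  if (any(is.na(out))) {
    abort(sprintf("Unrecognized i2b2 smoking status: %s",
                  paste(unique(s[is.na(out)]), collapse = ", ")))
  }
  out
}

read_corpus_i2b2 <- function(path) {
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, ".//RECORD")
  if (length(recs) == 0) return(empty_corpus())
  rows <- purrr::imap(recs, function(rec, i) {
    id <- xml2::xml_attr(rec, "ID")
    if (is.na(id)) abort(sprintf("Record %d: missing ID attribute", i))
    smoking <- xml2::xml_find_first(rec, ".//SMOKING")
    status <- if (inherits(smoking, "xml_missing")) NA_character_ else {
      i2b2_status_map(xml2::xml_attr(smoking, "STATUS"))
    }
    txt <- xml2::xml_text(xml2::xml_find_first(rec, ".//TEXT"))
    if (is.na(txt) || !nzchar(trimws(txt))) {
      abort(sprintf("Record %d (ID=%s): empty TEXT element", i, id))
    }
    row <- empty_corpus()[0, ]
    tibble::add_row(row,
      note_id = id, text = txt, status = parse_status(status)[1],
      meta = list(list())
    )
  })
  dplyr::bind_rows(rows)
}

validate_corpus <- function(corpus) {
  dup <- corpus$note_id[duplicated(corpus$note_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate note_id: %s", paste(unique(dup), collapse = ", ")))
  }
  # never/unknown notes cannot carry pack-year or cessation gold
  bad <- !is.na(corpus$status) &
    corpus$status %in% c("never", "unknown") &
    (dplyr::coalesce(corpus$has_pack_year_info, FALSE) |
       !is.na(corpus$cessation_date))
  if (any(bad)) {
    abort(sprintf(
      "Gold invariant violated (never/unknown note with pack-year or cessation gold): %s",
      paste(corpus$note_id[bad], collapse = ", ")
    ))
  }
  invisible(corpus)
}

#' Write a corpus to JSON-lines
#'
#' Inverse of [read_corpus()] on the JSONL dialect: `read_corpus()` after
#' `write_corpus()` reproduces the corpus field-for-field.
#'
#' @param corpus Corpus tibble as returned by [read_corpus()] or
#'   [synth_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    rec <- list(note_id = row$note_id, text = row$text)
    if (!is.na(row$visit_date)) rec$visit_date <- format(row$visit_date)
    if (!is.na(row$patient_id)) rec$patient_id <- row$patient_id
    gold <- list()
    if (!is.na(row$status)) gold$status <- as.character(row$status)
    if (!is.na(row$has_pack_year_info)) gold$has_pack_year_info <- row$has_pack_year_info
    for (col in c("pack_years", "packs_per_day", "cigarettes_per_day", "years_smoked")) {
      if (!is.na(row[[col]])) gold[[col]] <- row[[col]]
    }
    if (!is.na(row$cessation_date)) {
      gold$cessation_date <- format(row$cessation_date)
      gold$cessation_precision <- row$cessation_precision
    }
    if (length(gold) > 0) rec$gold <- gold
    meta <- row$meta[[1]]
    if (length(meta) > 0) rec[names(meta)] <- meta
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write note-level predictions and findings to JSON-lines
#'
#' Serializes one record per predicted note: the note identifiers plus a
#' `prediction` object (status, rule provenance, decision scores, and any
#' pack-year or cessation findings). The file is readable back with
#' [read_predictions()]; [read_corpus()] also accepts it when `text` is
#' carried along.
#'
#' @param corpus Corpus tibble; every prediction's `note_id` must appear in
#'   it.
#' @param predictions Prediction tibble as returned by
#'   [predict.status_model()] or [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(corpus, predictions, path) {
  missing_ids <- setdiff(predictions$note_id, corpus$note_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Predictions refer to unknown note_id: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  header <- "# smokereg predictions v1 (one JSON object per line)"
  if (nrow(predictions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  lines <- purrr::map_chr(seq_len(nrow(predictions)), function(i) {
    row <- predictions[i, ]
    pred <- list(
      status = as.character(row$status),
      via_hotspot_rule = row$via_hotspot_rule
    )
    if (!is.null(row$decision_scores) && !is.null(row$decision_scores[[1]])) {
      pred$decision_scores <- as.list(row$decision_scores[[1]])
    }
    for (col in c("pack_year_kind", "pack_years", "packs_per_day",
                  "cigarettes_per_day", "years_smoked", "pack_year_text")) {
      if (col %in% names(row) && !is.na(row[[col]])) pred[[col]] <- row[[col]]
    }
    if ("cessation_date" %in% names(row) && !is.na(row$cessation_date)) {
      pred$cessation_date <- format(row$cessation_date)
      pred$cessation_precision <- row$cessation_precision
      if ("cessation_text" %in% names(row)) pred$cessation_text <- row$cessation_text
    }
    rec <- list(note_id = row$note_id, prediction = pred)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path Path to a predictions JSONL file.
#' @return Prediction tibble (one row per note).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_predictions())
  rows <- purrr::imap(lines, function(line, i) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    p <- rec$prediction
    if (is.null(p)) abort(sprintf("Record %d: missing 'prediction' object", i))
    tibble::tibble(
      note_id = as.character(rec$note_id),
      status = parse_status(p$status),
      via_hotspot_rule = as.logical(p$via_hotspot_rule),
      decision_scores = list(
        if (is.null(p$decision_scores)) NULL else unlist(p$decision_scores)
      ),
      pack_year_kind = as.character(as_scalar(p$pack_year_kind, NA_character_)),
      pack_years = as.double(as_scalar(p$pack_years, NA_real_)),
      packs_per_day = as.double(as_scalar(p$packs_per_day, NA_real_)),
      cigarettes_per_day = as.double(as_scalar(p$cigarettes_per_day, NA_real_)),
      years_smoked = as.double(as_scalar(p$years_smoked, NA_real_)),
      pack_year_text = as.character(as_scalar(p$pack_year_text, NA_character_)),
      cessation_date = parse_iso_date(as_scalar(p$cessation_date, NA_character_)),
      cessation_precision = as.character(as_scalar(p$cessation_precision, NA_character_)),
      cessation_text = as.character(as_scalar(p$cessation_text, NA_character_))
    )
  })
  dplyr::bind_rows(rows)
}

empty_predictions <- function() {
  tibble::tibble(
    note_id = character(),
    status = parse_status(character()),
    via_hotspot_rule = logical(),
    decision_scores = list(),
    pack_year_kind = character(),
    pack_years = double(), packs_per_day = double(),
    cigarettes_per_day = double(), years_smoked = double(),
    pack_year_text = character(),
    cessation_date = as.Date(character()),
    cessation_precision = character(),
    cessation_text = character()
  )
}
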