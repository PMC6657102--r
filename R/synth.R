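# Deterministic generator of labeled, semi-structured synthetic clinical
# notes. Notes mimic the section structure of real visit notes (vitals,
# social history, health summary, impressions); smoking sentences come
# from a versioned phrasing bank covering every pipeline path: the five
# status classes (including negated never-phrasings and hotspot-bearing
# non-tobacco "smoke detector" text for unknown), complete/computed/
# partial consumption quantities, cessation dates in every supported
# format plus unparseable decade phrases, and distractor sentences with
# lab values and service dates.
#
# The gold annotation of each note is exactly what the templates
# embedded, so extraction can be scored against it with zero slack.

#' Synthetic-corpus configuration
#'
#' Defaults reflect the class balance of a primary-care note sample in
#' which roughly half the notes carry no smoking-status information, and
#' the annotated rates of consumption and cessation documentation among
#' smoker notes: about 60% of smoker-category notes carry pack-year
#' information, a quarter of which is partial only, and about three
#' quarters of former-smoker notes record a quit date.
#'
#' @param n_notes Number of notes.
#' @param seed Integer seed (Mersenne-Twister; identical seed gives a
#'   byte-identical corpus).
#' @param status_mix Named probability vector over the five classes
#'   (never, former, current, smoker, unknown); must sum to 1.
#' @param p_pack_year_complete Probability that a smoker-category note
#'   carries a derivable pack-year total (directly stated, or computable
#'   from intensity and duration).
#' @param p_pack_year_partial Probability of partial-only consumption
#'   information (one quantity, no derivable total).
#' @param p_cessation_date Probability that a former-smoker note records
#'   a parseable quit date.
#' @param p_cessation_vague Probability of an unparseable decade phrase
#'   ("quit in the late 1980s") instead of a date.
#' @param p_distractor Probability of injecting a distractor sentence
#'   (lab panel or service date) into a note.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_notes = 500L,
                         seed = 42L,
                         status_mix = c(never = 0.23, former = 0.13,
                                        current = 0.14, smoker = 0.02,
                                        unknown = 0.48),
                         p_pack_year_complete = 0.45,
                         p_pack_year_partial = 0.15,
                         p_cessation_date = 0.75,
                         p_cessation_vague = 0.10,
                         p_distractor = 0.30) {
  if (!setequal(names(status_mix), smoking_statuses())) {
    abort("status_mix must be named with the five status classes")
  }
  status_mix <- status_mix[smoking_statuses()]
  probs <- c(status_mix, p_pack_year_complete, p_pack_year_partial,
             p_cessation_date, p_cessation_vague, p_distractor)
  if (any(probs < 0) || any(probs > 1)) abort("Probabilities must lie in [0, 1]")
  if (abs(sum(status_mix) - 1) > 1e-8) abort("status_mix must sum to 1")
  if (p_pack_year_complete + p_pack_year_partial > 1) {
    abort("p_pack_year_complete + p_pack_year_partial must be <= 1")
  }
  structure(
    list(
      n_notes = as.integer(n_notes), seed = as.integer(seed),
      status_mix = status_mix,
      p_pack_year_complete = p_pack_year_complete,
      p_pack_year_partial = p_pack_year_partial,
      p_cessation_date = p_cessation_date,
      p_cessation_vague = p_cessation_vague,
      p_distractor = p_distractor,
      template_bank_version = "1"
    ),
    class = "synth_config"
  )
}

pick <- function(x) if (length(x) == 1) x else x[[sample.int(length(x), 1)]]

# --- phrasing banks (template bank v1) --------------------------------

status_phrases <- function(status) {
  switch(status,
    never = c(
      "Never smoker.", "No tobacco use.", "Denies smoking.",
      "Patient has never smoked.", "Nonsmoker.",
      "Tobacco use: never.", "Denies any cigarette use."
    ),
    former = c(
      "Former smoker.", "Ex-smoker.", "Tobacco use: former.",
      "Patient is a former smoker.", "Remote smoking history, now abstinent."
    ),
    current = c(
      "Current smoker.", "Active smoker.", "Tobacco use: current every day smoker.",
      "Patient smokes cigarettes daily.", "Continues to smoke."
    ),
    smoker = c(
      "Positive smoking history, temporality unclear.",
      "Smoking history noted in chart.",
      "Tobacco history present, details not documented.",
      "Patient is a smoker per old records, current use unclear."
    ),
    unknown = c(
      "Home smoke detector batteries replaced.",
      "Counseled on fire safety; smoke alarm present and functional.",
      "Discussed smoke detector placement at home."
    )
  )
}

filler_sentences <- function() {
  c("Patient feels well overall.", "Reviewed medication list.",
    "No acute distress.", "Diet and exercise discussed.",
    "Sleep is adequate.", "Will continue current plan.",
    "Return to clinic as needed.", "Immunizations up to date.")
}

distractor_sentences <- function() {
  c("CBC drawn 03/15/2014.", "Labs: WBC 9.5, Hgb 13.2, Plt 250.",
    "Last visit 04/02/2016.", "Follow-up scheduled 05/01/2016.",
    "Basic metabolic panel collected 11/30/2015.",
    "A1c 6.1 on 02/10/2016.")
}

random_date <- function(year_min = 1975, year_max = 2015) {
  list(
    year = sample(seq(year_min, year_max), 1),
    month = sample(1:12, 1),
    day = sample(1:28, 1)
  )
}

# consumption sentence + gold quantities for one smoker-category note;
# verb is tense-matched to the status ("Smokes" current, "Smoked" else)
draw_consumption <- function(config, verb = "Smoked") {
  u <- stats::runif(1)
  if (u < config$p_pack_year_complete) {
    kind <- pick(c("complete", "computed_ppd", "computed_cpd"))
  } else if (u < config$p_pack_year_complete + config$p_pack_year_partial) {
    kind <- pick(c("partial_ppd", "partial_cpd", "partial_years"))
  } else {
    return(NULL)
  }
  ppd_vals <- c(0.5, 1, 1.5, 2, 3)
  cpd_vals <- c(5, 10, 15, 20, 30, 40)
  yrs <- sample(5:50, 1)
  if (kind == "complete") {
    py <- sample(c(5, 10, 15, 20, 25, 30, 40, 50, 60), 1)
    text <- pick(c(
      sprintf("%g pack year history.", py),
      sprintf("Approximately %g pack-year smoking history.", py),
      sprintf("Pack years: %g.", py)
    ))
    return(list(kind = kind, text = text, pack_years = py,
                packs_per_day = NA_real_, cigarettes_per_day = NA_real_,
                years_smoked = NA_real_))
  }
  if (kind == "computed_ppd") {
    ppd <- pick(ppd_vals)
    text <- pick(c(
      sprintf("%s %g packs per day for %d years.", verb, ppd, yrs),
      sprintf("%g ppd x %d yrs.", ppd, yrs),
      sprintf("Reports %g packs a day for %d years.", ppd, yrs)
    ))
    return(list(kind = kind, text = text,
                pack_years = round(ppd * yrs, 1),
                packs_per_day = ppd, cigarettes_per_day = NA_real_,
                years_smoked = yrs))
  }
  if (kind == "computed_cpd") {
    cpd <- pick(cpd_vals)
    text <- pick(c(
      sprintf("%s %d cigarettes a day for %d years.", verb, cpd, yrs),
      sprintf("%d cigarettes per day for %d years.", cpd, yrs)
    ))
    return(list(kind = kind, text = text,
                pack_years = round(cpd / cigarettes_per_pack * yrs, 1),
                packs_per_day = NA_real_, cigarettes_per_day = cpd,
                years_smoked = yrs))
  }
  if (kind == "partial_ppd") {
    ppd <- pick(ppd_vals)
    text <- if (ppd == 0.5) {
      pick(c(sprintf("%s about half a pack per day.", verb), "0.5 ppd."))
    } else {
      pick(c(sprintf("%s %g packs per day.", verb, ppd),
             sprintf("%g ppd.", ppd)))
    }
    return(list(kind = kind, text = text, pack_years = NA_real_,
                packs_per_day = ppd, cigarettes_per_day = NA_real_,
                years_smoked = NA_real_))
  }
  if (kind == "partial_cpd") {
    cpd <- pick(cpd_vals)
    text <- pick(c(sprintf("%s %d cigarettes a day.", verb, cpd),
                   sprintf("About %d cigarettes per day.", cpd)))
    return(list(kind = kind, text = text, pack_years = NA_real_,
                packs_per_day = NA_real_, cigarettes_per_day = cpd,
                years_smoked = NA_real_))
  }
  # partial_years
  list(kind = "partial_years",
       text = pick(c(sprintf("Has smoked for %d years.", yrs),
                     sprintf("Smoked for %d years.", yrs))),
       pack_years = NA_real_, packs_per_day = NA_real_,
       cigarettes_per_day = NA_real_, years_smoked = yrs)
}

# cessation sentence + gold date for one former-smoker note
draw_cessation <- function(config) {
  u <- stats::runif(1)
  if (u < config$p_cessation_vague) {
    decade <- pick(c("1970s", "1980s", "1990s"))
    text <- sprintf("Quit in the %s %s.", pick(c("early", "late", "mid")), decade)
    return(list(format = "decade", text = text,
                date = as.Date(NA), precision = NA_character_))
  }
  if (u > config$p_cessation_vague + config$p_cessation_date) return(NULL)
  d <- random_date()
  fmt <- pick(c("mdy_slash", "mdy_slash2", "month_dd_yyyy", "month_yyyy",
                "mm_yyyy", "yyyy", "two_digit"))
  cue <- pick(c("Quit smoking", "Stopped smoking", "Quit tobacco"))
  out <- switch(fmt,
    mdy_slash = list(
      text = sprintf("%s %02d/%02d/%d.", cue, d$month, d$day, d$year),
      date = make_date(d$year, d$month, d$day), precision = "day"),
    mdy_slash2 = list(
      text = sprintf("%s %d/%d/%02d.", cue, d$month, d$day, d$year %% 100),
      date = make_date(d$year, d$month, d$day), precision = "day"),
    month_dd_yyyy = list(
      text = sprintf("%s %s %d, %d.", cue, month.name[d$month], d$day, d$year),
      date = make_date(d$year, d$month, d$day), precision = "day"),
    month_yyyy = list(
      text = sprintf("%s in %s %d.", cue, month.name[d$month], d$year),
      date = make_date(d$year, d$month, 1L), precision = "month"),
    mm_yyyy = list(
      text = sprintf("%s %02d/%d.", cue, d$month, d$year),
      date = make_date(d$year, d$month, 1L), precision = "month"),
    yyyy = list(
      text = sprintf("%s in %d.", cue, d$year),
      date = make_date(d$year, 1L, 1L), precision = "year"),
    two_digit = list(
      text = sprintf("%s in '%02d.", cue, d$year %% 100),
      date = make_date(d$year, 1L, 1L), precision = "year")
  )
  # two-digit years must respect the parser's pivot (00-29 -> 2000s)
  if (fmt %in% c("mdy_slash2", "two_digit")) {
    out$date <- make_date(pivot_two_digit_year(d$year %% 100),
                          if (fmt == "two_digit") 1L else d$month,
                          if (fmt == "two_digit") 1L else d$day)
  }
  c(out, list(format = fmt))
}

#' Generate a synthetic labeled corpus
#'
#' Assembles `n_notes` semi-structured notes from section templates and
#' the phrasing bank, with full gold annotations (status, embedded
#' quantities and dates, and the source sentences and spans in the `meta`
#' column). The same configuration and seed always produce a
#' byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @return Corpus tibble (see [read_corpus()] for columns).
#' @export
#' @examples
#' corpus <- synth_corpus(synth_config(n_notes = 20, seed = 1))
#' dplyr::count(corpus, status)
synth_corpus <- function(config = synth_config()) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  statuses <- sample(smoking_statuses(), config$n_notes, replace = TRUE,
                     prob = config$status_mix)
  rows <- purrr::map(seq_len(config$n_notes), function(i) {
    synth_note(sprintf("N%04d", i), sprintf("P%04d", i), statuses[i], config)
  })
  validate_corpus(dplyr::bind_rows(rows))
}

synth_note <- function(note_id, patient_id, status, config) {
  smoker <- status %in% smoker_statuses()
  verb <- if (status == "current") "Smokes" else "Smoked"
  consumption <- if (smoker) draw_consumption(config, verb) else NULL
  cessation <- if (status == "former") draw_cessation(config) else NULL

  smoking_lines <- character()
  if (status == "unknown") {
    # half the unknowns mention nothing smoking-related at all (the
    # zero-hotspot rule path); the rest carry non-tobacco "smoke" text
    if (stats::runif(1) < 0.5) smoking_lines <- pick(status_phrases("unknown"))
  } else {
    smoking_lines <- pick(status_phrases(status))
    if (!is.null(consumption)) smoking_lines <- c(smoking_lines, consumption$text)
    if (!is.null(cessation)) smoking_lines <- c(smoking_lines, cessation$text)
  }

  vitals <- sprintf("BP %d/%d, HR %d.", sample(100:150, 1),
                    sample(60:95, 1), sample(55:100, 1))
  sections <- list(
    c("VITALS:", vitals),
    c("SOCIAL HISTORY:",
      if (length(smoking_lines) > 0 && stats::runif(1) < 0.8) smoking_lines else pick(filler_sentences())),
    c("HEALTH SUMMARY:", pick(filler_sentences())),
    c("IMPRESSIONS:", pick(filler_sentences()))
  )
  # smoking text that did not land in social history goes to impressions
  if (length(smoking_lines) > 0 && !any(smoking_lines[1] == sections[[2]])) {
    sections[[4]] <- c("IMPRESSIONS:", smoking_lines, pick(filler_sentences()))
  }
  if (stats::runif(1) < config$p_distractor) {
    sections[[3]] <- c("HEALTH SUMMARY:", pick(distractor_sentences()),
                       sections[[3]][-1])
  }
  lines <- unlist(sections)
  text <- paste(lines, collapse = "\n")

  locate <- function(s) {
    if (is.null(s)) return(list(start = NA_integer_, end = NA_integer_))
    start <- regexpr(s, text, fixed = TRUE)[[1]]
    list(start = as.integer(start - 1L), end = as.integer(start - 1L + nchar(s)))
  }
  cons_span <- locate(consumption$text)
  cess_span <- locate(cessation$text)

  tibble::tibble(
    note_id = note_id,
    text = text,
    visit_date = as.Date("2016-03-28") + sample(0:7, 1),
    patient_id = patient_id,
    status = parse_status(status),
    has_pack_year_info = smoker && !is.null(consumption),
    pack_years = if (!is.null(consumption)) consumption$pack_years else NA_real_,
    packs_per_day = if (!is.null(consumption)) consumption$packs_per_day else NA_real_,
    cigarettes_per_day = if (!is.null(consumption)) consumption$cigarettes_per_day else NA_real_,
    years_smoked = if (!is.null(consumption)) consumption$years_smoked else NA_real_,
    cessation_date = if (!is.null(cessation)) cessation$date else as.Date(NA),
    cessation_precision = if (!is.null(cessation)) cessation$precision else NA_character_,
    meta = list(list(
      consumption_kind = if (is.null(consumption)) NA_character_ else consumption$kind,
      consumption_text = if (is.null(consumption)) NA_character_ else consumption$text,
      consumption_start = cons_span$start, consumption_end = cons_span$end,
      cessation_format = if (is.null(cessation)) NA_character_ else cessation$format,
      cessation_text = if (is.null(cessation)) NA_character_ else cessation$text,
      cessation_start = cess_span$start, cessation_end = cess_span$end
    ))
  )
}

#' Template-coverage report for a synthetic corpus
#'
#' Tallies, over the generated gold, how often each extraction path is
#' exercised: every consumption kind (complete, computed via packs/day,
#' computed via cigarettes/day, each partial quantity), every cessation
#' date format plus the unparseable decade phrase, and distractor text.
#' Lists any template class left unexercised at the configured size.
#'
#' @param corpus A [synth_corpus()] corpus (the `meta` column must carry
#'   the generator's gold provenance).
#' @return Tibble with columns `category`, `n`, `covered`.
#' @export
template_coverage_report <- function(corpus) {
  meta <- purrr::map(corpus$meta, ~.x)
  kinds <- purrr::map_chr(meta, ~ .x$consumption_kind %||% NA_character_)
  fmts <- purrr::map_chr(meta, ~ .x$cessation_format %||% NA_character_)
  expected_kinds <- c("complete", "computed_ppd", "computed_cpd",
                      "partial_ppd", "partial_cpd", "partial_years")
  expected_fmts <- c("mdy_slash", "mdy_slash2", "month_dd_yyyy",
                     "month_yyyy", "mm_yyyy", "yyyy", "two_digit", "decade")
  rows <- c(
    purrr::map(expected_kinds, function(k) {
      tibble::tibble(category = paste0("consumption_", k),
                     n = sum(kinds == k, na.rm = TRUE))
    }),
    purrr::map(expected_fmts, function(f) {
      tibble::tibble(category = paste0("cessation_", f),
                     n = sum(fmts == f, na.rm = TRUE))
    }),
    list(tibble::tibble(
      category = "distractor",
      n = sum(grepl("drawn|Labs:|Last visit|scheduled|panel|A1c", corpus$text))
    ))
  )
  out <- dplyr::bind_rows(rows)
  out$covered <- out$n > 0
  out
}
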