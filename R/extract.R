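# Rule-based extraction of pack-year history and cessation dates.
#
# Pack-year tiers are evaluated in a fixed order: complete pack years,
# then packs per day, then cigarettes per day, then years smoked. A
# complete pack-year match short-circuits everything below it. When an
# intensity (packs/day or cigarettes/day) co-occurs with years smoked,
# the pack-year total is computed (cigarettes convert at 20 per pack);
# otherwise whatever was found is kept as partial information.

cigarettes_per_pack <- 20

# all matches of one tier against text; first match in document order wins
match_tier <- function(text, tier_rules, word_numbers) {
  rows <- purrr::map(tier_rules, function(rule) {
    m <- gregexpr(rule$pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    cap_start <- attr(m, "capture.start")
    cap_len <- attr(m, "capture.length")
    value <- if (!is.null(rule$fixed_value)) {
      rep(as.numeric(rule$fixed_value), length(start))
    } else {
      token <- substring(text, cap_start[, 1], cap_start[, 1] + cap_len[, 1] - 1L)
      purrr::map_dbl(token, parse_quantity, word_numbers = word_numbers)
    }
    tibble::tibble(
      start = start, end = start + as.integer(len),
      text = substring(text, start + 1L, start + len),
      value = value
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) return(out)
  out <- out[!is.na(out$value), ]
  dplyr::arrange(out, .data$start, .data$end)
}

empty_pack_year_finding <- function() {
  tibble::tibble(
    kind = character(), pack_years = double(), packs_per_day = double(),
    cigarettes_per_day = double(), years_smoked = double(),
    start = integer(), end = integer(), text = character(),
    matches = list()
  )
}

#' Extract pack-year history from note text
#'
#' Evaluates the rule tiers in order (pack years, then packs per day,
#' then cigarettes per day, then years smoked). A direct pack-year match
#' returns a `COMPLETE` finding and stops — no lower tier is evaluated.
#' Otherwise partial quantities are gathered; if an intensity (packs/day
#' or cigarettes/day) and a duration (years smoked) are both present the
#' total is computed (`pack_years = packs_per_day * years_smoked`, with
#' cigarettes/day converted at 20 cigarettes per pack, rounded to one
#' decimal) and the finding is `COMPUTED`; otherwise it is `PARTIAL`.
#' When several matches exist for one tier the first in document order is
#' used; all matches are retained in the `matches` list-column.
#'
#' @param text Note text.
#' @param rules A [load_rules()] rule set.
#' @return A one-row tibble (`kind`, `pack_years`, `packs_per_day`,
#'   `cigarettes_per_day`, `years_smoked`, `start`, `end`, `text`,
#'   `matches`), or a zero-row tibble when nothing matched. Offsets are
#'   0-based half-open; `start`/`end` is the span hull of the
#'   contributing matches.
#' @export
#' @examples
#' rules <- default_rules()
#' extract_pack_years("30 pack year history; currently 1 ppd", rules)
#' extract_pack_years("2 packs per day for 20 years", rules)
extract_pack_years <- function(text, rules = default_rules()) {
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    return(empty_pack_year_finding())
  }
  wn <- rules$word_numbers
  py <- match_tier(text, rules$tiers$pack_years, wn)
  if (nrow(py) > 0) {
    first <- py[1, ]
    return(tibble::tibble(
      kind = "complete", pack_years = first$value,
      packs_per_day = NA_real_, cigarettes_per_day = NA_real_,
      years_smoked = NA_real_,
      start = first$start, end = first$end, text = first$text,
      matches = list(list(pack_years = py))
    ))
  }
  ppd <- match_tier(text, rules$tiers$packs_per_day, wn)
  cpd <- match_tier(text, rules$tiers$cigarettes_per_day, wn)
  # a packs/day match shadows any cigarettes/day candidate inside its span
  if (nrow(ppd) > 0 && nrow(cpd) > 0) {
    keep <- !purrr::map_lgl(seq_len(nrow(cpd)), function(i) {
      any(ppd$start <= cpd$start[i] & cpd$end[i] <= ppd$end)
    })
    cpd <- cpd[keep, ]
  }
  yrs <- match_tier(text, rules$tiers$years_smoked, wn)
  found <- list(
    packs_per_day = if (nrow(ppd) > 0) ppd$value[1] else NA_real_,
    cigarettes_per_day = if (nrow(cpd) > 0) cpd$value[1] else NA_real_,
    years_smoked = if (nrow(yrs) > 0) yrs$value[1] else NA_real_
  )
  if (all(is.na(unlist(found)))) return(empty_pack_year_finding())
  intensity <- if (!is.na(found$packs_per_day)) {
    found$packs_per_day
  } else if (!is.na(found$cigarettes_per_day)) {
    found$cigarettes_per_day / cigarettes_per_pack
  } else {
    NA_real_
  }
  computed <- !is.na(intensity) && !is.na(found$years_smoked)
  contrib <- dplyr::bind_rows(head(ppd, 1), head(cpd, 1), head(yrs, 1))
  tibble::tibble(
    kind = if (computed) "computed" else "partial",
    pack_years = if (computed) round(intensity * found$years_smoked, 1) else NA_real_,
    packs_per_day = found$packs_per_day,
    cigarettes_per_day = found$cigarettes_per_day,
    years_smoked = found$years_smoked,
    start = min(contrib$start), end = max(contrib$end),
    text = substring(text, min(contrib$start) + 1L, max(contrib$end)),
    matches = list(list(packs_per_day = ppd, cigarettes_per_day = cpd,
                        years_smoked = yrs))
  )
}

month_from_name <- function(name) {
  name <- tolower(sub("\\.$", "", trimws(name)))
  full <- match(name, tolower(month.name))
  if (!is.na(full)) return(full)
  match(substr(name, 1, 3), tolower(month.abb))
}

pivot_two_digit_year <- function(yy) {
  yy <- as.integer(yy)
  ifelse(yy <= 29L, 2000L + yy, 1900L + yy)
}

make_date <- function(year, month, day) {
  d <- as.Date(sprintf("%04d-%02d-%02d", year, month, day),
               format = "%Y-%m-%d")
  d
}

#' Normalize a date expression
#'
#' Parses a self-contained date expression into a calendar date with a
#' precision. Accepted formats: `MM/DD/YYYY`, `M/D/YY` (two-digit years
#' pivot at 29: 00-29 resolve to the 2000s, 30-99 to the 1900s),
#' `MM/YYYY`, `"Month DD, YYYY"`, `"Month YYYY"` (full or abbreviated
#' month names), bare `YYYY`, and `'YY`/`YY` two-digit years. Year and
#' month precision use placeholder day/month components (January, day 1),
#' flagged by the `precision` field. Decades ("the late 1980s"), seasons
#' and ranges are rejected.
#'
#' @param expression Character scalar.
#' @return A list `(date, precision)` with `precision` one of `"day"`,
#'   `"month"`, `"year"`, or `NULL` when the expression cannot be parsed
#'   (failure is a value, not an error).
#' @export
#' @examples
#' normalize_date("July 4, 1999")
#' normalize_date("3/15/10")
#' normalize_date("the late 1980s")  # NULL
normalize_date <- function(expression) {
  s <- trimws(expression)
  if (!nzchar(s)) return(NULL)
  ok <- function(date, precision) {
    if (is.na(date)) NULL else list(date = date, precision = precision)
  }
  # MM/DD/YYYY or M/D/YY
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{1,2})/(\\d{4}|\\d{2})$", s))[[1]]
  if (length(m) > 0) {
    year <- if (nchar(m[4]) == 2) pivot_two_digit_year(m[4]) else as.integer(m[4])
    return(ok(make_date(year, as.integer(m[2]), as.integer(m[3])), "day"))
  }
  # MM/YYYY
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{4})$", s))[[1]]
  if (length(m) > 0) {
    return(ok(make_date(as.integer(m[3]), as.integer(m[2]), 1L), "month"))
  }
  # Month DD, YYYY
  m <- regmatches(s, regexec(
    "^([A-Za-z]+)\\.?\\s+(\\d{1,2})(?:st|nd|rd|th)?,?\\s+(\\d{4})$", s,
    perl = TRUE))[[1]]
  if (length(m) > 0 && !is.na(month_from_name(m[2]))) {
    return(ok(make_date(as.integer(m[4]), month_from_name(m[2]),
                        as.integer(m[3])), "day"))
  }
  # Month YYYY
  m <- regmatches(s, regexec("^([A-Za-z]+)\\.?,?\\s+(\\d{4})$", s))[[1]]
  if (length(m) > 0 && !is.na(month_from_name(m[2]))) {
    return(ok(make_date(as.integer(m[3]), month_from_name(m[2]), 1L), "month"))
  }
  # bare YYYY (not a decade: no trailing "s")
  if (grepl("^(19|20)\\d{2}$", s)) {
    return(ok(make_date(as.integer(s), 1L, 1L), "year"))
  }
  # 'YY or bare two-digit year
  m <- regmatches(s, regexec("^'?(\\d{2})$", s))[[1]]
  if (length(m) > 0) {
    return(ok(make_date(pivot_two_digit_year(m[2]), 1L, 1L), "year"))
  }
  NULL
}

#' Render a normalized date back to text
#'
#' Inverse companion of [normalize_date()]: renders a (date, precision)
#' pair in a canonical format that re-parses to the same value.
#'
#' @param date A `Date`.
#' @param precision `"day"`, `"month"` or `"year"`.
#' @return Character scalar.
#' @export
render_date <- function(date, precision = c("day", "month", "year")) {
  precision <- match.arg(precision)
  switch(precision,
    day = format(date, "%m/%d/%Y"),
    month = format(date, "%B %Y"),
    year = format(date, "%Y")
  )
}

# Ordered date-expression scanners (most specific first). Each returns
# matches as (start, end) spans whose text normalize_date() can parse.
date_scanners <- function() {
  c(
    "\\b\\d{1,2}/\\d{1,2}/(?:\\d{4}|\\d{2})(?![\\d/])",
    "\\b\\d{1,2}/\\d{4}\\b",
    "\\b[A-Za-z]+\\.?\\s+\\d{1,2}(?:st|nd|rd|th)?,?\\s+(?:19|20)\\d{2}\\b",
    "\\b[A-Za-z]+\\.?,?\\s+(?:19|20)\\d{2}\\b",
    "\\b(?:19|20)\\d{2}\\b(?!s)",
    "(?<=\\b(?:in|since)\\s)'?\\d{2}(?![\\ds])"
  )
}

scan_dates <- function(text) {
  rows <- purrr::imap(date_scanners(), function(pat, rank) {
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    tibble::tibble(start = start, end = start + as.integer(len),
                   rank = rank)
  })
  cand <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(cand) == 0) return(cand)
  # leftmost first, most specific scanner first among same start; the
  # caller skips candidates normalize_date() cannot parse, so a nested
  # bare year still gets its turn when its covering match fails to parse
  dplyr::arrange(cand, .data$start, .data$rank)
}

empty_cessation_finding <- function() {
  tibble::tibble(
    date = as.Date(character()), precision = character(),
    start = integer(), end = integer(), text = character()
  )
}

#' Extract a smoking-cessation date from note text
#'
#' A cessation cue (quit/stopped/cessation vocabulary from the rule set)
#' must co-occur with a parseable date expression in the same sentence;
#' the date is normalized by [normalize_date()]. Dates with no cessation
#' cue in their sentence are never returned (this is what keeps blood
#' panels and service dates out), negated cues ("denies quitting") do not
#' anchor, and vague decade or range expressions ("quit in the late
#' 1980s") yield no finding.
#'
#' @param text Note text.
#' @param rules A [load_rules()] rule set.
#' @return One-row tibble (`date`, `precision`, `start`, `end`, `text`,
#'   with the date-expression span and the anchoring sentence text), or a
#'   zero-row tibble when no anchored date was found.
#' @export
#' @examples
#' rules <- default_rules()
#' extract_cessation_date("Patient quit smoking 03/15/2010.", rules)
#' extract_cessation_date("Patient quit in the late 1980s.", rules)
extract_cessation_date <- function(text, rules = default_rules()) {
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    return(empty_cessation_finding())
  }
  sents <- segment_sentences(text)
  for (i in seq_len(nrow(sents))) {
    sent <- sents$text[i]
    cue <- find_cue(sent, rules)
    if (is.null(cue)) next
    cand <- scan_dates(sent)
    for (j in seq_len(nrow(cand))) {
      expr <- substring(sent, cand$start[j] + 1L, cand$end[j])
      norm <- normalize_date(expr)
      if (is.null(norm)) next
      return(tibble::tibble(
        date = norm$date, precision = norm$precision,
        start = sents$start[i] + cand$start[j],
        end = sents$start[i] + cand$end[j],
        text = sent
      ))
    }
  }
  empty_cessation_finding()
}

# first non-negated cessation cue in a sentence, or NULL
find_cue <- function(sentence, rules) {
  for (pat in rules$cessation_cues) {
    m <- gregexpr(pat, sentence, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      start <- as.integer(m[k]) - 1L
      before <- substring(sentence, max(1L, start - 24L), start)
      if (grepl(rules$cue_negators, before, perl = TRUE, ignore.case = TRUE)) next
      return(list(start = start,
                  end = start + attr(m, "match.length")[k]))
    }
  }
  NULL
}

#' Extract all smoking behaviors from one note
#'
#' Convenience wrapper running [extract_pack_years()] and
#' [extract_cessation_date()] on one note text. The pipeline calls this
#' only for notes classified into a smoker category.
#'
#' @param text Note text.
#' @param rules A [load_rules()] rule set.
#' @return One-row tibble with pack-year and cessation columns (`NA`
#'   where nothing was found).
#' @export
extract_behaviors <- function(text, rules = default_rules()) {
  py <- extract_pack_years(text, rules)
  cd <- extract_cessation_date(text, rules)
  behavior_row(py, cd)
}

# the all-NA finding row; used by the pipeline for notes the gate skips,
# without entering any extraction code
no_behaviors <- function() {
  behavior_row(empty_pack_year_finding(), empty_cessation_finding())
}

behavior_row <- function(py, cd) {
  tibble::tibble(
    pack_year_kind = if (nrow(py) > 0) py$kind else NA_character_,
    pack_years = if (nrow(py) > 0) py$pack_years else NA_real_,
    packs_per_day = if (nrow(py) > 0) py$packs_per_day else NA_real_,
    cigarettes_per_day = if (nrow(py) > 0) py$cigarettes_per_day else NA_real_,
    years_smoked = if (nrow(py) > 0) py$years_smoked else NA_real_,
    pack_year_start = if (nrow(py) > 0) py$start else NA_integer_,
    pack_year_end = if (nrow(py) > 0) py$end else NA_integer_,
    pack_year_text = if (nrow(py) > 0) py$text else NA_character_,
    cessation_date = if (nrow(cd) > 0) cd$date else as.Date(NA),
    cessation_precision = if (nrow(cd) > 0) cd$precision else NA_character_,
    cessation_start = if (nrow(cd) > 0) cd$start else NA_integer_,
    cessation_end = if (nrow(cd) > 0) cd$end else NA_integer_,
    cessation_text = if (nrow(cd) > 0) cd$text else NA_character_
  )
}
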