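# Hotspot location and context-window extraction.
#
# A "hotspot" is a word stem (e.g. "smok") whose occurrence marks text
# likely to describe smoking behavior. Only text near hotspots is fed to
# the status classifier; a note with no hotspot at all is labeled
# "unknown" by rule, without classification.
#
# All character offsets are 0-based, half-open [start, end).

#' Hotspot configuration
#'
#' @param stems Lowercase word stems matched as substrings anywhere in the
#'   text (so `"smok"` hits "smokes", "smoking" and "nonsmoker"). The
#'   default four-stem set is the reduced set that performs as well as the
#'   legacy six-stem set.
#' @param mode `"words"`: the window is up to `window_size` word tokens on
#'   each side of the token containing the match, truncated at sentence
#'   boundaries. `"chars"`: up to `window_size` characters each side, with
#'   no sentence constraint.
#' @param window_size Positive integer; defaults to 5 in words mode and
#'   100 in chars mode.
#' @return A list of class `hotspot_config`.
#' @export
#' @examples
#' hotspot_config()
#' hotspot_config_legacy()
hotspot_config <- function(stems = c("smok", "cig", "tobac", "nicoti"),
                           mode = c("words", "chars"),
                           window_size = NULL) {
  mode <- match.arg(mode)
  if (length(stems) == 0) abort("At least one hotspot stem is required")
  if (any(stems != tolower(stems))) abort("Hotspot stems must be lowercase")
  if (is.null(window_size)) {
    window_size <- if (mode == "words") 5L else 100L
  }
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) abort("window_size must be >= 1")
  structure(
    list(stems = stems, mode = mode, window_size = window_size),
    class = "hotspot_config"
  )
}

#' @rdname hotspot_config
#' @details `hotspot_config_legacy()` returns the original six-stem,
#'   plus/minus-100-character configuration that the four-stem word-window
#'   default supersedes.
#' @export
hotspot_config_legacy <- function() {
  hotspot_config(
    stems = c("smok", "cig", "tobac", "packs", "tob", "nicotine"),
    mode = "chars", window_size = 100L
  )
}

# Window-boundary marker inserted between appended windows. It contains no
# alphanumeric characters, so the tokenizer drops it: it can never enter
# the feature vocabulary or fuse adjacent window tokens.
window_boundary <- function() " | "

#' Tokenize text
#'
#' Lowercases and splits on maximal runs of non-alphanumeric characters;
#' digits are retained as tokens (so "1", "ppd" and "1995" survive as
#' features).
#'
#' @param text A character scalar.
#' @return Tibble with columns `token`, `start`, `end` (0-based half-open
#'   offsets into `text`).
#' @export
#' @examples
#' tokenize_text("Smokes 1 ppd since 1995.")$token
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble::tibble(
    token = tolower(substring(text, start + 1L, start + len)),
    start = start,
    end = start + as.integer(len)
  )
}

#' Segment text into sentences
#'
#' Deterministic segmentation on terminal punctuation (`.`, `!`, `?`) and
#' newlines; section-header lines (which end in a newline) therefore form
#' their own sentences. Every non-delimiter, non-whitespace character is
#' attributed to exactly one sentence.
#'
#' @param text A character scalar.
#' @return Tibble with columns `text`, `start`, `end` (0-based half-open
#'   offsets); zero rows for empty input.
#' @export
#' @examples
#' segment_sentences("SOCIAL HISTORY:\nQuit 1995. Feels well.")
segment_sentences <- function(text) {
  empty <- tibble::tibble(text = character(), start = integer(), end = integer())
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  m <- gregexpr("[.!?\n]+", text)[[1]]
  if (m[1] == -1) {
    cuts <- integer(0)
    lens <- integer(0)
  } else {
    cuts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
  }
  seg_start <- c(0L, cuts + lens)
  seg_end <- c(cuts, n)
  rows <- purrr::map2(seg_start, seg_end, function(s, e) {
    if (e <= s) return(NULL)
    raw <- substring(text, s + 1L, e)
    # trim whitespace, keeping offsets aligned with the source
    lead <- nchar(sub("^(\\s*).*$", "\\1", raw))
    trail <- nchar(sub("^.*?(\\s*)$", "\\1", raw))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 <= s2) return(NULL)
    tibble::tibble(
      text = substring(text, s2 + 1L, e2),
      start = as.integer(s2), end = as.integer(e2)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Locate hotspot stems in a note
#'
#' Case-insensitive substring match of every configured stem against the
#' note text; one row per occurrence, ordered by position.
#'
#' @param text Note text (character scalar).
#' @param config A [hotspot_config()].
#' @return Tibble with columns `stem`, `start`, `end` (0-based half-open).
#' @export
#' @examples
#' find_hotspots("Patient smokes. No cigarette use.", hotspot_config())
find_hotspots <- function(text, config = hotspot_config()) {
  lower <- tolower(text)
  rows <- purrr::map(config$stems, function(stem) {
    m <- gregexpr(stem, lower, fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    start <- as.integer(m) - 1L
    tibble::tibble(stem = stem, start = start, end = start + nchar(stem))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(stem = character(), start = integer(), end = integer()))
  }
  dplyr::arrange(out, .data$start, .data$end, .data$stem)
}

#' Extract the context window around one hotspot match
#'
#' In words mode the window spans up to `window_size` word tokens on each
#' side of the token containing the match (the matched token itself is the
#' center and does not count toward the size), truncated at sentence
#' boundaries. In chars mode it spans up to `window_size` characters each
#' side, clamped to the text.
#'
#' @param text Note text.
#' @param start,end Match span (0-based half-open), e.g. one row of
#'   [find_hotspots()].
#' @param config A [hotspot_config()].
#' @return Tibble row: `window_text`, `window_start`, `window_end`,
#'   `sentence_index` (`NA` in chars mode).
#' @export
extract_window <- function(text, start, end, config = hotspot_config()) {
  n <- nchar(text)
  if (start < 0 || end > n || end <= start) {
    abort(sprintf("Match span [%d, %d) outside text of length %d", start, end, n))
  }
  if (config$mode == "chars") {
    ws <- max(0L, start - config$window_size)
    we <- min(n, end + config$window_size)
    return(tibble::tibble(
      window_text = substring(text, ws + 1L, we),
      window_start = as.integer(ws), window_end = as.integer(we),
      sentence_index = NA_integer_
    ))
  }
  sents <- segment_sentences(text)
  si <- which(sents$start <= start & start < sents$end)
  if (length(si) == 0) {
    # match inside stripped whitespace/delimiters; fall back to char clamp
    return(tibble::tibble(
      window_text = substring(text, start + 1L, end),
      window_start = as.integer(start), window_end = as.integer(end),
      sentence_index = NA_integer_
    ))
  }
  si <- si[1]
  sent <- sents[si, ]
  toks <- tokenize_text(sent$text)
  toks$start <- toks$start + sent$start
  toks$end <- toks$end + sent$start
  center <- which(toks$start <= start & start < toks$end)
  if (length(center) == 0) center <- which.min(abs(toks$start - start))
  center <- center[1]
  k <- config$window_size
  lo <- max(1L, center - k)
  hi <- min(nrow(toks), center + k)
  ws <- toks$start[lo]
  we <- toks$end[hi]
  tibble::tibble(
    window_text = substring(text, ws + 1L, we),
    window_start = as.integer(ws), window_end = as.integer(we),
    sentence_index = as.integer(si)
  )
}

#' All hotspot windows of a note
#'
#' @param text Note text.
#' @param config A [hotspot_config()].
#' @return Tibble with one row per hotspot occurrence, in document order:
#'   `stem`, `start`, `end` (match span), `window_text`, `window_start`,
#'   `window_end`, `sentence_index`.
#' @export
hotspot_windows <- function(text, config = hotspot_config()) {
  matches <- find_hotspots(text, config)
  if (nrow(matches) == 0) {
    return(tibble::tibble(
      stem = character(), start = integer(), end = integer(),
      window_text = character(), window_start = integer(),
      window_end = integer(), sentence_index = integer()
    ))
  }
  wins <- purrr::map(seq_len(nrow(matches)), function(i) {
    extract_window(text, matches$start[i], matches$end[i], config)
  })
  dplyr::bind_cols(matches, dplyr::bind_rows(wins))
}

#' Appended hotspot-window text of a note
#'
#' All hotspot windows of the note, concatenated in document order and
#' separated by a reserved boundary marker, yielding the single string the
#' classifier sees. Overlapping windows are emitted independently
#' (duplicated text is allowed, not merged).
#'
#' @param text Note text.
#' @param config A [hotspot_config()].
#' @return A character scalar, or `NA_character_` when no hotspot matched
#'   (such notes are labeled `"unknown"` by rule downstream).
#' @export
#' @examples
#' note_window_text("He quit smoking ten years ago after his MI.")
#' note_window_text("BP 120/80. Lungs clear.")  # NA: no hotspot
note_window_text <- function(text, config = hotspot_config()) {
  wins <- hotspot_windows(text, config)
  if (nrow(wins) == 0) return(NA_character_)
  paste(wins$window_text, collapse = window_boundary())
}
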