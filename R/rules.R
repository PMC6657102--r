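# Rule-set loading. Extraction patterns are data, not code: a versioned
# JSON file ships with the package and can be replaced without touching
# the extractor. In each pattern the placeholder NUM is expanded to an
# alternation of decimal numbers and the supported word-number forms.

num_token_regex <- function(word_numbers) {
  paste0("\\d+(?:\\.\\d+)?|", paste(names(word_numbers), collapse = "|"))
}

compile_tier <- function(tier, num_regex) {
  purrr::map(tier, function(rule) {
    list(
      pattern = gsub("NUM", num_regex, rule$pattern, fixed = TRUE),
      fixed_value = rule$fixed_value %||% NULL
    )
  })
}

#' Load an extraction rule set
#'
#' Reads a versioned JSON rule file describing the four pack-year tiers
#' (pack years, packs per day, cigarettes per day, years smoked), the
#' cessation cue vocabulary, cue negators, and the word-number map, and
#' compiles the patterns for matching.
#'
#' @param path Path to a rule JSON file; the packaged version-1 rules by
#'   default.
#' @return Object of class `smoke_rules`.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules_v1.json", package = "smokereg")
  }
  if (!file.exists(path)) abort(sprintf("No such rule file: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  wn <- unlist(raw$word_numbers)
  num_regex <- num_token_regex(wn)
  tiers <- c("pack_years", "packs_per_day", "cigarettes_per_day", "years_smoked")
  compiled <- purrr::map(setNames(tiers, tiers), function(t) {
    compile_tier(raw[[t]], num_regex)
  })
  structure(
    list(
      version = raw$version,
      word_numbers = wn,
      tiers = compiled,
      cessation_cues = unlist(raw$cessation_cues),
      cue_negators = raw$cue_negators,
      path = path
    ),
    class = "smoke_rules"
  )
}

#' Default packaged rule set
#'
#' @return The compiled version-1 `smoke_rules` shipped with the package.
#' @export
default_rules <- function() {
  rules <- getOption("smokereg.rules.cache")
  if (is.null(rules)) {
    rules <- load_rules()
    options(smokereg.rules.cache = rules)
  }
  rules
}

#' @export
print.smoke_rules <- function(x, ...) {
  cat(sprintf("<smoke_rules> version %s\n", x$version))
  for (t in names(x$tiers)) {
    cat(sprintf("  %s: %d pattern(s)\n", t, length(x$tiers[[t]])))
  }
  cat(sprintf("  cessation cues: %d pattern(s)\n", length(x$cessation_cues)))
  invisible(x)
}

# numeric value of a captured quantity token ("2", "1.5", "half", "ten")
parse_quantity <- function(token, word_numbers) {
  token <- tolower(trimws(token))
  if (grepl("^\\d+(\\.\\d+)?$", token)) return(as.numeric(token))
  val <- word_numbers[[token]]
  if (is.null(val)) NA_real_ else as.numeric(val)
}
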