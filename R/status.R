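#' Smoking-status classes
#'
#' The five note-level smoking-status classes, in their canonical order.
#' `"smoker"` means a smoking history is documented but the note does not
#' establish whether the patient currently smokes (smoker temporality
#' unknown); `"unknown"` means the note carries no smoking-status
#' information at all. The order is also the deterministic tie-break order
#' used by [predict.status_model()].
#'
#' @return Character vector of the five class labels.
#' @export
#' @examples
#' smoking_statuses()
smoking_statuses <- function() {
  c("never", "former", "current", "smoker", "unknown")
}

# Smoker categories eligible for the registry (extraction gate).
smoker_statuses <- function() c("former", "current", "smoker")

#' Parse smoking-status labels
#'
#' Case-insensitive parsing of the five class strings into a factor over
#' [smoking_statuses()]. Any other string is an error: status parsing is
#' total over exactly five values.
#'
#' @param x Character vector of status labels.
#' @return Factor with levels `smoking_statuses()`.
#' @export
#' @examples
#' parse_status(c("NEVER", "Former", "current"))
parse_status <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  bad <- !is.na(lx) & !(lx %in% smoking_statuses())
  if (any(bad)) {
    abort(sprintf(
      "Unrecognized smoking status label(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  factor(lx, levels = smoking_statuses())
}
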