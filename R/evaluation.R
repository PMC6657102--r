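# Evaluation suite: per-class precision/recall/F1, micro-F1,
# sensitivity/specificity, ever-smoker merging, and two-by-two evaluation
# of the extraction algorithms.
#
# Rates with zero denominators are reported as NA (absent), never as 0:
# an undefined rate is distinct from a measured 0.

#' Harmonic-mean F1 score
#'
#' `2 * (recall * precision) / (recall + precision)`, penalizing both
#' false positives and false negatives. By convention `f1(0, 0) = 0`.
#'
#' @param precision,recall Numeric vectors in `[0, 1]` (recycled).
#' @return Numeric vector of F1 scores.
#' @export
#' @examples
#' f1(0.83, 0.98)  # 0.90 to 2 d.p.
f1 <- function(precision, recall) {
  ok <- is.na(precision) | is.na(recall) |
    (precision >= 0 & precision <= 1 & recall >= 0 & recall <= 1)
  if (!all(ok)) abort("precision and recall must lie in [0, 1]")
  out <- 2 * (recall * precision) / (recall + precision)
  out[!is.na(precision) & !is.na(recall) & precision == 0 & recall == 0] <- 0
  out
}

#' Confusion matrix over the five status classes
#'
#' @param gold,predicted Vectors of status labels (anything
#'   [parse_status()] accepts); equal length.
#' @param classes Ordered class set (default [smoking_statuses()]).
#' @return Object of class `smoke_confusion`: an integer matrix with gold
#'   classes as rows and predicted classes as columns.
#' @export
confusion_matrix <- function(gold, predicted, classes = smoking_statuses()) {
  if (length(gold) != length(predicted)) {
    abort("gold and predicted must have equal length")
  }
  g <- factor(as.character(parse_status(gold)), levels = classes)
  p <- factor(as.character(parse_status(predicted)), levels = classes)
  m <- table(gold = g, predicted = p)
  structure(unclass(m), class = "smoke_confusion")
}

cm_matrix <- function(cm) {
  m <- unclass(cm)
  storage.mode(m) <- "double"
  m
}

#' Micro-averaged F1 score
#'
#' Pooled-count F1 over all classes: with pooled true positives `TP`
#' (the diagonal), pooled false positives and false negatives (both the
#' off-diagonal total), micro-F1 is `2 TP / (2 TP + FP + FN)`. In
#' single-label multiclass classification this is identically the overall
#' accuracy `trace / total`.
#'
#' @param cm A `smoke_confusion` (or plain gold-by-predicted count matrix).
#' @return Micro-F1 in `[0, 1]`.
#' @export
micro_f1 <- function(cm) {
  m <- cm_matrix(cm)
  total <- sum(m)
  if (total == 0) abort("Empty confusion matrix")
  tp <- sum(diag(m))
  fp <- sum(m) - tp
  fn <- sum(m) - tp
  2 * tp / (2 * tp + fp + fn)
}

#' Per-class evaluation report
#'
#' One-vs-rest precision, recall, F1, sensitivity and specificity for each
#' class, plus micro-F1 and the merged ever-smoker two-by-two. Sensitivity
#' is definitionally identical to recall; specificity is the true-negative
#' rate of the one-vs-rest split. Zero-denominator rates are `NA`.
#'
#' @param cm A `smoke_confusion`.
#' @return Object of class `smoke_eval`: list with `per_class` (tibble),
#'   `micro_f1`, `merged_ever`, `confusion`, `n`.
#' @export
per_class_report <- function(cm) {
  m <- cm_matrix(cm)
  classes <- rownames(m)
  total <- sum(m)
  rows <- purrr::map(classes, function(cls) {
    tp <- m[cls, cls]
    fn <- sum(m[cls, ]) - tp
    fp <- sum(m[, cls]) - tp
    tn <- total - tp - fn - fp
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(
      class = cls, n = tp + fn,
      precision = precision, recall = recall,
      f1 = if (is.na(precision) || is.na(recall)) NA_real_ else f1(precision, recall),
      sensitivity = recall, specificity = specificity
    )
  })
  merged <- if (setequal(classes, smoking_statuses())) merge_ever(cm) else NULL
  structure(
    list(
      per_class = dplyr::bind_rows(rows),
      micro_f1 = micro_f1(cm),
      merged_ever = merged,
      confusion = cm,
      n = total
    ),
    class = "smoke_eval"
  )
}

#' Merge the three smoker categories into one "ever smoker" class
#'
#' Pools former/current/smoker-temporality-unknown into a single positive
#' class against never/unknown, so confusions among the three smoker
#' categories become correct. Returns the resulting two-by-two with its
#' sensitivity and specificity.
#'
#' @param cm A `smoke_confusion` over the five classes.
#' @return Object of class `smoke_two_by_two` (fields `tp`, `fn`, `fp`,
#'   `tn`, `sensitivity`, `specificity`).
#' @export
merge_ever <- function(cm) {
  m <- cm_matrix(cm)
  pos <- intersect(smoker_statuses(), rownames(m))
  neg <- setdiff(rownames(m), pos)
  two_by_two(
    tp = sum(m[pos, pos]), fn = sum(m[pos, neg]),
    fp = sum(m[neg, pos]), tn = sum(m[neg, neg])
  )
}

two_by_two <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) abort("two-by-two counts must be non-negative")
  structure(
    list(
      tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ),
    class = "smoke_two_by_two"
  )
}

#' Two-by-two evaluation of a binary finding against annotation
#'
#' Standard two-by-two crosstabulation of gold presence/absence flags
#' versus algorithm found/not-found flags, with sensitivity
#' `tp / (tp + fn)` and specificity `tn / (tn + fp)`. Used to score the
#' pack-year and cessation-date extraction against manual annotation.
#'
#' @param gold_flags,found_flags Logical vectors of equal length.
#' @return Object of class `smoke_two_by_two`.
#' @export
#' @examples
#' two_by_two_eval(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
two_by_two_eval <- function(gold_flags, found_flags) {
  if (length(gold_flags) != length(found_flags)) {
    abort("gold_flags and found_flags must have equal length")
  }
  gold_flags <- as.logical(gold_flags)
  found_flags <- as.logical(found_flags)
  two_by_two(
    tp = sum(gold_flags & found_flags),
    fn = sum(gold_flags & !found_flags),
    fp = sum(!gold_flags & found_flags),
    tn = sum(!gold_flags & !found_flags)
  )
}

#' Evaluate status predictions against gold labels
#'
#' @param gold,predicted Status label vectors of equal length.
#' @return A `smoke_eval` report (see [per_class_report()]).
#' @export
evaluate_predictions <- function(gold, predicted) {
  per_class_report(confusion_matrix(gold, predicted))
}

#' @export
print.smoke_two_by_two <- function(x, ...) {
  cat("<two-by-two>\n")
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity: %s  specificity: %s\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity)))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)

#' @export
print.smoke_eval <- function(x, ...) {
  cat(sprintf("<smoke_eval> n = %d, micro-F1 = %.2f\n", x$n, x$micro_f1))
  tab <- x$per_class
  tab$precision <- round(tab$precision, 2)
  tab$recall <- round(tab$recall, 2)
  tab$f1 <- round(tab$f1, 2)
  tab$sensitivity <- purrr::map_chr(tab$sensitivity, fmt_pct)
  tab$specificity <- purrr::map_chr(tab$specificity, fmt_pct)
  print(as.data.frame(tab), row.names = FALSE)
  if (!is.null(x$merged_ever)) {
    cat(sprintf("ever smoker (merged): sensitivity %s, specificity %s\n",
                fmt_pct(x$merged_ever$sensitivity),
                fmt_pct(x$merged_ever$specificity)))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `smoke_eval`.
#' @param ... Unused.
#' @return The per-class tibble (class, n, precision, recall, f1,
#'   sensitivity, specificity).
#' @method tidy smoke_eval
#' @export
tidy.smoke_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x A `smoke_eval`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `micro_f1`, and merged ever-smoker
#'   sensitivity/specificity (NA when the class set is not the canonical
#'   five).
#' @method glance smoke_eval
#' @export
glance.smoke_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    micro_f1 = x$micro_f1,
    ever_sensitivity = if (is.null(x$merged_ever)) NA_real_ else x$merged_ever$sensitivity,
    ever_specificity = if (is.null(x$merged_ever)) NA_real_ else x$merged_ever$specificity
  )
}

#' Plot per-class metrics of an evaluation report
#'
#' @param object A `smoke_eval`.
#' @param ... Unused.
#' @return A ggplot: precision/recall/F1 bars per status class.
#' @method autoplot smoke_eval
#' @export
autoplot.smoke_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_class[, c("class", "precision", "recall", "f1")],
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  df$class <- factor(df$class, levels = smoking_statuses())
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "smoking status", y = "score",
                  title = sprintf("Per-class performance (micro-F1 = %.2f)",
                                  object$micro_f1)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `smoke_confusion`.
#' @param ... Unused.
#' @return A ggplot heat map of counts (gold rows, predicted columns).
#' @method autoplot smoke_confusion
#' @export
autoplot.smoke_confusion <- function(object, ...) {
  m <- cm_matrix(object)
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "count"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$gold,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix (gold x predicted)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
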