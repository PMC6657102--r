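# Five-class smoking-status classifier: unigram counts over appended
# hotspot windows, a linear-kernel SVM with inverse-class-frequency
# ("balanced") weighting, and the zero-hotspot -> "unknown" rule.

negation_tokens <- function() c("neither", "never", "no", "nor", "not")

#' Stop-word list used by the classifier
#'
#' The versioned English stop-word list shipped with the package, minus
#' the five negation tokens (`neither`, `never`, `no`, `nor`, `not`),
#' which are always retained as features so that negated assertions such
#' as "no tobacco use" keep their polarity.
#'
#' @return Character vector of stop-word tokens.
#' @export
smoke_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english_v1.txt", package = "smokereg")
  words <- readLines(path, encoding = "UTF-8")
  words <- words[!grepl("^\\s*(#|$)", words)]
  setdiff(words, negation_tokens())
}

#' Build a feature space from window texts
#'
#' The vocabulary is the sorted set of unigram tokens occurring in the
#' training window texts, after stop-word removal. The window-boundary
#' marker contains no alphanumeric characters and therefore can never
#' enter the vocabulary.
#'
#' @param window_texts Character vector of appended hotspot-window texts.
#' @param stopwords Stop-word tokens; defaults to [smoke_stopwords()].
#' @return A list of class `feature_space` with elements `vocabulary` and
#'   `stopwords`.
#' @export
feature_space <- function(window_texts, stopwords = smoke_stopwords()) {
  tokens <- unlist(purrr::map(window_texts[!is.na(window_texts)],
                              function(x) tokenize_text(x)$token))
  vocab <- sort(unique(setdiff(tokens, stopwords)), method = "radix")
  structure(list(vocabulary = vocab, stopwords = stopwords),
            class = "feature_space")
}

#' Vectorize window text into unigram counts
#'
#' @param window_texts Character vector (NA rows yield zero vectors).
#' @param space A [feature_space()].
#' @return Sparse count matrix (`dgCMatrix`), one row per input text,
#'   columns in vocabulary order. Out-of-vocabulary and stop-word tokens
#'   are ignored.
#' @export
vectorize <- function(window_texts, space) {
  v <- length(space$vocabulary)
  n <- length(window_texts)
  ijx <- purrr::imap(window_texts, function(txt, i) {
    if (is.na(txt)) return(NULL)
    toks <- tokenize_text(txt)$token
    toks <- toks[!(toks %in% space$stopwords)]
    idx <- match(toks, space$vocabulary)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NULL)
    counts <- table(idx)
    list(i = rep(i, length(counts)),
         j = as.integer(names(counts)),
         x = as.numeric(counts))
  })
  ijx <- purrr::compact(ijx)
  Matrix::sparseMatrix(
    i = unlist(purrr::map(ijx, "i")) %||% integer(0),
    j = unlist(purrr::map(ijx, "j")) %||% integer(0),
    x = unlist(purrr::map(ijx, "x")) %||% numeric(0),
    dims = c(n, v),
    dimnames = list(NULL, space$vocabulary)
  )
}

#' Classifier configuration
#'
#' @param hotspot A [hotspot_config()] controlling window extraction.
#' @param cost SVM regularization cost (conventional default 1).
#' @param seed Integer seed used wherever randomness enters (e.g.
#'   cross-validation fold assignment). SVM training itself is
#'   deterministic.
#' @return A list of class `status_config`.
#' @export
status_config <- function(hotspot = hotspot_config(), cost = 1, seed = 1L) {
  structure(list(hotspot = hotspot, cost = cost, seed = as.integer(seed)),
            class = "status_config")
}

#' Fit the smoking-status model
#'
#' Trains a linear-kernel multi-class SVM with inverse-class-frequency
#' ("balanced") class weights on the appended hotspot-window texts of the
#' labeled notes. Notes with no hotspot are excluded from training: the
#' zero-hotspot rule labels them `"unknown"` at prediction time without
#' consulting the learner. `"unknown"` remains a learnable class for
#' hotspot-bearing notes (e.g. "smoke detector" mentions).
#'
#' @param corpus Corpus tibble with gold `status` labels (rows with `NA`
#'   status are ignored).
#' @param config A [status_config()].
#' @return Object of class `status_model`.
#' @export
fit_status_model <- function(corpus, config = status_config()) {
  if (nrow(corpus) == 0) abort("Cannot fit on an empty corpus")
  labeled <- corpus[!is.na(corpus$status), ]
  if (nrow(labeled) == 0) abort("Cannot fit: no labeled notes")
  windows <- purrr::map_chr(labeled$text, note_window_text,
                            config = config$hotspot)
  train <- !is.na(windows)
  y <- droplevels(labeled$status[train])
  if (nlevels(y) < 2) {
    abort(sprintf(
      "Need >= 2 classes among hotspot-bearing notes; got %d", nlevels(y)
    ))
  }
  space <- feature_space(windows[train])
  # dense model matrix: training sets are small (hundreds of notes by a
  # few hundred unigrams) and dense keeps the weight reconstruction simple
  x <- as.matrix(vectorize(windows[train], space))
  counts <- table(y)
  weights <- as.numeric(length(y) / (nlevels(y) * counts))
  names(weights) <- names(counts)
  set.seed(config$seed)
  svm_fit <- e1071::svm(
    x = x, y = y, kernel = "linear", cost = config$cost,
    class.weights = weights, scale = FALSE, fitted = FALSE
  )
  structure(
    list(
      svm = svm_fit,
      space = space,
      classes = levels(y),
      class_weights = weights,
      config = config,
      n_train = sum(train),
      stopword_hash = rlang::hash(space$stopwords)
    ),
    class = "status_model"
  )
}

# Per-class scores from libsvm's pairwise decision values: each pairwise
# value d for pair "A/B" contributes +d to A and -d to B. The predicted
# class is the argmax; ties break by the canonical class order
# never < former < current < smoker < unknown.
class_scores <- function(decision_row, classes) {
  scores <- setNames(numeric(length(classes)), classes)
  for (nm in names(decision_row)) {
    pair <- strsplit(nm, "/", fixed = TRUE)[[1]]
    scores[pair[1]] <- scores[pair[1]] + decision_row[[nm]]
    scores[pair[2]] <- scores[pair[2]] - decision_row[[nm]]
  }
  scores[order(match(names(scores), smoking_statuses()))]
}

#' Predict smoking status for notes
#'
#' Notes with no hotspot are labeled `"unknown"` by rule
#' (`via_hotspot_rule = TRUE`, no decision scores); all other notes get
#' the learner's argmax class over the per-class decision scores, with
#' ties broken by the canonical class order.
#'
#' @param object A fitted `status_model`.
#' @param corpus Corpus tibble (columns `note_id`, `text`).
#' @param ... Unused.
#' @return Tibble with columns `note_id`, `status`, `via_hotspot_rule`,
#'   and `decision_scores` (list-column of named per-class scores; `NULL`
#'   for rule-labeled notes).
#' @export
predict.status_model <- function(object, corpus, ...) {
  windows <- purrr::map_chr(corpus$text, note_window_text,
                            config = object$config$hotspot)
  has_window <- !is.na(windows)
  status <- rep("unknown", nrow(corpus))
  scores <- vector("list", nrow(corpus))
  if (any(has_window)) {
    x <- as.matrix(vectorize(windows[has_window], object$space))
    pred <- predict(object$svm, x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    rows <- which(has_window)
    for (r in seq_along(rows)) {
      s <- class_scores(setNames(as.list(dv[r, ]), colnames(dv)),
                        object$classes)
      best <- names(s)[s == max(s)]
      # canonical-order tie-break; names(s) already canonical order
      status[rows[r]] <- best[1]
      scores[[rows[r]]] <- s
    }
  }
  tibble::tibble(
    note_id = corpus$note_id,
    status = parse_status(status),
    via_hotspot_rule = !has_window,
    decision_scores = scores
  )
}

#' Stratified k-fold cross-validation of the status classifier
#'
#' Folds are stratified by gold status under the configured seed; classes
#' with fewer members than folds degrade gracefully (their notes are still
#' dealt round-robin, so some folds simply lack that class). Each fold's
#' held-out notes are scored with a model fitted on the remainder.
#'
#' @param corpus Labeled corpus tibble.
#' @param k Number of folds (default 5; must be >= 2).
#' @param config A [status_config()].
#' @return List with `folds` (per-fold `smoke_eval` reports), `pooled`
#'   (report over all out-of-fold predictions), `predictions` (pooled
#'   out-of-fold prediction tibble with a `fold` column).
#' @export
cross_validate <- function(corpus, k = 5L, config = status_config()) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort("k must be an integer >= 2")
  labeled <- corpus[!is.na(corpus$status), ]
  set.seed(config$seed)
  fold <- integer(nrow(labeled))
  for (cls in levels(labeled$status)) {
    idx <- which(labeled$status == cls)
    if (length(idx) == 0) next
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  preds <- purrr::map(seq_len(k), function(f) {
    fit <- fit_status_model(labeled[fold != f, ], config)
    p <- predict(fit, labeled[fold == f, ])
    p$fold <- f
    p
  })
  preds <- dplyr::bind_rows(preds)
  preds <- preds[match(labeled$note_id, preds$note_id), ]
  reports <- purrr::map(seq_len(k), function(f) {
    sel <- preds$fold == f
    evaluate_predictions(labeled$status[sel], preds$status[sel])
  })
  list(
    folds = reports,
    pooled = evaluate_predictions(labeled$status, preds$status),
    predictions = preds
  )
}

#' @export
print.status_model <- function(x, ...) {
  cat("<status_model>\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  training notes (hotspot-bearing): %d\n", x$n_train))
  cat(sprintf("  vocabulary size: %d\n", length(x$space$vocabulary)))
  cat(sprintf("  hotspots: %s; mode=%s; window=%d\n",
              paste(x$config$hotspot$stems, collapse = ","),
              x$config$hotspot$mode, x$config$hotspot$window_size))
  invisible(x)
}

#' Tidy a fitted status model into per-pair feature weights
#'
#' Reconstructs the primal weight vector of each one-vs-one class pair
#' from the SVM's support vectors and dual coefficients, giving a
#' human-readable view of which unigrams drive each pairwise decision.
#'
#' @param x A fitted `status_model`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `term`, `weight`, sorted within
#'   pair by decreasing absolute weight.
#' @method tidy status_model
#' @export
tidy.status_model <- function(x, ...) {
  svm_fit <- x$svm
  k <- length(svm_fit$levels)
  # libsvm groups support vectors and dual coefficients by its internal
  # label order (order of first appearance), not by factor-level order
  lev <- svm_fit$levels[svm_fit$labels]
  sv <- svm_fit$SV
  coefs <- svm_fit$coefs  # nSV x (k-1)
  nsv <- svm_fit$nSV
  starts <- cumsum(c(0, nsv))
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      ri <- (starts[i] + 1):(starts[i] + nsv[i])
      rj <- (starts[j] + 1):(starts[j] + nsv[j])
      w <- colSums(coefs[ri, j - 1, drop = TRUE] * sv[ri, , drop = FALSE]) +
        colSums(coefs[rj, i, drop = TRUE] * sv[rj, , drop = FALSE])
      nz <- which(w != 0)
      if (length(nz) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        pair = paste(lev[i], lev[j], sep = "/"),
        term = colnames(sv)[nz],
        weight = unname(w[nz])
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$pair, dplyr::desc(abs(.data$weight)))
}

#' One-row summary of a fitted status model
#'
#' @param x A fitted `status_model`.
#' @param ... Unused.
#' @return One-row tibble: training size, vocabulary size, classes,
#'   window configuration, cost.
#' @method glance status_model
#' @export
glance.status_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_features = length(x$space$vocabulary),
    n_classes = length(x$classes),
    n_support_vectors = nrow(x$svm$SV),
    hotspot_mode = x$config$hotspot$mode,
    window_size = x$config$hotspot$window_size,
    cost = x$config$cost
  )
}
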