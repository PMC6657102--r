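test_that("negation tokens are never stop words", {
  sw <- smoke_stopwords()
  expect_false(any(c("neither", "never", "no", "nor", "not") %in% sw))
  expect_true("the" %in% sw)
})

test_that("vectorization keeps negations, drops stopwords, is deterministic", {
  space <- feature_space(c("no tobacco use", "the of and smoking"))
  x <- vectorize("no tobacco use", space)
  expect_gt(x[1, "no"], 0)
  expect_gt(x[1, "tobacco"], 0)
  expect_false("the" %in% colnames(x))
  # all-stopword text -> zero vector
  expect_equal(sum(vectorize("the of and", space)), 0)
  expect_identical(vectorize("no tobacco use", space),
                   vectorize("no tobacco use", space))
  # window-boundary marker contributes no feature
  expect_false(any(grepl("\\|", space$vocabulary)))
})

test_that("fitting requires at least two learner classes", {
  # hotspot-bearing notes all one class, plus rule-covered unknowns
  corpus <- make_corpus(
    c("Smokes daily.", "Smokes often.", "BP 120/80.", "Lungs clear."),
    c("current", "current", "unknown", "unknown")
  )
  expect_error(fit_status_model(corpus), ">= 2 classes")
  expect_error(fit_status_model(corpus[0, ]), "empty")
})

test_that("a linearly separable toy corpus is fit to 100% training accuracy", {
  corpus <- toy_separable_corpus()
  model <- fit_status_model(corpus)
  pred <- predict(model, corpus)
  expect_equal(as.character(pred$status), as.character(corpus$status))
})

test_that("prediction flags the hotspot rule consistently and is total", {
  model <- fit_status_model(toy_separable_corpus())
  corpus <- make_corpus(c(
    "BP 120/80. Lungs clear.",       # no hotspot -> rule
    "Smokes daily, heavy habit.",    # hotspot -> learner
    "Vitals stable."                 # no hotspot -> rule
  ))
  pred <- predict(model, corpus)
  expect_equal(pred$via_hotspot_rule, c(TRUE, FALSE, TRUE))
  expect_equal(as.character(pred$status[1]), "unknown")
  expect_true(all(as.character(pred$status) %in% smoking_statuses()))
  # rule predictions have no decision scores; learner predictions do
  expect_null(pred$decision_scores[[1]])
  expect_false(is.null(pred$decision_scores[[2]]))
})

test_that("tied decision scores resolve by the canonical class order", {
  scores <- smokereg:::class_scores(
    list("former/current" = 0), c("former", "current")
  )
  expect_equal(names(scores), c("former", "current"))
  best <- names(scores)[scores == max(scores)][1]
  expect_equal(best, "former")  # never < former < current < smoker < unknown
})

test_that("training is reproducible and invariant to note order", {
  corpus <- synth_corpus(synth_config(n_notes = 120, seed = 3))
  probe <- synth_corpus(synth_config(n_notes = 40, seed = 4))
  m1 <- fit_status_model(corpus, status_config(seed = 1))
  m2 <- fit_status_model(corpus, status_config(seed = 1))
  expect_identical(predict(m1, probe), predict(m2, probe))
  shuffled <- corpus[rev(seq_len(nrow(corpus))), ]
  m3 <- fit_status_model(shuffled, status_config(seed = 1))
  p1 <- predict(m1, probe)
  p3 <- predict(m3, probe)
  expect_equal(as.character(p1$status), as.character(p3$status))
})

test_that("a saved model reloads with identical predictions", {
  corpus <- synth_corpus(synth_config(n_notes = 80, seed = 5))
  model <- fit_status_model(corpus)
  path <- withr::local_tempfile(fileext = ".rds")
  save_status_model(model, path)
  reloaded <- load_status_model(path)
  expect_identical(predict(model, corpus), predict(reloaded, corpus))
})

test_that("cross-validation folds are balanced, seeded, and pool to accuracy", {
  corpus <- synth_corpus(synth_config(n_notes = 200, seed = 9))
  expect_error(cross_validate(corpus, k = 1), "k must be")
  cv1 <- cross_validate(corpus, k = 5, status_config(seed = 2))
  cv2 <- cross_validate(corpus, k = 5, status_config(seed = 2))
  expect_identical(cv1$predictions$fold, cv2$predictions$fold)
  expect_length(cv1$folds, 5)
  fold_sizes <- table(cv1$predictions$fold)
  expect_true(max(fold_sizes) - min(fold_sizes) <= length(smoking_statuses()))
  # pooled micro-F1 equals pooled out-of-fold accuracy (identity)
  acc <- mean(as.character(cv1$predictions$status) ==
                as.character(corpus$status))
  expect_equal(cv1$pooled$micro_f1, acc)
})

test_that("tidy/glance expose human-readable weights and a model summary", {
  model <- fit_status_model(toy_separable_corpus())
  weights <- tidy(model)
  expect_true(all(c("pair", "term", "weight") %in% names(weights)))
  expect_true(all(weights$term %in% model$space$vocabulary))
  # weights are attributed to the right classes: tokens exclusive to the
  # "current" notes pull toward current, never-tokens pull the other way
  expect_equal(unique(weights$pair), "current/never")
  w_smokes <- weights$weight[weights$term == "smokes"]
  w_nonsmoker <- weights$weight[weights$term == "nonsmoker"]
  expect_gt(w_smokes, 0)
  expect_lt(w_nonsmoker, 0)
  g <- glance(model)
  expect_equal(g$n_classes, 2)
  expect_equal(g$n_train, 20)
})
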