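test_that("status parsing is total over the five classes and rejects others", {
  expect_equal(as.character(parse_status(c("NEVER", "Former", "current",
                                           "SmOkEr", "unknown"))),
               c("never", "former", "current", "smoker", "unknown"))
  expect_error(parse_status("quitter"), "Unrecognized")
  expect_equal(levels(parse_status(character())), smoking_statuses())
})

test_that("JSONL corpora round-trip field-for-field through write/read", {
  corpus <- make_corpus(
    c("Smokes 1 ppd.", "No tobacco use.", "BP 120/80."),
    c("current", "never", NA)
  )
  corpus$visit_date[1] <- as.Date("2016-03-30")
  corpus$patient_id <- c("P1", "P2", "P3")
  corpus$pack_years[1] <- 20
  corpus$has_pack_year_info[1] <- TRUE
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$note_id, corpus$note_id)
  expect_equal(back$text, corpus$text)
  expect_equal(back$status, corpus$status)
  expect_equal(back$visit_date, corpus$visit_date)
  expect_equal(back$pack_years, corpus$pack_years)
  # second pass is byte-identical (read-write-read fixpoint)
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed records fail with the record index and field named", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"note_id":"a","text":"ok"}', '{"note_id":"b","text":"  "}'),
             path)
  expect_error(read_corpus(path), "Record 2.*note_id=b.*text")
  writeLines(c('{"text":"no id"}'), path)
  expect_error(read_corpus(path), "Record 1.*note_id")
  writeLines(c('{"note_id":"a","text":"x"}', '{"note_id":"a","text":"y"}'),
             path)
  expect_error(read_corpus(path), "Duplicate note_id: a")
})

test_that("unknown fields survive in the metadata bag", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"note_id":"a","text":"ok","source_system":"epic"}', path)
  corpus <- read_corpus(path)
  expect_equal(corpus$meta[[1]]$source_system, "epic")
})

test_that("i2b2 XML records parse with PAST mapped to former", {
  xml <- paste0(
    "<ROOT>",
    '<RECORD ID="101"><SMOKING STATUS="PAST SMOKER"/>',
    "<TEXT>He used to smoke.</TEXT></RECORD>",
    '<RECORD ID="102"><SMOKING STATUS="CURRENT SMOKER"/>',
    "<TEXT>Smokes 1 ppd.</TEXT></RECORD>",
    '<RECORD ID="103"><SMOKING STATUS="NON-SMOKER"/>',
    "<TEXT>Never smoked.</TEXT></RECORD>",
    '<RECORD ID="104"><SMOKING STATUS="UNKNOWN"/>',
    "<TEXT>Lungs clear.</TEXT></RECORD>",
    "</ROOT>"
  )
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  corpus <- read_corpus(path, format = "i2b2_xml")
  expect_equal(nrow(corpus), 4)
  expect_equal(as.character(corpus$status),
               c("former", "current", "never", "unknown"))
  expect_equal(corpus$note_id, c("101", "102", "103", "104"))
})

test_that("predictions round-trip and reject unknown note ids", {
  corpus <- make_corpus(c("Smokes 1 ppd for 10 years.", "No tobacco."),
                        c("current", "never"))
  model <- fit_status_model(toy_separable_corpus())
  result <- run_pipeline(corpus, model)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(corpus, result$predictions, path)
  back <- read_predictions(path)
  expect_equal(back$note_id, result$predictions$note_id)
  expect_equal(back$status, result$predictions$status)
  expect_equal(back$via_hotspot_rule, result$predictions$via_hotspot_rule)
  expect_equal(back$pack_years, result$predictions$pack_years)

  bogus <- result$predictions
  bogus$note_id[1] <- "nope"
  expect_error(write_predictions(corpus, bogus, path), "unknown note_id")

  # empty prediction set -> header-comment-only file
  write_predictions(corpus, result$predictions[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^#")
  expect_equal(nrow(read_predictions(path)), 0)
})

test_that("gold invariant rejects never/unknown notes with behavior gold", {
  corpus <- make_corpus("Never smoked.", "never")
  corpus$has_pack_year_info <- TRUE
  path <- withr::local_tempfile(fileext = ".jsonl")
  expect_error(write_corpus(corpus, path) |> read_corpus(),
               "invariant")
})
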