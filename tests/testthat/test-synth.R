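test_that("generation is deterministic under a fixed seed", {
  c1 <- synth_corpus(synth_config(n_notes = 10, seed = 1))
  c2 <- synth_corpus(synth_config(n_notes = 10, seed = 1))
  expect_identical(c1, c2)
  c3 <- synth_corpus(synth_config(n_notes = 10, seed = 2))
  expect_false(identical(c1$text, c3$text))
})

test_that("degenerate status mixes are honored", {
  cfg <- synth_config(
    n_notes = 25, seed = 1,
    status_mix = c(never = 1, former = 0, current = 0, smoker = 0, unknown = 0)
  )
  corpus <- synth_corpus(cfg)
  expect_true(all(corpus$status == "never"))
  expect_true(all(is.na(corpus$pack_years)))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(status_mix = c(never = 0.5, former = 0.2,
                                           current = 0.2, smoker = 0.2,
                                           unknown = 0.2)),
               "sum to 1")
  expect_error(synth_config(p_distractor = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(status_mix = c(a = 1, b = 0, c = 0, d = 0, e = 0)),
               "named")
})

test_that("class proportions stay inside exact 99% binomial bounds", {
  mix <- c(never = 0.2, former = 0.2, current = 0.2, smoker = 0.1,
           unknown = 0.3)
  n <- 1000
  corpus <- synth_corpus(synth_config(n_notes = n, seed = 7, status_mix = mix))
  counts <- table(corpus$status)
  for (cls in names(mix)) {
    lo <- qbinom(0.005, n, mix[[cls]])
    hi <- qbinom(0.995, n, mix[[cls]])
    expect_gte(counts[[cls]], lo)
    expect_lte(counts[[cls]], hi)
  }
})

test_that("notes are semi-structured with the expected sections", {
  corpus <- synth_corpus(synth_config(n_notes = 50, seed = 3))
  for (section in c("VITALS:", "SOCIAL HISTORY:", "HEALTH SUMMARY:",
                    "IMPRESSIONS:")) {
    expect_true(all(grepl(section, corpus$text, fixed = TRUE)))
  }
})

test_that("template coverage is complete at the default size", {
  corpus <- synth_corpus(synth_config(n_notes = 500, seed = 42))
  coverage <- template_coverage_report(corpus)
  expect_true(all(coverage$covered),
              info = paste(coverage$category[!coverage$covered], collapse = ", "))
})

test_that("tiny corpora report their uncovered templates", {
  corpus <- synth_corpus(synth_config(n_notes = 1, seed = 1))
  coverage <- template_coverage_report(corpus)
  expect_true(any(!coverage$covered))
})

test_that("gold spans resolve to the embedded sentences", {
  corpus <- synth_corpus(synth_config(n_notes = 200, seed = 15))
  for (i in seq_len(nrow(corpus))) {
    m <- corpus$meta[[i]]
    if (!is.na(m$consumption_start)) {
      expect_equal(substring(corpus$text[i], m$consumption_start + 1,
                             m$consumption_end),
                   m$consumption_text)
    }
    if (!is.na(m$cessation_start)) {
      expect_equal(substring(corpus$text[i], m$cessation_start + 1,
                             m$cessation_end),
                   m$cessation_text)
    }
  }
})

test_that("extraction on gold source text reproduces embedded values exactly", {
  corpus <- synth_corpus(synth_config(n_notes = 300, seed = 23))
  rules <- default_rules()
  for (i in seq_len(nrow(corpus))) {
    m <- corpus$meta[[i]]
    if (!is.na(m$consumption_text)) {
      f <- extract_pack_years(m$consumption_text, rules)
      expect_equal(nrow(f), 1, info = m$consumption_text)
      expect_equal(f$pack_years, corpus$pack_years[i], info = m$consumption_text)
      expect_equal(f$packs_per_day, corpus$packs_per_day[i],
                   info = m$consumption_text)
      expect_equal(f$cigarettes_per_day, corpus$cigarettes_per_day[i],
                   info = m$consumption_text)
      expect_equal(f$years_smoked, corpus$years_smoked[i],
                   info = m$consumption_text)
    }
    if (!is.na(m$cessation_text)) {
      f <- extract_cessation_date(m$cessation_text, rules)
      if (identical(m$cessation_format, "decade")) {
        expect_equal(nrow(f), 0, info = m$cessation_text)
      } else {
        expect_equal(f$date, corpus$cessation_date[i], info = m$cessation_text)
        expect_equal(f$precision, corpus$cessation_precision[i],
                     info = m$cessation_text)
      }
    }
  }
})
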