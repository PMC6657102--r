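rules <- default_rules()

test_that("a complete pack-year match short-circuits the lower tiers", {
  f <- extract_pack_years("30 pack year history; currently 1 ppd", rules)
  expect_equal(f$kind, "complete")
  expect_equal(f$pack_years, 30)
  expect_true(is.na(f$packs_per_day))  # lower tier never consulted
  # adding a pack-year phrase to any partial text overrides lower tiers
  partials <- c("2 packs per day for 20 years", "smokes 10 cigarettes a day",
                "has smoked for 15 years")
  for (p in partials) {
    f2 <- extract_pack_years(paste("12 pack years.", p), rules)
    expect_equal(f2$kind, "complete")
    expect_equal(f2$pack_years, 12)
  }
})

test_that("computed pack years multiply intensity by duration", {
  f <- extract_pack_years("2 packs per day for 20 years", rules)
  expect_equal(f$kind, "computed")
  expect_equal(f$pack_years, 40)
  f <- extract_pack_years("smokes 10 cigarettes a day for 10 years", rules)
  expect_equal(f$kind, "computed")
  expect_equal(f$pack_years, 5)  # (10/20) x 10
  f <- extract_pack_years("1 ppd x 20 yrs", rules)
  expect_equal(f$pack_years, 20)
})

test_that("computed arithmetic holds over random quantities", {
  set.seed(101)
  for (i in 1:50) {
    ppd <- sample(c(0.5, 1, 1.5, 2, 2.5, 3), 1)
    cpd <- sample(c(3, 5, 10, 15, 20, 30, 40), 1)
    yrs <- sample(1:60, 1)
    f <- extract_pack_years(
      sprintf("smokes %g packs per day for %d years", ppd, yrs), rules)
    expect_equal(f$pack_years, round(ppd * yrs, 1))
    f <- extract_pack_years(
      sprintf("smokes %g cigarettes per day for %d years", cpd, yrs), rules)
    expect_equal(f$pack_years, round(cpd / 20 * yrs, 1))
  }
})

test_that("partial information is stored without a pack-year total", {
  f <- extract_pack_years("smokes about half a pack per day", rules)
  expect_equal(f$kind, "partial")
  expect_equal(f$packs_per_day, 0.5)
  expect_true(is.na(f$pack_years))
  f <- extract_pack_years("has smoked for 15 years", rules)
  expect_equal(f$kind, "partial")
  expect_equal(f$years_smoked, 15)
  f <- extract_pack_years("about 10 cigarettes per day", rules)
  expect_equal(f$cigarettes_per_day, 10)
})

test_that("word-number forms parse and empty text yields nothing", {
  f <- extract_pack_years("smokes two packs per day for ten years", rules)
  expect_equal(f$pack_years, 20)
  f <- extract_pack_years("a pack a day habit", rules)
  expect_equal(f$packs_per_day, 1)
  expect_equal(nrow(extract_pack_years("", rules)), 0)
  expect_equal(nrow(extract_pack_years("Lungs clear. BP 120/80.", rules)), 0)
})

test_that("relative durations ('ten years ago') are not years smoked", {
  expect_equal(nrow(extract_pack_years("quit smoking ten years ago", rules)), 0)
})

test_that("the first finding in document order wins; all matches retained", {
  f <- extract_pack_years("20 pack years per old chart; 35 pack years today",
                          rules)
  expect_equal(f$pack_years, 20)
  expect_equal(nrow(f$matches[[1]]$pack_years), 2)
})

test_that("date normalization covers the format matrix with correct precision", {
  cases <- list(
    list("07/04/1999", "1999-07-04", "day"),
    list("7/4/99", "1999-07-04", "day"),
    list("3/15/10", "2010-03-15", "day"),
    list("July 4, 1999", "1999-07-04", "day"),
    list("Jul 4 1999", "1999-07-04", "day"),
    list("July 1999", "1999-07-01", "month"),
    list("03/2010", "2010-03-01", "month"),
    list("1995", "1995-01-01", "year"),
    list("'95", "1995-01-01", "year"),
    list("05", "2005-01-01", "year")
  )
  for (case in cases) {
    norm <- normalize_date(case[[1]])
    expect_false(is.null(norm), info = case[[1]])
    expect_equal(format(norm$date), case[[2]], info = case[[1]])
    expect_equal(norm$precision, case[[3]], info = case[[1]])
  }
  for (bad in c("the late 1980s", "1980s", "spring 1995", "1995-1998",
                "13/45/2010", "sometime", "")) {
    expect_null(normalize_date(bad), info = bad)
  }
})

test_that("two-digit years pivot at 29 across the whole range", {
  for (yy in 0:99) {
    expected <- if (yy <= 29) 2000 + yy else 1900 + yy
    norm <- normalize_date(sprintf("%02d", yy))
    expect_equal(as.integer(format(norm$date, "%Y")), expected)
  }
})

test_that("normalize_date is idempotent under re-rendering", {
  cases <- list(
    list(as.Date("2010-03-15"), "day"),
    list(as.Date("1999-07-01"), "month"),
    list(as.Date("1995-01-01"), "year")
  )
  for (case in cases) {
    rendered <- render_date(case[[1]], case[[2]])
    norm <- normalize_date(rendered)
    expect_equal(norm$date, case[[1]])
    expect_equal(norm$precision, case[[2]])
  }
})

test_that("cessation dates require a cue anchored in the same sentence", {
  f <- extract_cessation_date("quit smoking 03/15/2010", rules)
  expect_equal(format(f$date), "2010-03-15")
  expect_equal(f$precision, "day")
  f <- extract_cessation_date("quit tobacco in 1995", rules)
  expect_equal(format(f$date), "1995-01-01")
  expect_equal(f$precision, "year")
  # unanchored dates (service dates, blood panels) are never returned
  expect_equal(nrow(extract_cessation_date(
    "CBC drawn 03/15/2010; denies quitting", rules)), 0)
  expect_equal(nrow(extract_cessation_date(
    "Follow-up 04/02/2016. Patient quit smoking.", rules)), 0)
  # vague decade phrasing is rejected by contract
  expect_equal(nrow(extract_cessation_date(
    "patient quit in the late 1980s", rules)), 0)
  expect_equal(nrow(extract_cessation_date("", rules)), 0)
})

test_that("negated cues do not anchor dates", {
  expect_equal(nrow(extract_cessation_date(
    "never quit, still smoking as of 03/15/2010", rules)), 0)
  expect_equal(nrow(extract_cessation_date(
    "has not stopped smoking since 2005", rules)), 0)
})

test_that("rule sets load from the versioned pattern file", {
  expect_equal(default_rules()$version, "1")
  expect_equal(names(default_rules()$tiers),
               c("pack_years", "packs_per_day", "cigarettes_per_day",
                 "years_smoked"))
  expect_error(load_rules("/nonexistent/rules.json"), "No such rule file")
})
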