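# Corpus reading, label parsing, truncation, and prediction round-trips.

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("rows map to records with parsed labels", {
  p <- write_fixture(c(
    "record_id,activity_code,narrative",
    "7,1,injured hand on saw at work",
    "8,0,",
    "9,,no activity code recorded",
    "10,WORK,upper case label",
    "11,weird,unparseable label"
  ))
  corp <- read_corpus(p)
  expect_s3_class(corp, "labeled_corpus")
  expect_equal(nrow(corp), 5L)
  expect_equal(corp$record_id, as.character(7:11))
  expect_equal(corp$activity_label,
               c("work", "other", "missing", "work", "missing"))
  expect_equal(corp$narrative[1], "injured hand on saw at work")
  expect_equal(corp$narrative[2], "")
})

test_that("missing-label rows are retained on load, excluded at evaluation", {
  p <- write_fixture(c(
    "id,code,text",
    paste(1:20, rep(c(1, 0), 10), "some text", sep = ","),
    "21,,blank label one",
    "22,,blank label two"
  ))
  corp <- read_corpus(p)
  expect_equal(nrow(corp), 22L) # nothing dropped by the loader
  flags <- stats::setNames(rep(FALSE, 22), corp$record_id)
  ev <- evaluate_flags(flags, corp)
  expect_equal(ev$n_excluded_missing, 2L)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn + ev$n_excluded_missing,
               nrow(corp))
})

test_that("long narratives are truncated to 255 characters with a warning", {
  long <- paste(rep("x", 300), collapse = "")
  p <- write_fixture(c("id,code,text", paste0("1,1,", long)))
  expect_warning(corp <- read_corpus(p), "truncated")
  expect_equal(nchar(corp$narrative[1]), 255L)
})

test_that("wrong column count errors with the row number", {
  p <- write_fixture(c("id,code,text", "1,1,ok", "2,1"))
  expect_error(read_corpus(p), "row 3")
})

test_that("missing file and duplicate IDs are fatal", {
  expect_error(read_corpus(file.path(tempdir(), "nope-not-here.csv")),
               "not found")
  expect_error(labeled_corpus(c("1", "1"), c("work", "other"), c("a", "b")),
               "duplicate")
})

test_that("write/read round-trip preserves count, IDs, labels, narratives", {
  corp <- generate_corpus(generator_params(n_records = 120L, seed = 3L,
                                           missing_label_count = 4L))$corpus
  p <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, p)
  back <- read_corpus(p)
  expect_equal(nrow(back), nrow(corp))
  expect_equal(back$record_id, corp$record_id)
  expect_equal(back$activity_label, corp$activity_label)
  expect_equal(back$narrative, corp$narrative)
})

test_that("narratives containing the delimiter survive quoting", {
  corp <- labeled_corpus("1", "work", "cut hand, at work, with saw")
  p <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, p)
  back <- read_corpus(p)
  expect_equal(back$narrative, corp$narrative)
})

test_that("predictions round-trip and refuse incomplete flag sets", {
  corp <- tiny_corpus()
  kw <- keyword_flag_corpus(corp)
  p <- withr::local_tempfile(fileext = ".csv")
  write_predictions(corp, list(keyword = kw), p)
  back <- read_predictions(p)
  expect_equal(back$record_id, corp$record_id)
  expect_equal(back$activity_label, corp$activity_label)
  expect_equal(back$keyword, unname(kw))
  expect_error(write_predictions(corp, list(bad = kw[-1]), p), "missing")
})

test_that("tab-delimited corpora are supported via the dialect argument", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tcode\ttext", "1\t1\thurt at work"), p)
  corp <- read_corpus(p, delim = "\t")
  expect_equal(corp$activity_label, "work")
  expect_equal(corp$narrative, "hurt at work")
})
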