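# Index construction and index/union flagging.

ann_row <- function(id, heading, keyword) {
  data.frame(record_id = as.character(id), heading = heading,
             keyword = keyword, stringsAsFactors = FALSE)
}

test_that("stems merge by prefix before the frequency threshold", {
  # weld appears as an activity (welding, 3x) and an occupation (welder,
  # 4x); neither variant alone reaches 5, the merged stem does
  ann <- rbind(
    ann_row(1:3, "activity task", "welding"),
    ann_row(4:7, "occupation", "welder"),
    ann_row(8:11, "body site", "hand") # outside the used headings
  )
  idx <- build_index(ann, min_frequency = 5L)
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$stem, "weld")
  expect_equal(idx$frequency, 7L)
  expect_match(idx$headings, "activity task")
  expect_match(idx$headings, "occupation")
})

test_that("min_frequency boundaries behave as specified", {
  ann <- rbind(ann_row(1:4, "occupation", "welder"))
  # merged frequency 4 < 5: nothing survives
  expect_error(build_index(ann, min_frequency = 5L), "min_frequency")
  # threshold 1 keeps every distinct stem
  ann2 <- rbind(ann_row(1, "occupation", "welder"),
                ann_row(2, "work location", "factory"))
  idx2 <- build_index(ann2, min_frequency = 1L)
  expect_setequal(idx2$stem, c("welder", "factor"))
})

test_that("index building is permutation-invariant", {
  gen <- generate_corpus(generator_params(n_records = 30000L, seed = 13L))
  ann <- gen$annotations
  idx1 <- build_index(ann)
  set.seed(99)
  idx2 <- build_index(ann[sample(nrow(ann)), ])
  expect_equal(as.data.frame(idx1), as.data.frame(idx2))
})

test_that("single-word index stems are substrings of their surface forms", {
  gen <- generate_corpus(generator_params(n_records = 30000L, seed = 13L))
  idx <- build_index(gen$annotations)
  single <- idx$stem[!grepl(" ", idx$stem)]
  surfaces <- tolower(gen$annotations$keyword)
  for (s in single) {
    expect_true(any(startsWith(surfaces, s)), info = s)
  }
})

test_that("index flag matches stems and multi-word phrases", {
  idx <- default_index()
  expect_true(index_flag("fell from forklift at job site", idx))
  expect_true(index_flag("cut hand at the FACTORY", idx))
  expect_true(index_flag("welding accident", idx))
  # phrase matches across collapsed whitespace
  expect_true(index_flag("on the job   site this morning", idx))
  expect_false(index_flag("", idx))
  expect_false(index_flag("fell at home", idx))
})

test_that("index matches report every matched stem", {
  corp <- labeled_corpus("1", "work",
                         "driving forklift at job site near the mine")
  m <- index_matches(corp, default_index())
  expect_setequal(m[["1"]], c("forklift", "job site", "mine"))
})

test_that("empty index is rejected", {
  idx <- default_index()[0, ]
  class(idx) <- c("term_index", "data.frame")
  expect_error(index_flag("anything", idx), "empty")
})

test_that("index files round-trip", {
  idx <- default_index()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_index(idx, p)
  back <- read_index(p)
  expect_equal(back$stem, idx$stem)
  expect_equal(back$frequency, idx$frequency)
})

test_that("union flag is the exact set union", {
  corp <- generate_corpus(generator_params(n_records = 3000L,
                                           seed = 17L))$corpus
  kw <- keyword_flag_corpus(corp)
  ix <- index_flag_corpus(corp, default_index())
  un <- union_flag(kw, ix)
  expect_equal(un, kw | ix[names(kw)])
  expect_equal(sum(un),
               length(union(names(kw)[kw], names(ix)[ix])))
  expect_gte(sum(un), max(sum(kw), sum(ix)))
  # domain mismatch errors and names the difference
  expect_error(union_flag(kw[-1], ix), "symmetric difference")
})

test_that("review sample is work-labelled, keyword-negative, deterministic", {
  corp <- generate_corpus(generator_params(n_records = 20000L,
                                           seed = 19L))$corpus
  kw <- keyword_flag_corpus(corp)
  s1 <- select_review_sample(corp, kw, n = 500L, seed = 42L)
  expect_equal(nrow(s1), 500L)
  expect_true(all(s1$activity_label == "work"))
  expect_false(any(keyword_flag(s1$narrative)))
  s2 <- select_review_sample(corp, kw, n = 500L, seed = 42L)
  expect_identical(s1$record_id, s2$record_id)
  s3 <- select_review_sample(corp, kw, n = 500L, seed = 43L)
  expect_false(identical(s1$record_id, s3$record_id))
  # n = 0 gives an empty corpus; infeasible n errors with the count
  expect_equal(nrow(select_review_sample(corp, kw, n = 0L, seed = 1L)), 0L)
  expect_error(select_review_sample(corp, kw, n = nrow(corp), seed = 1L),
               "eligible")
})
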