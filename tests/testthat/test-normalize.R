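# Tokenization, stemming and stop-list behaviour.

test_that("tokenize splits on non-alphanumeric runs and folds case", {
  expect_equal(tokenize("Hurt back at work yesterday")[[1]],
               c("hurt", "back", "at", "work", "yesterday"))
  expect_equal(tokenize("work-related eye injury")[[1]],
               c("work", "related", "eye", "injury"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize(NA_character_)[[1]], character(0))
  # numerals are kept
  expect_equal(tokenize("fell 2 hours ago")[[1]],
               c("fell", "2", "hours", "ago"))
})

test_that("hand tokenization of fixture narratives matches", {
  fixtures <- list(
    "Went home from work; metal in eye" =
      c("went", "home", "from", "work", "metal", "in", "eye"),
    "co-worker dropped box on foot" =
      c("co", "worker", "dropped", "box", "on", "foot"),
    "L)  hand lac." = c("l", "hand", "lac"),
    "NOT work-related" = c("not", "work", "related")
  )
  for (txt in names(fixtures)) {
    expect_equal(tokenize(txt)[[1]], fixtures[[txt]], info = txt)
  }
})

test_that("porter stem collapses grammatical variants of work", {
  expect_equal(porter_stem(c("work", "works", "working", "worked")),
               rep("work", 4))
})

test_that("porter stem matches pinned golden outputs", {
  golden <- c(
    caresses = "caress", ponies = "poni", caress = "caress", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster", bled = "bled",
    motoring = "motor", sing = "sing", hopping = "hop", tanned = "tan",
    falling = "fall", hissing = "hiss", filing = "file", happy = "happi",
    sky = "sky", conditional = "condit", operator = "oper",
    feudalism = "feudal", hopefulness = "hope", formative = "form",
    allowance = "allow", inference = "infer", adjustable = "adjust",
    replacement = "replac", adoption = "adopt", activate = "activ",
    effective = "effect", rate = "rate", cease = "ceas",
    controll = "control",
    # index-vocabulary words
    factories = "factori", factory = "factori", injuries = "injuri",
    injured = "injur", welding = "weld", welder = "welder",
    mining = "mine", miner = "miner", construction = "construct",
    labourer = "labour", lacerated = "lacer", forklift = "forklift"
  )
  expect_equal(porter_stem(names(golden)), unname(golden))
})

test_that("stemming is deterministic, idempotent, and total", {
  set.seed(7)
  words <- c(
    replicate(200, paste(sample(letters, sample(3:12, 1), TRUE),
                         collapse = "")),
    "x1y2", "a", "", "R2D2"
  )
  s1 <- porter_stem(words)
  expect_identical(s1, porter_stem(words))
  expect_identical(porter_stem(s1), s1)
  expect_equal(length(s1), length(words))
})

test_that("stop-list removes function words but keeps injury vocabulary", {
  stream <- token_stream("the saw cut his back")
  out <- apply_stoplist(stream, default_stoplist())
  expect_equal(out$tokens, c("saw", "cut", "back"))
  # order of survivors preserved
  out2 <- apply_stoplist(token_stream("back the saw"), default_stoplist())
  expect_equal(out2$tokens, c("back", "saw"))
})

test_that("stop-list edge cases: empty stream and all-stop stream", {
  expect_equal(apply_stoplist(token_stream(""))$tokens, character(0))
  expect_equal(apply_stoplist(token_stream("the and but of"))$tokens,
               character(0))
})

test_that("retained overrides beat the exclusion list", {
  st <- stoplist(exclude = c("saw", "the", "machines"),
                 retain = c("saw", "machine"))
  expect_false("saw" %in% st$excluded)
  expect_false("machin" %in% st$excluded)
  expect_true("the" %in% st$excluded)
})

test_that("normalization of a corpus is byte-identical across runs", {
  texts <- generate_corpus(generator_params(n_records = 300L,
                                            seed = 11L))$corpus$narrative
  expect_identical(narrative_stems(texts), narrative_stems(texts))
})
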