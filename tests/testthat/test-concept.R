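# Concept learning, scoring, classification rules, calibration, t-test.

toy_params <- function(...) {
  concept_params(min_term_frequency = 2L, margin_floor = 0, ...)
}

test_that("class association is the smoothed conditional frequency", {
  model <- learn_concept_model(tiny_corpus(), toy_params())
  seeds <- vapply(model$concepts, `[[`, character(1), "seed")
  fact <- model$concepts[[which(seeds == "factori")]]
  # factory occurs in 2 records, both work: (2+1)/(2+2) with add-one
  expect_equal(fact$assoc_work, 0.75)
  expect_equal(fact$assoc_other, 0.25)
  expect_equal(fact$tag, "work")
  # associations always sum to 1
  for (co in model$concepts) {
    expect_equal(co$assoc_work + co$assoc_other, 1)
  }
})

test_that("degenerate corpora are rejected", {
  corp <- tiny_corpus()
  only_work <- labeled_corpus(corp$record_id[1:3], corp$activity_label[1:3],
                              corp$narrative[1:3])
  expect_error(learn_concept_model(only_work, toy_params()), "each label")
  expect_error(
    learn_concept_model(tiny_corpus(),
                        concept_params(min_term_frequency = 99L)),
    "min_term_frequency")
})

test_that("duplicating every record leaves class associations almost unchanged", {
  corp <- tiny_corpus()
  dup <- labeled_corpus(c(corp$record_id, paste0("d", corp$record_id)),
                        rep(corp$activity_label, 2),
                        rep(corp$narrative, 2))
  # threshold 1 so the seed set is frequency-scale invariant
  p <- concept_params(min_term_frequency = 1L, margin_floor = 0)
  m1 <- learn_concept_model(corp, p)
  m2 <- learn_concept_model(dup, p)
  s1 <- vapply(m1$concepts, `[[`, character(1), "seed")
  s2 <- vapply(m2$concepts, `[[`, character(1), "seed")
  expect_setequal(s1, s2)
  for (s in s1) {
    a1 <- m1$concepts[[which(s1 == s)]]$assoc_work
    a2 <- m2$concepts[[which(s2 == s)]]$assoc_work
    # identical raw frequencies; only the fixed smoothing constant keeps
    # the doubled-corpus estimate from matching exactly
    expect_lt(abs(a1 - a2), 0.15)
    expect_equal(sign(a1 - 0.5), sign(a2 - 0.5))
  }
})

test_that("scoring the worked example favours work but keeps other evidence", {
  # training corpus in which metal, eye and work are work-associated and
  # home is other-associated
  train <- labeled_corpus(
    as.character(1:8),
    c(rep("work", 4), rep("other", 4)),
    c("metal in eye at work", "eye injury from metal grinding at work",
      "metal shaving in eye at work", "metal fragment in eye at work",
      "fell over at home", "slipped at home", "burnt hand at home",
      "tripped at home in garden")
  )
  model <- learn_concept_model(train, toy_params())
  corp <- plant_worked_example(labeled_corpus(character(0), character(0),
                                              character(0)))
  sc <- score_record(model, corp$narrative[1])
  expect_gt(sc$score_work, sc$score_other)
  expect_gt(sc$score_other, 0) # 'home' carries other-activity evidence
})

test_that("empty and no-evidence narratives score (0, 0)", {
  model <- learn_concept_model(tiny_corpus(), toy_params())
  sc <- score_record(model, "")
  expect_equal(sc$score_work, 0)
  expect_equal(sc$score_other, 0)
  expect_equal(classify_binary(sc)[[1]], FALSE)
  expect_equal(as.character(classify_four_way(sc)), "OtherActivity")
})

test_that("binary classification accepts any positive work score", {
  sc <- data.frame(record_id = c("a", "b", "c"),
                   score_work = c(0.4, 0, 0),
                   score_other = c(0.9, 0.3, 0))
  sc$diff <- sc$score_work - sc$score_other
  expect_equal(unname(classify_binary(sc)), c(TRUE, FALSE, FALSE))
})

test_that("four-way rules are forced on canonical score pairs", {
  sc <- data.frame(record_id = as.character(1:4),
                   score_work = c(0.5, 0.4, 0.2, 0),
                   score_other = c(0, 0.4, 0.5, 0.3))
  sc$diff <- sc$score_work - sc$score_other
  expect_equal(as.character(classify_four_way(sc)),
               c("WorkActivity", "ProbableWorkActivity",
                 "ProbableOtherActivity", "OtherActivity"))
})

test_that("four-way classification is total and single-valued", {
  set.seed(31)
  vals <- c(0, 0, 0.2, runif(40, 0, 3))
  grid <- expand.grid(w = vals, o = vals)
  # include exact ties explicitly
  grid <- rbind(grid, data.frame(w = c(0.4, 1.7), o = c(0.4, 1.7)))
  sc <- data.frame(record_id = as.character(seq_len(nrow(grid))),
                   score_work = grid$w, score_other = grid$o,
                   diff = grid$w - grid$o)
  cls <- classify_four_way(sc)
  expect_false(anyNA(cls))
  # rules are mutually exclusive re-derived by direct logic
  expected <- ifelse(grid$w > 0 & grid$o == 0, "WorkActivity",
              ifelse(grid$w > 0 & grid$o > 0 & grid$w >= grid$o,
                     "ProbableWorkActivity",
              ifelse(grid$w > 0 & grid$o > 0, "ProbableOtherActivity",
                     "OtherActivity")))
  expect_equal(as.character(cls), expected)
  # ties with both sides positive go to ProbableWorkActivity
  ties <- grid$w == grid$o & grid$w > 0
  expect_true(all(cls[ties] == "ProbableWorkActivity"))
})

test_that("cutoff calibration follows |mean| + sd on the target group", {
  sc <- data.frame(record_id = as.character(1:5),
                   score_work = c(0.5, 0.5, 0.5, 1, 0.1),
                   score_other = c(1.0, 1.5, 2.0, 0.5, 0.4))
  sc$diff <- sc$score_work - sc$score_other
  labels <- c("work", "work", "work", "work", "other")
  cal <- calibrate_cutoff(sc, labels)
  # work-labelled ProbableOtherActivity diffs: -0.5, -1.0, -1.5
  expect_equal(cal$cutoff, 1.5)
  wsum <- cal$summary[cal$summary$label == "work", ]
  expect_equal(wsum$n, 3L)
  expect_equal(wsum$mean, -1.0)
  expect_equal(wsum$sd, 0.5)
})

test_that("all-equal diffs give sd 0 and cutoff |mean|", {
  sc <- data.frame(record_id = as.character(1:2),
                   score_work = c(0.5, 0.5), score_other = c(1.2, 1.2))
  sc$diff <- sc$score_work - sc$score_other
  cal <- calibrate_cutoff(sc, c("work", "work"))
  expect_equal(cal$cutoff, 0.7)
  expect_error(calibrate_cutoff(sc, c("work", "other")), "at least 2")
})

test_that("moment-based cutoff reproduces the published construction", {
  expect_equal(cutoff_from_moments(-0.83, 0.63), 1.46)
})

test_that("adjusted classification touches only rule-3 records", {
  sc <- data.frame(record_id = as.character(1:4),
                   score_work = c(0.5, 0.4, 0.2, 0),
                   score_other = c(0, 0.4, 0.5, 0.3))
  sc$diff <- sc$score_work - sc$score_other
  cls <- classify_four_way(sc)
  adj <- apply_adjusted_classification(cls, sc, cutoff = 1.47)
  expect_equal(as.character(adj$class),
               c("WorkActivity", "ProbableWorkActivity",
                 "ProbableWorkActivity", "OtherActivity"))
  expect_equal(unname(adj$flag), c(TRUE, TRUE, TRUE, FALSE))
  # a rule-3 record beyond the cutoff stays put (strict inequality)
  sc2 <- data.frame(record_id = "x", score_work = 0.2, score_other = 2.2,
                    diff = -2.0)
  cls2 <- classify_four_way(sc2)
  adj2 <- apply_adjusted_classification(cls2, sc2, cutoff = 1.47)
  expect_equal(as.character(adj2$class), "ProbableOtherActivity")
  expect_false(adj2$flag[[1]])
  expect_error(apply_adjusted_classification(cls2, sc2, cutoff = 0),
               "positive")
})

test_that("flag count is monotone in the cutoff and non-rule-3 never flip", {
  set.seed(37)
  n <- 400
  sc <- data.frame(record_id = as.character(1:n),
                   score_work = round(runif(n, 0, 2), 2) *
                     rbinom(n, 1, 0.8),
                   score_other = round(runif(n, 0, 2), 2) *
                     rbinom(n, 1, 0.8))
  sc$diff <- sc$score_work - sc$score_other
  cls <- classify_four_way(sc)
  cuts <- c(0.1, 0.5, 1, 1.47, 2, 5)
  counts <- integer(0)
  for (ct in cuts) {
    adj <- apply_adjusted_classification(cls, sc, ct)
    counts <- c(counts, sum(adj$flag))
    changed <- as.character(adj$class) != as.character(cls)
    expect_true(all(cls[changed] == "ProbableOtherActivity"))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("pooled t-test matches the hand-computed formula", {
  expect_error(compare_groups_ttest(1, c(1, 2)), "at least 2")
  expect_error(compare_groups_ttest(c(1, 1), c(1, 1)), "pooled variance")
  # identical groups: t = 0
  tt0 <- compare_groups_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  # hand computation: means 2 vs 5, pooled var 1, se = sqrt(2/3)
  tt <- compare_groups_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(tt$df, 4)
})

test_that("groups with the published moments give |t| near 47", {
  set.seed(41)
  make_group <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  work <- make_group(5609, -0.83, 0.63)
  other <- make_group(11662, -1.47, 0.92)
  tt <- compare_groups_ttest(work, other)
  expect_equal(tt$df, 17269)
  # analytic value from the exact moments is 47.06
  expect_equal(abs(tt$t), 47.06, tolerance = 0.01)
})
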