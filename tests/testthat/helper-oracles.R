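# Independent oracles and fixture builders shared across the suite.

# Naive character-scan substring test, independent of grepl: slides a
# window over the lower-cased text and compares character by character.
oracle_substring <- function(text, pattern) {
  text <- tolower(text)
  pattern <- tolower(pattern)
  nt <- nchar(text)
  np <- nchar(pattern)
  if (np == 0L || nt < np) return(FALSE)
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (start in seq_len(nt - np + 1L)) {
    if (all(tc[start:(start + np - 1L)] == pc)) return(TRUE)
  }
  FALSE
}

# Brute-force concept scoring: enumerate every concept, find its matched
# members in the record's stop-listed stem set by explicit set
# intersection, take the maximum member weight, and accumulate the class
# association on the concept's tag. Mirrors the scoring definition without
# any matrix machinery.
oracle_score <- function(model, narrative) {
  toks <- tokenize(narrative)[[1]]
  stems <- unique(porter_stem(toks))
  stems <- stems[!(stems %in% model$stops$excluded)]
  sw <- 0
  so <- 0
  for (co in model$concepts) {
    matched <- intersect(names(co$members), stems)
    if (length(matched)) {
      best <- max(co$members[matched])
      if (co$tag == "work") {
        sw <- sw + co$assoc_work * best
      } else {
        so <- so + co$assoc_other * best
      }
    }
  }
  c(score_work = sw, score_other = so)
}

# Explicit set-algebra region counts for k flag sets plus the gold work set.
oracle_venn <- function(flag_sets, corpus) {
  labelled <- corpus$activity_label %in% c("work", "other")
  ids <- corpus$record_id[labelled]
  sets <- c(
    lapply(flag_sets, function(v) ids[as.logical(v[ids])]),
    list(work_code = ids[corpus$activity_label[labelled] == "work"])
  )
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- names(sets)
  counts <- integer(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    members <- ids
    for (cidx in seq_len(k)) {
      members <- if (combos[r, cidx]) intersect(members, sets[[cidx]])
      else setdiff(members, sets[[cidx]])
    }
    counts[r] <- length(members)
  }
  combos$count <- counts
  combos
}

# Small fully-specified corpus used across module tests.
tiny_corpus <- function() {
  labeled_corpus(
    record_id = as.character(1:6),
    activity_label = c("work", "work", "work", "other", "other", "other"),
    narrative = c("fell at factory", "forklift hit leg",
                  "cut hand at factory", "fell at home",
                  "cut hand at home", "dog bite at park"),
    provenance = "fixture"
  )
}

# Random tiny corpus over a fixed 15-word vocabulary, with both labels
# guaranteed present; used by the scoring-oracle property test.
random_tiny_corpus <- function(vocab15) {
  n <- sample(4:10, 1L)
  narr <- vapply(seq_len(n), function(i) {
    k <- sample(0:5, 1L)
    paste(sample(vocab15, k, replace = TRUE), collapse = " ")
  }, character(1))
  lab <- sample(c("work", "other"), n, replace = TRUE)
  lab[1:2] <- c("work", "other")
  labeled_corpus(as.character(seq_len(n)), lab, narr,
                 provenance = "property-fixture")
}
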