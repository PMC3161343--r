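# Synthetic triage-narrative generator. Emulates the class-conditional
# structure of the surveillance corpus the classifiers were designed for:
# ~10.3% of presentations are work-coded; the word "work" appears in ~58% of
# work-coded and ~1% of other-coded narratives (the latter via phrases like
# "saw that was not working properly"); work-coded narratives without the
# keyword carry curated index terms at known rates; plus negation phrases,
# scant/empty descriptions and occasional misspellings. The emission rates
# are calibrated to published marginal flag rates, so agreement between the
# classifiers and those marginals on synthetic data validates the pipeline's
# mechanics by construction — it says nothing new about real triage text.

#' Generator parameters
#'
#' Defaults reproduce the published class-conditional flag rates:
#' 10.3% work prevalence; keyword present in 58.16% of work and 1.03% of
#' other records; among work records the index-term rate is 69.9% with the
#' keyword and 50.7% without (the joint structure implied by the published
#' keyword/index/union counts); 12.54% of other records carry an index term.
#'
#' @param n_records Number of records.
#' @param work_prevalence P(work label).
#' @param p_keyword_given_work P(narrative contains "work" | work label).
#' @param p_keyword_given_other P(narrative contains "work" | other label).
#' @param p_index_term_given_work_with_keyword P(index term | work label,
#'   keyword present).
#' @param p_index_term_given_work_no_keyword P(index term | work label,
#'   keyword absent).
#' @param p_index_term_given_other P(index term | other label).
#' @param negation_rate Rate of an extra negation phrase on keyword-positive
#'   work records ("hurt back at work yesterday and did not work today").
#'   Negation phrases never remove a record from consideration downstream.
#' @param empty_text_rate Rate of empty narratives among records with no
#'   planted keyword/term (planted rates are never perturbed).
#' @param misspelling_rate Rate of single-character corruptions, applied to
#'   non-planted tokens only.
#' @param missing_label_count Number of records whose activity label is
#'   blanked (default 10).
#' @param seed Integer RNG seed; a fixed seed gives a byte-identical corpus.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_records = 10000L,
                             work_prevalence = 0.103,
                             p_keyword_given_work = 0.5816,
                             p_keyword_given_other = 0.0103,
                             p_index_term_given_work_with_keyword = 0.699,
                             p_index_term_given_work_no_keyword = 0.507,
                             p_index_term_given_other = 0.1254,
                             negation_rate = 0.03,
                             empty_text_rate = 0.02,
                             misspelling_rate = 0.02,
                             missing_label_count = 10L,
                             seed = 1L) {
  p <- list(n_records = as.integer(n_records),
            work_prevalence = work_prevalence,
            p_keyword_given_work = p_keyword_given_work,
            p_keyword_given_other = p_keyword_given_other,
            p_index_term_given_work_with_keyword =
              p_index_term_given_work_with_keyword,
            p_index_term_given_work_no_keyword =
              p_index_term_given_work_no_keyword,
            p_index_term_given_other = p_index_term_given_other,
            negation_rate = negation_rate,
            empty_text_rate = empty_text_rate,
            misspelling_rate = misspelling_rate,
            missing_label_count = as.integer(missing_label_count),
            seed = as.integer(seed))
  probs <- unlist(p[grepl("^p_|prevalence|rate$", names(p))])
  stopifnot(p$n_records >= 0L, all(probs >= 0 & probs <= 1),
            p$missing_label_count >= 0L)
  structure(p, class = "generator_params")
}

#' Default vocabulary pools
#'
#' Work terms (with annotation heading and class-conditional sampling
#' weights), other-activity contexts, shared injury phrases, keyword and
#' negation phrase pools, and temporal tails. Work terms and other-activity
#' contexts are disjoint; shared injury phrases appear in both classes.
#' Seven of the work terms are the published high-specificity index terms
#' (job site, factory, labourer, forklift, mine/miner, construction,
#' client); the rest are synthetic vocabulary. Sampling weights are chosen
#' so specific terms occur overwhelmingly in work records while a few
#' ambiguous terms (truck, station, office, boss, ...) occur in both
#' classes, mirroring the heterogeneous term specificity seen in practice.
#'
#' @return List of class `vocabulary_pools`.
#' @export
default_vocabulary <- function() {
  wt <- data.frame(
    term = c("job site", "factory", "forklift", "mine", "miner",
             "construction", "labourer", "client", "welding", "welder",
             "scaffold", "crane", "warehouse", "grinder", "hard hat",
             "safety harness", "apprentice", "lathe",
             "boss", "supervisor", "station", "driver", "truck", "office",
             "customer", "shift"),
    heading = c("work location", "work location", "object involved",
                "work location", "occupation", "activity task",
                "occupation", "occupation", "activity task", "occupation",
                "object involved", "object involved", "work location",
                "object involved", "safety/preventative devices",
                "safety/preventative devices", "occupation",
                "object involved", "occupation", "occupation",
                "work location", "occupation", "object involved",
                "work location", "human agency involved",
                "nature of work"),
    w_work = c(8, 8, 8, 10, 2, 8, 4, 4, 8, 4,
               6, 5, 8, 6, 5, 4, 4, 0.5,
               5, 5, 4, 5, 6, 5, 1, 2),
    w_other = c(0.10, 0.12, 0.15, 0.18, 0.03, 0.25, 0.07, 0.12, 0.10, 0.05,
                0.10, 0.30, 0.30, 0.10, 0.05, 0.05, 0.05, 0.01,
                1.50, 1.20, 3.00, 2.50, 3.00, 1.50, 0.40, 0.50),
    stringsAsFactors = FALSE
  )
  structure(list(
    work_terms = wt,
    other_contexts = c(
      "at home", "in the park", "at school", "playing football",
      "riding his bike", "in the garden", "at the beach",
      "on the playground", "at the shops", "during soccer game",
      "on the trampoline", "in the kitchen", "at daycare",
      "during netball", "at a party", "on holiday"
    ),
    injury_phrases = c(
      "cut to hand", "laceration to scalp", "sprained ankle",
      "hurt back lifting box", "fell from ladder", "burn to forearm",
      "blow to head", "crush injury to finger", "foreign body in eye",
      "bruised ribs", "twisted knee", "deep cut to thumb",
      "hit face", "swollen wrist", "puncture wound to foot",
      "laceration to left arm", "injured shoulder", "fractured finger"
    ),
    keyword_phrases = c(
      "at work", "whilst at work", "injured at work",
      "work related injury", "while working", "co-worker dropped box",
      "at workplace", "returning to work"
    ),
    other_keyword_phrases = c(
      "saw that was not working properly",
      "drill stopped working", "machine not working",
      "went to work out at gym", "watching fireworks"
    ),
    negation_phrases = c(
      "and did not work today", "machine not working properly",
      "not work related per patient", "unable to return to work"
    ),
    temporal = c("yesterday", "this morning", "today", "last night",
                 "earlier today", "2 hours ago", "", "", "")
  ), class = "vocabulary_pools")
}

# single-character corruption of one alphabetic character; refuses any edit
# that would create "work" or a work-term stem, so planted detection rates
# are never perturbed by misspellings
.corrupt_word <- function(phrase, forbidden) {
  ch <- strsplit(phrase, "", fixed = TRUE)[[1]]
  alpha <- which(grepl("[a-z]", ch))
  if (!length(alpha)) return(phrase)
  i <- alpha[sample.int(length(alpha), 1L)]
  ch[i] <- sample(letters, 1L)
  out <- paste(ch, collapse = "")
  low <- tolower(out)
  for (f in forbidden) {
    if (grepl(f, low, fixed = TRUE)) return(phrase)
  }
  out
}

.generate_impl <- function(params, vocab) {
  n <- params$n_records
  wt <- vocab$work_terms
  id <- as.character(seq_len(n))
  work <- stats::runif(n) < params$work_prevalence

  kw <- logical(n)
  kw[work] <- stats::runif(sum(work)) < params$p_keyword_given_work
  kw[!work] <- stats::runif(sum(!work)) < params$p_keyword_given_other

  idx <- logical(n)
  grp_wk <- work & kw
  grp_wn <- work & !kw
  grp_ot <- !work
  idx[grp_wk] <- stats::runif(sum(grp_wk)) <
    params$p_index_term_given_work_with_keyword
  idx[grp_wn] <- stats::runif(sum(grp_wn)) <
    params$p_index_term_given_work_no_keyword
  idx[grp_ot] <- stats::runif(sum(grp_ot)) <
    params$p_index_term_given_other

  pick <- integer(n)
  iw <- which(idx & work)
  io <- which(idx & !work)
  if (length(iw)) {
    pick[iw] <- sample.int(nrow(wt), length(iw), replace = TRUE,
                           prob = wt$w_work)
  }
  if (length(io)) {
    pick[io] <- sample.int(nrow(wt), length(io), replace = TRUE,
                           prob = wt$w_other)
  }

  injury <- sample(vocab$injury_phrases, n, replace = TRUE)
  temporal <- sample(vocab$temporal, n, replace = TRUE)

  kwph <- character(n)
  if (any(grp_wk)) {
    kwph[grp_wk] <- sample(vocab$keyword_phrases, sum(grp_wk),
                           replace = TRUE)
  }
  ko <- grp_ot & kw
  if (any(ko)) {
    kwph[ko] <- sample(vocab$other_keyword_phrases, sum(ko), replace = TRUE)
  }

  negph <- character(n)
  neg <- grp_wk & stats::runif(n) < params$negation_rate
  if (any(neg)) {
    negph[neg] <- sample(vocab$negation_phrases, sum(neg), replace = TRUE)
  }

  termph <- character(n)
  if (any(idx)) {
    prefix <- sample(c("at the", "on the", "near the", "operating",
                       "involving", ""),
                     sum(idx), replace = TRUE)
    termph[idx] <- trimws(paste(prefix, wt$term[pick[idx]]))
  }

  ctx <- character(n)
  if (any(grp_ot)) {
    ctx[grp_ot] <- sample(vocab$other_contexts, sum(grp_ot), replace = TRUE)
  }

  # misspellings hit the (never-planted) injury phrase only
  mis <- which(stats::runif(n) < params$misspelling_rate)
  if (length(mis)) {
    forbidden <- unique(c("work", tolower(wt$term)))
    injury[mis] <- vapply(injury[mis], .corrupt_word, character(1),
                          forbidden = forbidden, USE.NAMES = FALSE)
  }

  narrative <- trimws(gsub("  +", " ",
                           paste(injury, kwph, negph, termph, ctx,
                                 temporal)))

  unplanted <- !kw & !idx
  empty <- unplanted & stats::runif(n) < params$empty_text_rate
  narrative[empty] <- ""
  narrative <- substr(narrative, 1L, 255L)

  lab <- ifelse(work, "work", "other")
  if (params$missing_label_count > 0L && n > 0L) {
    blank <- sample.int(n, min(params$missing_label_count, n))
    lab[blank] <- "missing"
  }

  ann_rows <- which(work & !kw & idx & lab == "work")
  annotations <- data.frame(
    record_id = id[ann_rows],
    heading = wt$heading[pick[ann_rows]],
    keyword = wt$term[pick[ann_rows]],
    stringsAsFactors = FALSE
  )

  corpus <- labeled_corpus(id, lab, narrative, provenance = "synthetic")
  list(corpus = corpus, annotations = annotations, params = params)
}

#' Generate a synthetic labelled corpus
#'
#' Assembles each narrative from a template — injury phrase, planted
#' keyword/index/negation phrases per the configured class-conditional
#' rates, activity context and optional temporal tail — and returns the
#' corpus together with a companion annotation table listing the work term
#' planted in each work-labelled, keyword-negative record with its semantic
#' heading (the input a manual review would produce). A fixed seed yields a
#' byte-identical corpus.
#'
#' @param params A [generator_params()].
#' @param vocab A [default_vocabulary()]-shaped list of pools.
#' @return List with elements `corpus` (a [labeled_corpus()]),
#'   `annotations` (data frame: `record_id`, `heading`, `keyword`) and
#'   `params`.
#' @export
generate_corpus <- function(params = generator_params(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(params, "generator_params"))
  withr::with_seed(params$seed, .generate_impl(params, vocab))
}

.WORKED_EXAMPLE_ID <- "worked-example-1"

#' Plant the worked-example narrative
#'
#' Appends the canonical mixed-evidence narrative — went home from work
#' after getting a piece of metal in the eye — as a work-labelled record
#' with the fixed ID `worked-example-1`. The text carries both work evidence
#' (work, metal, eye) and other-activity evidence (home), making it a
#' convenient end-to-end smoke test for concept scoring. Refuses to plant
#' twice (the fixed ID must stay unique).
#'
#' @param corpus A [labeled_corpus()].
#' @return The corpus with one appended record.
#' @export
plant_worked_example <- function(corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (.WORKED_EXAMPLE_ID %in% corpus$record_id) {
    stop("worked example already planted (duplicate ID '",
         .WORKED_EXAMPLE_ID, "')")
  }
  labeled_corpus(
    record_id = c(corpus$record_id, .WORKED_EXAMPLE_ID),
    activity_label = c(corpus$activity_label, "work"),
    narrative = c(corpus$narrative,
                  paste("Went home from work after getting piece of metal",
                        "in eye; eye red and inflamed")),
    provenance = attr(corpus, "provenance")
  )
}
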