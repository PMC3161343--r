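# Tag-supervised concept classifier. An open algorithm with the behavioural
# contract of content analytic text mining engines: frequency-seeded
# concepts, a co-occurrence thesaurus per concept, class associations learnt
# from the coded activity tags, and additive relevance scores per tag. A
# record can be relevant to both tags at once; classification uses the score
# difference. Scores are unnormalized sums, not probabilities — observed
# score differences routinely exceed 1 in magnitude.

.FOUR_WAY_LEVELS <- c("WorkActivity", "ProbableWorkActivity",
                      "ProbableOtherActivity", "OtherActivity")

#' Concept-model parameters
#'
#' @param generality Positive integer: number of co-occurring stems adopted
#'   into each concept's thesaurus (default 10, chosen so extracted concepts
#'   are not too broad).
#' @param max_concepts Cap on the number of seed concepts (default `Inf`,
#'   i.e. the number of concepts to discover is not restricted).
#' @param min_term_frequency Minimum document frequency for a stem to seed a
#'   concept (default 5).
#' @param margin_floor Concepts whose discriminative margin
#'   `|assoc_work - assoc_other|` falls below this floor are dropped: only
#'   concepts more strongly associated with one activity group than the
#'   other are retained (default 0.1).
#' @param smoothing Additive smoothing constant on the per-class record
#'   counts behind the class associations (default 1; prevents degenerate
#'   0/1 associations on small corpora).
#' @param lift_threshold Minimum co-occurrence lift
#'   (`P(member | seed) / P(member)`) for a stem to join a concept's
#'   thesaurus (default 2): members must co-occur with the seed clearly
#'   above their base rate, not merely be globally frequent.
#' @param seed Integer seed recorded with the model (learning itself is
#'   deterministic).
#' @return A list of class `concept_params`.
#' @export
concept_params <- function(generality = 10L, max_concepts = Inf,
                           min_term_frequency = 5L, margin_floor = 0.1,
                           smoothing = 1, lift_threshold = 2, seed = 1L) {
  stopifnot(generality >= 1L, min_term_frequency >= 1L,
            margin_floor >= 0, margin_floor <= 1,
            smoothing > 0, lift_threshold >= 0)
  structure(list(generality = as.integer(generality),
                 max_concepts = max_concepts,
                 min_term_frequency = as.integer(min_term_frequency),
                 margin_floor = margin_floor,
                 smoothing = smoothing,
                 lift_threshold = lift_threshold,
                 seed = as.integer(seed)),
            class = "concept_params")
}

# record x stem presence matrix over unique stems per record
.stem_incidence <- function(stem_sets) {
  lens <- lengths(stem_sets)
  flat <- unlist(stem_sets, use.names = FALSE)
  vocab <- sort(unique(flat))
  if (!length(vocab)) {
    return(list(X = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0),
                                         dims = c(length(stem_sets), 0L)),
                vocab = character(0)))
  }
  X <- Matrix::sparseMatrix(i = rep.int(seq_along(stem_sets), lens),
                            j = match(flat, vocab), x = 1,
                            dims = c(length(stem_sets), length(vocab)),
                            dimnames = list(NULL, vocab))
  list(X = X, vocab = vocab)
}

#' Learn a tag-supervised concept model
#'
#' Seeds one concept per sufficiently frequent stop-listed stem, grows each
#' concept's thesaurus from stems that co-occur with the seed within
#' narratives at well above their base rate, estimates each concept's
#' class association as the smoothed share of seed-containing training
#' records carrying each activity label, drops concepts that do not
#' discriminate the groups, and assigns each surviving concept to the tag it
#' is more strongly associated with. Records with a missing activity label
#' are ignored during learning. Learning is deterministic given the corpus
#' and parameters, and invariant to duplicating every training record.
#'
#' @param corpus A [labeled_corpus()] with at least one record of each
#'   label (errors otherwise: class associations are undefined on a
#'   single-label corpus).
#' @param params A [concept_params()].
#' @param stops A [stoplist()] used for normalization (stored on the model
#'   so scoring uses the identical normalization).
#' @return An object of class `concept_model`.
#' @export
learn_concept_model <- function(corpus, params = concept_params(),
                                stops = default_stoplist()) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            inherits(params, "concept_params"))
  lab <- corpus$activity_label
  use <- lab %in% c("work", "other")
  n_missing <- sum(!use)
  lab <- lab[use]
  if (!any(lab == "work") || !any(lab == "other")) {
    stop("corpus must contain at least one record of each label ",
         "(work and other); class associations are undefined otherwise")
  }
  stem_sets <- lapply(narrative_stems(corpus$narrative[use], stops), unique)
  inc <- .stem_incidence(stem_sets)
  X <- inc$X
  vocab <- inc$vocab
  n <- nrow(X)
  df <- Matrix::colSums(X)

  seeds <- vocab[df >= params$min_term_frequency]
  if (!length(seeds)) {
    stop("no stem reaches min_term_frequency = ", params$min_term_frequency)
  }
  seeds <- seeds[order(-df[seeds], seeds)]
  if (is.finite(params$max_concepts)) {
    seeds <- utils::head(seeds, params$max_concepts)
  }

  C <- Matrix::crossprod(X) # stem x stem joint presence counts
  base_rate <- df / n
  is_work <- lab == "work"
  df_work <- Matrix::colSums(X[is_work, , drop = FALSE])
  s0 <- params$smoothing

  # per-stem smoothed work share, used both for the concept's own class
  # association and to keep thesaurus learning tag-aware
  stem_assoc_work <- (df_work + s0) / (df + 2 * s0)

  concepts <- vector("list", length(seeds))
  kept <- logical(length(seeds))
  for (k in seq_along(seeds)) {
    s <- seeds[k]

    # class association is estimated on the records containing the seed
    # itself — the concept's defining term — not on thesaurus-member
    # matches, whose weaker co-occurrence would dilute the estimate toward
    # the base rate and wash out genuinely discriminative concepts
    n_seed <- as.integer(df[[s]])
    n_work <- as.integer(df_work[[s]])
    assoc_work <- (n_work + s0) / (n_seed + 2 * s0)
    assoc_other <- (n_seed - n_work + s0) / (n_seed + 2 * s0)
    tag <- if (assoc_work >= assoc_other) "work" else "other"

    co <- as.numeric(C[s, ])
    names(co) <- vocab
    co[s] <- 0
    p_member <- co / df[[s]]
    lift <- ifelse(co > 0, p_member / base_rate, 0)
    # a member must co-occur with the seed well above its base rate AND
    # lean toward the concept's own tag: the thesaurus of a work-associated
    # concept is learnt from work-associated terms, not from class-neutral
    # terms that merely share narratives with the seed
    same_lean <- if (tag == "work") stem_assoc_work >= 0.5 else
      stem_assoc_work < 0.5
    cand <- which(co > 0 & lift >= params$lift_threshold & same_lean)
    if (length(cand)) {
      ord <- order(-p_member[cand], vocab[cand])
      cand <- cand[ord][seq_len(min(params$generality, length(cand)))]
    }
    members <- c(1, p_member[cand])
    names(members) <- c(s, vocab[cand])

    margin <- abs(assoc_work - assoc_other)
    kept[k] <- margin >= params$margin_floor
    concepts[[k]] <- list(
      seed = s,
      members = members,
      assoc_work = assoc_work,
      assoc_other = assoc_other,
      tag = tag,
      n_seed = n_seed,
      n_seed_work = n_work
    )
  }
  concepts <- concepts[kept]
  if (!length(concepts)) {
    stop("no concept survives the discriminative-margin floor (",
         params$margin_floor, ")")
  }
  structure(list(
    concepts = concepts,
    params = params,
    stops = stops,
    training_summary = c(work = sum(is_work), other = sum(!is_work),
                         missing = n_missing)
  ), class = "concept_model")
}

#' @export
print.concept_model <- function(x, ...) {
  tags <- vapply(x$concepts, `[[`, character(1), "tag")
  cat("<concept_model> ", length(x$concepts), " concept(s): ",
      sum(tags == "work"), " work-tagged, ", sum(tags == "other"),
      " other-tagged\n", sep = "")
  cat("  trained on ", x$training_summary[["work"]], " work / ",
      x$training_summary[["other"]], " other record(s)",
      if (x$training_summary[["missing"]] > 0)
        paste0(" (", x$training_summary[["missing"]],
               " missing-label ignored)"),
      "\n", sep = "")
  invisible(x)
}

#' Score records against a concept model
#'
#' A concept matches a record when any of its member stems occurs in the
#' record's stop-listed stem stream. Each matched concept contributes its
#' class association times the weight of the best-matching member to the
#' score of the tag it is assigned to. Both scores are zero when nothing
#' matches (e.g. an empty narrative).
#'
#' @param model A `concept_model`.
#' @param corpus A [labeled_corpus()].
#' @return A data frame of class `class_scores` with columns `record_id`,
#'   `score_work`, `score_other`, `diff` (`score_work - score_other`).
#' @export
score_corpus <- function(model, corpus) {
  stopifnot(inherits(model, "concept_model"),
            inherits(corpus, "labeled_corpus"))
  stem_sets <- lapply(narrative_stems(corpus$narrative, model$stops), unique)
  mvocab <- unique(unlist(lapply(model$concepts,
                                 function(co) names(co$members))))
  n <- length(stem_sets)
  lens <- lengths(stem_sets)
  flat <- unlist(stem_sets, use.names = FALSE)
  j <- match(flat, mvocab)
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lens)[keep],
                            j = j[keep], x = 1,
                            dims = c(n, length(mvocab)),
                            dimnames = list(NULL, mvocab))
  score_work <- numeric(n)
  score_other <- numeric(n)
  for (co in model$concepts) {
    wts <- co$members
    ord <- order(-wts, names(wts))
    best <- numeric(n)
    for (k in ord) {
      rows <- which(X[, names(wts)[k]] > 0)
      fresh <- rows[best[rows] == 0]
      best[fresh] <- wts[k]
    }
    if (co$tag == "work") {
      score_work <- score_work + co$assoc_work * best
    } else {
      score_other <- score_other + co$assoc_other * best
    }
  }
  out <- data.frame(record_id = corpus$record_id,
                    score_work = score_work,
                    score_other = score_other,
                    diff = score_work - score_other,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_scores", "data.frame")
  out
}

#' Score a single narrative
#'
#' @param model A `concept_model`.
#' @param narrative A single character string.
#' @return One-row `class_scores` data frame.
#' @export
score_record <- function(model, narrative) {
  stopifnot(length(narrative) == 1L)
  corp <- labeled_corpus("..single..", "missing", narrative,
                         provenance = "score_record")
  score_corpus(model, corp)
}

#' Binary classification from class scores
#'
#' Accepts every record with any positive work-tag relevance — the analogue
#' of accepting all cases assigned the work tag, including cases that also
#' carry the other tag.
#'
#' @param scores A `class_scores` data frame.
#' @return Named logical vector (`TRUE` iff `score_work > 0`).
#' @export
classify_binary <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("record_id", "score_work") %in% names(scores)))
  out <- scores$score_work > 0
  names(out) <- scores$record_id
  out
}

#' Four-way probability classification
#'
#' Rules, applied to `(score_work, score_other)`:
#' 1. work > 0 and other = 0: `WorkActivity`;
#' 2. both > 0 and work >= other: `ProbableWorkActivity` (ties go to the
#'    work side, per the "higher than or equal to" rule);
#' 3. both > 0 and work < other: `ProbableOtherActivity`;
#' 4. other > 0 and work = 0: `OtherActivity`.
#' A record with no evidence at all (0, 0) is classified `OtherActivity`:
#' narratives carrying no information cannot be identified as work-related
#' by any text interrogation approach.
#'
#' @param scores A `class_scores` data frame.
#' @return Named factor with levels `WorkActivity`, `ProbableWorkActivity`,
#'   `ProbableOtherActivity`, `OtherActivity`.
#' @export
classify_four_way <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("record_id", "score_work", "score_other")
                %in% names(scores)))
  w <- scores$score_work
  o <- scores$score_other
  cls <- ifelse(w > 0 & o == 0, "WorkActivity",
         ifelse(w > 0 & o > 0 & w >= o, "ProbableWorkActivity",
         ifelse(w > 0 & o > 0, "ProbableOtherActivity", "OtherActivity")))
  out <- factor(cls, levels = .FOUR_WAY_LEVELS)
  names(out) <- scores$record_id
  out
}

#' Cutoff from group moments
#'
#' The adjusted-classification cutoff is the magnitude of the mean score
#' difference for work-coded records in the target group plus one standard
#' deviation.
#'
#' @param mean_diff Mean score difference.
#' @param sd_diff Standard deviation of the score difference.
#' @return `abs(mean_diff) + sd_diff`.
#' @examples
#' cutoff_from_moments(-0.83, 0.63) # 1.46
#' @export
cutoff_from_moments <- function(mean_diff, sd_diff) {
  stopifnot(is.finite(mean_diff), is.finite(sd_diff), sd_diff >= 0)
  abs(mean_diff) + sd_diff
}

#' Calibrate the adjusted-classification cutoff
#'
#' Over the work-coded records that the four-way rules place in the target
#' group (by default `ProbableOtherActivity`, the group holding the
#' recoverable misses), computes `|mean(diff)| + sd(diff)` using the sample
#' (n-1) standard deviation, and returns the per-label summary used for
#' reporting.
#'
#' @param scores A `class_scores` data frame.
#' @param labels Gold labels aligned with `scores` (character vector in
#'   work/other/missing, or named by `record_id`).
#' @param group Target four-way group (default `"ProbableOtherActivity"`).
#' @return List with elements `cutoff`, `group`, and `summary` (data frame
#'   of n/mean/sd of `diff` per label within the group). Errors when fewer
#'   than two work-coded records fall in the group.
#' @export
calibrate_cutoff <- function(scores, labels,
                             group = "ProbableOtherActivity") {
  stopifnot(group %in% .FOUR_WAY_LEVELS)
  if (!is.null(names(labels))) labels <- labels[scores$record_id]
  stopifnot(length(labels) == nrow(scores))
  cls <- classify_four_way(scores)
  in_group <- as.character(cls) == group
  summ <- do.call(rbind, lapply(c("work", "other"), function(l) {
    d <- scores$diff[in_group & labels == l]
    data.frame(label = l, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) >= 2L) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  dw <- scores$diff[in_group & labels == "work"]
  if (length(dw) < 2L) {
    stop("need at least 2 work-coded records in group '", group,
         "' to calibrate (found ", length(dw), ")")
  }
  sdw <- stats::sd(dw)
  if (length(dw) >= 2L && !is.finite(sdw)) sdw <- 0
  list(cutoff = cutoff_from_moments(mean(dw), sdw),
       group = group, summary = summ)
}

#' Apply the adjusted classification
#'
#' Recodes `ProbableOtherActivity` records whose score-difference magnitude
#' is strictly below the cutoff to `ProbableWorkActivity`; all other classes
#' are untouched. The final binary work flag is `TRUE` for `WorkActivity`
#' and `ProbableWorkActivity`. Raising the cutoff can only recode more
#' records, so the flagged count is monotone in the cutoff.
#'
#' @param classes Four-way factor from [classify_four_way()].
#' @param scores The matching `class_scores` data frame.
#' @param cutoff Positive cutoff on `|diff|`.
#' @return List with `class` (recoded factor), `flag` (named logical map)
#'   and `n_recoded`.
#' @export
apply_adjusted_classification <- function(classes, scores, cutoff) {
  stopifnot(length(classes) == nrow(scores), is.numeric(cutoff),
            length(cutoff) == 1L)
  if (!(cutoff > 0)) stop("cutoff must be positive")
  recode <- as.character(classes) == "ProbableOtherActivity" &
    abs(scores$diff) < cutoff
  newcls <- classes
  newcls[recode] <- "ProbableWorkActivity"
  flag <- as.character(newcls) %in% c("WorkActivity", "ProbableWorkActivity")
  names(flag) <- scores$record_id
  list(class = newcls, flag = flag, n_recoded = sum(recode))
}

#' Pooled-variance two-sample t-test on score differences
#'
#' Compares the score-difference distributions of two groups (e.g. the
#' work-coded and other-coded records within `ProbableOtherActivity`) with a
#' pooled-variance two-sample t-test (df = nA + nB - 2).
#'
#' @param diffs_a,diffs_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
compare_groups_ttest <- function(diffs_a, diffs_b) {
  if (length(diffs_a) < 2L || length(diffs_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  na <- length(diffs_a)
  nb <- length(diffs_b)
  pooled <- ((na - 1) * stats::var(diffs_a) +
             (nb - 1) * stats::var(diffs_b)) / (na + nb - 2)
  if (pooled == 0) stop("zero pooled variance: t statistic undefined")
  tt <- stats::t.test(diffs_a, diffs_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
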