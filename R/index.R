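# Index search: build a curated list of minimal work-related word stems from
# a manually annotated review sample, then flag any narrative containing one
# of the stems. The review sample is drawn from work-coded records that do
# NOT contain the keyword "work", because the index exists precisely to catch
# the work cases the basic keyword search misses.

.heading_vocab <- c(
  "nature of injury", "body site", "activity task",
  "precipitating mechanism", "contributory factor",
  "injury event/exposure", "object involved", "physical force involved",
  "substance involved", "human agency involved", "organism involved",
  "work location", "occupation", "industry", "nature of work",
  "safety/preventative devices"
)

#' The sixteen annotation extraction headings
#'
#' Headings under which a reviewer extracts keywords describing an injury
#' event from a narrative.
#'
#' @return Character vector of the sixteen headings.
#' @export
annotation_headings <- function() .heading_vocab

#' The five headings mined for work-specific index terms
#'
#' Activity, object, location, occupation, and safety/preventative devices —
#' the extraction elements that provide the most work-specific terms.
#'
#' @return Character vector of five headings.
#' @export
default_index_headings <- function() {
  c("activity task", "object involved", "work location", "occupation",
    "safety/preventative devices")
}

#' Read an annotation file
#'
#' Delimited text with columns `record_id`, `heading`, `keyword`. Headings
#' must come from the fixed sixteen-value vocabulary
#' (see [annotation_headings()]).
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return Data frame of annotation rows.
#' @export
read_annotations <- function(path, delim = ",") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = delim, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character", encoding = "UTF-8")
  need <- c("record_id", "heading", "keyword")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ",
         paste(need, collapse = ", "))
  }
  .validate_annotations(df[need])
  df[need]
}

.validate_annotations <- function(annotations) {
  bad <- setdiff(unique(annotations$heading), .heading_vocab)
  if (length(bad)) {
    stop("unknown annotation heading(s): ", paste(bad, collapse = ", "))
  }
  invisible(annotations)
}

# Reduce an extracted keyword to the stem used for substring search.
# Single words: Porter stem, then trimmed back to the longest prefix shared
# with the surface word, so the stem is guaranteed to match its own surface
# form as a substring (Porter maps "factory" to "factori", which never occurs
# in text; the search stem is "factor"). Multi-word phrases are kept verbatim
# (lower case, single internal spaces) because stemming interior words would
# break phrase substring matching.
.search_stem <- function(keyword) {
  w <- gsub("[[:space:]]+", " ", trimws(tolower(keyword)))
  if (!nzchar(w)) return(w)
  if (grepl(" ", w, fixed = TRUE)) return(w)
  s <- porter_stem(w)
  while (nzchar(s) && !startsWith(w, s)) {
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  if (nzchar(s)) s else w
}

#' Build a term index from annotated review-sample keywords
#'
#' Restricts the annotations to the work-specific headings, reduces each
#' extracted keyword to its smallest search stem, merges entries where one
#' stem is a prefix of another (summing frequencies — "weld" covers both
#' "welding" the activity and "welder" the occupation), and drops merged
#' stems recorded fewer than `min_frequency` times, so infrequent terms do
#' not bloat the index. The result is ordered by descending sample frequency.
#' Building is permutation-invariant: shuffling annotation rows cannot
#' change the result.
#'
#' @param annotations Data frame with columns `record_id`, `heading`,
#'   `keyword` (see [read_annotations()]).
#' @param headings_used Headings to keep (default the five work-specific
#'   ones, [default_index_headings()]).
#' @param min_frequency Minimum pooled frequency for an entry to survive
#'   (default 5; terms recorded fewer than five times are excluded).
#' @return An object of class `term_index`: a data frame with columns
#'   `stem`, `frequency`, `headings`. Errors if no annotations remain after
#'   the heading restriction or no stem reaches `min_frequency`.
#' @export
build_index <- function(annotations, headings_used = default_index_headings(),
                        min_frequency = 5L) {
  stopifnot(is.data.frame(annotations),
            all(c("record_id", "heading", "keyword") %in% names(annotations)))
  if (!nrow(annotations)) stop("annotation set is empty")
  .validate_annotations(annotations)
  bad_h <- setdiff(headings_used, .heading_vocab)
  if (length(bad_h)) {
    stop("headings_used contains unknown heading(s): ",
         paste(bad_h, collapse = ", "))
  }
  ann <- annotations[annotations$heading %in% headings_used, , drop = FALSE]
  if (!nrow(ann)) stop("no annotations remain after heading restriction")

  stems <- vapply(ann$keyword, .search_stem, character(1), USE.NAMES = FALSE)
  keep <- nzchar(stems)
  stems <- stems[keep]
  heads <- ann$heading[keep]
  if (!length(stems)) stop("no usable keywords in annotations")

  agg <- stats::aggregate(list(frequency = rep(1L, length(stems))),
                          by = list(stem = stems), FUN = sum)
  head_map <- tapply(heads, stems, function(h) sort(unique(h)),
                     simplify = FALSE)
  agg <- agg[order(nchar(agg$stem), agg$stem), , drop = FALSE]

  # prefix merge: fold each entry into the shortest already-kept entry that
  # is a prefix of it (entries are visited shortest first, so merges chain
  # down to the minimal stem)
  kept_stem <- character(0)
  kept_freq <- integer(0)
  kept_heads <- list()
  for (i in seq_len(nrow(agg))) {
    s <- agg$stem[i]
    hit <- which(vapply(kept_stem, function(k) startsWith(s, k), logical(1)))
    if (length(hit)) {
      j <- hit[1L]
      kept_freq[j] <- kept_freq[j] + agg$frequency[i]
      kept_heads[[j]] <- sort(unique(c(kept_heads[[j]], head_map[[s]])))
    } else {
      kept_stem <- c(kept_stem, s)
      kept_freq <- c(kept_freq, agg$frequency[i])
      kept_heads <- c(kept_heads, list(head_map[[s]]))
    }
  }

  ok <- kept_freq >= min_frequency
  if (!any(ok)) {
    stop("no stem reaches min_frequency = ", min_frequency,
         " (largest pooled frequency: ", max(kept_freq), ")")
  }
  out <- data.frame(
    stem = kept_stem[ok],
    frequency = kept_freq[ok],
    headings = vapply(kept_heads[ok], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_frequency") <- as.integer(min_frequency)
  class(out) <- c("term_index", "data.frame")
  out
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", nrow(x), " stem(s), min_frequency = ",
      attr(x, "min_frequency"), "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Write a term index to a tab-separated file
#'
#' One line per entry: `stem<TAB>frequency<TAB>headings`.
#'
#' @param index A `term_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "term_index"))
  utils::write.table(as.data.frame(index), path, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a term index written by [write_index()]
#'
#' @param path Path to the file.
#' @param min_frequency Threshold recorded on the returned index.
#' @return A `term_index`.
#' @export
read_index <- function(path, min_frequency = 5L) {
  if (!file.exists(path)) stop("index file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          encoding = "UTF-8")
  stopifnot(all(c("stem", "frequency", "headings") %in% names(df)))
  df$stem <- as.character(df$stem)
  df <- df[order(-df$frequency, df$stem), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "min_frequency") <- as.integer(min_frequency)
  class(df) <- c("term_index", "data.frame")
  df
}

#' Default work-term index
#'
#' Contains the seven published high-specificity work terms from the QISU
#' evaluation (job site, factory, labour, forklift, mine, construction,
#' client) with their published sample frequencies, plus terms from this
#' package's synthetic vocabulary with nominal frequencies. The synthetic
#' additions are clearly an artifact of this package: the full 50-term
#' operational index was never published, so users working with real data
#' should build their own via [build_index()].
#'
#' @return A `term_index`.
#' @export
default_index <- function() {
  pub <- data.frame(
    stem = c("job site", "factor", "labour", "forklift", "mine",
             "construct", "client"),
    frequency = c(197L, 152L, 54L, 172L, 1842L, 303L, 165L),
    headings = c("work location", "work location", "occupation",
                 "object involved", "work location", "activity task",
                 "human agency involved"),
    stringsAsFactors = FALSE
  )
  synth <- data.frame(
    stem = c("weld", "scaffold", "crane", "warehous", "grinder",
             "hard hat", "safety harness", "apprentic", "boss",
             "supervisor", "station", "driver", "truck", "offic"),
    frequency = 25L,
    headings = c("activity task", "object involved", "object involved",
                 "work location", "object involved",
                 "safety/preventative devices",
                 "safety/preventative devices", "occupation", "occupation",
                 "occupation", "work location", "occupation",
                 "object involved", "work location"),
    stringsAsFactors = FALSE
  )
  out <- rbind(pub, synth)
  out <- out[order(-out$frequency, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_frequency") <- 5L
  class(out) <- c("term_index", "data.frame")
  out
}

.normalize_for_search <- function(narrative) {
  narrative <- as.character(narrative)
  narrative[is.na(narrative)] <- ""
  gsub("[[:space:]]+", " ", tolower(narrative))
}

#' Flag narratives containing any index stem
#'
#' True where any index stem occurs case-insensitively as a substring of the
#' narrative. Multi-word stems match across single internal spaces
#' (whitespace runs in the narrative are collapsed before matching).
#'
#' @param narrative Character vector of raw narratives.
#' @param index A `term_index` (non-empty).
#' @return Logical vector.
#' @export
index_flag <- function(narrative, index) {
  stopifnot(inherits(index, "term_index"))
  if (!nrow(index)) stop("index is empty")
  txt <- .normalize_for_search(narrative)
  hit <- logical(length(txt))
  for (s in index$stem) {
    hit <- hit | grepl(s, txt, fixed = TRUE)
  }
  hit
}

#' Index-flag every record of a corpus
#'
#' @param corpus A [labeled_corpus()].
#' @param index A `term_index`.
#' @param verbose Report the flagged count with a message?
#' @return Named logical vector (names are `record_id`).
#' @export
index_flag_corpus <- function(corpus, index, verbose = FALSE) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  f <- index_flag(corpus$narrative, index)
  names(f) <- corpus$record_id
  if (verbose) {
    message("index search: flagged ", sum(f), " of ", length(f),
            " record(s)")
  }
  f
}

#' Which index stems match each record
#'
#' Detail output backing [index_flag_corpus()]: the list of matched stems
#' per record.
#'
#' @param corpus A [labeled_corpus()].
#' @param index A `term_index`.
#' @return Named list (by `record_id`) of character vectors of matched stems.
#' @export
index_matches <- function(corpus, index) {
  stopifnot(inherits(corpus, "labeled_corpus"), inherits(index, "term_index"))
  if (!nrow(index)) stop("index is empty")
  txt <- .normalize_for_search(corpus$narrative)
  hits <- matrix(FALSE, nrow = length(txt), ncol = nrow(index))
  for (k in seq_len(nrow(index))) {
    hits[, k] <- grepl(index$stem[k], txt, fixed = TRUE)
  }
  out <- apply(hits, 1L, function(r) index$stem[r], simplify = FALSE)
  names(out) <- corpus$record_id
  out
}

#' Combine keyword and index flags by logical OR
#'
#' @param keyword_flags Named logical vector from [keyword_flag_corpus()].
#' @param index_flags Named logical vector from [index_flag_corpus()].
#'   Must cover exactly the same record IDs.
#' @return Named logical vector: per-record OR, in the order of
#'   `keyword_flags`.
#' @export
union_flag <- function(keyword_flags, index_flags) {
  ka <- names(keyword_flags)
  kb <- names(index_flags)
  if (is.null(ka) || is.null(kb)) stop("flag vectors must be named")
  sym <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(sym)) {
    stop("flag sets cover different record IDs; symmetric difference: ",
         paste(utils::head(sym, 5L), collapse = ", "),
         if (length(sym) > 5L) " ..." else "")
  }
  out <- keyword_flags | index_flags[ka]
  names(out) <- ka
  out
}

#' Draw the manual-review sample
#'
#' A random sample (without replacement) of work-coded records whose
#' narrative does not contain the keyword — the cases a keyword search
#' misses and the index is built to recover. Deterministic for a given seed.
#'
#' @param corpus A [labeled_corpus()].
#' @param keyword_flags Named logical vector from [keyword_flag_corpus()].
#' @param n Sample size (default 1000, large enough to harvest a broad term
#'   set while staying reviewable by hand).
#' @param seed Integer RNG seed.
#' @return A [labeled_corpus()] of exactly `n` records. Errors when fewer
#'   than `n` records are eligible, reporting the eligible count.
#' @export
select_review_sample <- function(corpus, keyword_flags, n = 1000L, seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  miss <- setdiff(corpus$record_id, names(keyword_flags))
  if (length(miss)) {
    stop("keyword_flags missing ", length(miss), " record_id(s)")
  }
  f <- keyword_flags[corpus$record_id]
  eligible <- which(corpus$activity_label == "work" & !f)
  if (length(eligible) < n) {
    stop("only ", length(eligible), " eligible record(s) but n = ", n)
  }
  idx <- if (n == 0L) integer(0) else
    withr::with_seed(seed, sort(sample(eligible, n)))
  .subset_corpus(corpus, idx)
}
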