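# Basic keyword search: flag any narrative containing "work" (or another
# pattern) as a case-insensitive substring of the raw text. Substring — not
# token — matching is deliberate, so "worker", "work-related" and compounds
# all match; and negation phrases such as "not working" do NOT rule a case
# out, because those phrases occur inside genuinely work-related narratives
# ("injured hand on saw that was not working properly").

#' Flag narratives containing a keyword
#'
#' @param narrative Character vector of raw narratives.
#' @param pattern Keyword to match as a case-insensitive substring
#'   (default `"work"`). Must be a single non-empty string; it is folded to
#'   lower case.
#' @return Logical vector, `TRUE` where the pattern occurs. Matching runs on
#'   the case-folded raw narrative, not a tokenized form, so punctuation and
#'   hyphens cannot block a match. Appending text to a flagged narrative can
#'   never unflag it.
#' @examples
#' keyword_flag("injured hand on saw that was not working properly")
#' keyword_flag("co-worker dropped box on foot")
#' @export
keyword_flag <- function(narrative, pattern = "work") {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  pattern <- tolower(pattern)
  narrative <- as.character(narrative)
  narrative[is.na(narrative)] <- ""
  grepl(pattern, tolower(narrative), fixed = TRUE)
}

#' Keyword-flag every record of a corpus
#'
#' @param corpus A [labeled_corpus()].
#' @param pattern Keyword substring, as in [keyword_flag()].
#' @param verbose Report the flagged count with a message?
#' @return Named logical vector (names are `record_id`).
#' @export
keyword_flag_corpus <- function(corpus, pattern = "work", verbose = FALSE) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  f <- keyword_flag(corpus$narrative, pattern)
  names(f) <- corpus$record_id
  if (verbose) {
    message("keyword '", pattern, "': flagged ", sum(f), " of ", length(f),
            " record(s)")
  }
  f
}
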