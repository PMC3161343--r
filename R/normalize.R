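# Shared text normalization: tokenization, stop-list handling, and the
# per-narrative stem streams consumed by the concept classifier. Each
# narrative is treated as one undivided context block: there is no sentence
# segmentation anywhere in the package, because triage narratives are not
# grammatical prose.

#' Tokenize free text
#'
#' Splits each text on any run of non-alphanumeric characters and folds case.
#' Hyphenated compounds therefore yield their parts ("work-related" gives
#' "work" and "related"); classifiers that need the joined form match on the
#' raw narrative instead (see [keyword_flag()]). Numerals are kept as tokens.
#' Total over any input: `NA` and empty strings give empty token vectors.
#'
#' @param text Character vector of narratives.
#' @return List of character vectors, one per input text.
#' @examples
#' tokenize("Hurt back at work yesterday")
#' @export
tokenize <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  parts <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(parts, function(p) p[nzchar(p)])
}

#' Token stream for a single narrative
#'
#' Pairs the tokens of one narrative with their Porter stems.
#'
#' @param text A single character string.
#' @return An object of class `token_stream`: a list with parallel character
#'   vectors `tokens` and `stems`.
#' @examples
#' token_stream("work-related eye injury")
#' @export
token_stream <- function(text) {
  stopifnot(length(text) == 1L)
  tk <- tokenize(text)[[1]]
  structure(list(tokens = tk, stems = porter_stem(tk)),
            class = "token_stream")
}

#' @export
print.token_stream <- function(x, ...) {
  cat("<token_stream> ", length(x$tokens), " token(s)\n", sep = "")
  if (length(x$tokens)) {
    print(data.frame(token = x$tokens, stem = x$stems))
  }
  invisible(x)
}

#' Construct a stop-list
#'
#' A stop-list is the set of high-frequency, semantically light words excluded
#' from concept learning. Entries are stemmed on construction so that any
#' grammatical variant is excluded. Words on the retained-override list are
#' exempt from exclusion no matter what: the shipped default override list
#' keeps words that can refer to body parts (back, face, feet), injury
#' mechanisms (cut) or injurious objects (saw), which ordinary English
#' stop-lists would throw away but which carry real signal in injury text.
#'
#' @param exclude Character vector of words/stems to exclude.
#' @param retain Character vector of words/stems exempt from exclusion.
#' @return An object of class `stoplist` with elements `excluded` and
#'   `retained` (disjoint stem sets).
#' @export
stoplist <- function(exclude, retain = character()) {
  ex <- unique(porter_stem(trimws(tolower(as.character(exclude)))))
  re <- unique(porter_stem(trimws(tolower(as.character(retain)))))
  ex <- setdiff(ex[nzchar(ex)], re)
  structure(list(excluded = ex, retained = re[nzchar(re)]),
            class = "stoplist")
}

#' @export
print.stoplist <- function(x, ...) {
  cat("<stoplist> ", length(x$excluded), " excluded stems, ",
      length(x$retained), " retained overrides\n", sep = "")
  invisible(x)
}

#' Read a stop-list word file
#'
#' One entry per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path Path to the file.
#' @return Character vector of entries.
#' @export
read_stoplist_file <- function(path) {
  if (!file.exists(path)) stop("stop-list file not found: ", path)
  ln <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln[nzchar(ln)]
}

#' Load a stop-list from files
#'
#' @param exclude_path Path to the exclusion list.
#' @param retain_path Optional path to the retained-override list.
#' @return A [stoplist()] object.
#' @export
load_stoplist <- function(exclude_path, retain_path = NULL) {
  retain <- if (is.null(retain_path)) character() else
    read_stoplist_file(retain_path)
  stoplist(read_stoplist_file(exclude_path), retain)
}

.worknarr_env <- new.env(parent = emptyenv())

#' Default stop-list shipped with the package
#'
#' A standard English stop-list minus an override list of body parts, injury
#' mechanisms and injurious objects. The override list is a design artifact
#' of this package (the categories are standard in injury surveillance, the
#' exact membership is ours); both files are plain text under
#' `inst/extdata/` and can be replaced via [load_stoplist()].
#'
#' @return A [stoplist()] object (cached per session).
#' @export
default_stoplist <- function() {
  if (is.null(.worknarr_env$default_stoplist)) {
    .worknarr_env$default_stoplist <- load_stoplist(
      system.file("extdata", "stopwords_en.txt", package = "worknarr",
                  mustWork = TRUE),
      system.file("extdata", "stopwords_retained.txt", package = "worknarr",
                  mustWork = TRUE)
    )
  }
  .worknarr_env$default_stoplist
}

#' Apply a stop-list to a token stream
#'
#' Removes tokens whose stems are excluded; order of survivors is preserved.
#'
#' @param stream A [token_stream()].
#' @param stops A [stoplist()].
#' @return A filtered `token_stream`.
#' @examples
#' apply_stoplist(token_stream("the saw cut his back"), default_stoplist())
#' @export
apply_stoplist <- function(stream, stops = default_stoplist()) {
  stopifnot(inherits(stream, "token_stream"), inherits(stops, "stoplist"))
  keep <- !(stream$stems %in% stops$excluded)
  structure(list(tokens = stream$tokens[keep], stems = stream$stems[keep]),
            class = "token_stream")
}

#' Stop-listed stem streams for a vector of narratives
#'
#' Vectorized normalization used by the concept classifier: tokenize, stem,
#' drop stop-listed stems. Duplicate stems within a narrative are kept (the
#' caller decides whether presence or multiplicity matters).
#'
#' @param texts Character vector of narratives.
#' @param stops A [stoplist()].
#' @return List of character stem vectors, one per narrative.
#' @export
narrative_stems <- function(texts, stops = default_stoplist()) {
  toks <- tokenize(texts)
  lens <- lengths(toks)
  if (sum(lens) == 0L) {
    return(rep(list(character()), length(texts)))
  }
  flat <- unlist(toks, use.names = FALSE)
  st <- porter_stem(flat)
  id <- rep.int(seq_along(texts), lens)
  keep <- !(st %in% stops$excluded)
  out <- split(st[keep], factor(id[keep], levels = seq_along(texts)))
  names(out) <- NULL
  out
}
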