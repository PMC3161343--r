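# Labelled narrative corpora: reading, validation, and prediction output.
# The exchange format is a three-column delimited file — record ID, binary
# activity label (1/work = working for an income, 0/other = any other
# activity, anything else = missing), and the free-text injury description
# (at most 255 characters, the length of the triage narrative field).

.parse_activity_label <- function(x) {
  v <- trimws(tolower(as.character(x)))
  out <- rep("missing", length(v))
  out[v %in% c("1", "work")] <- "work"
  out[v %in% c("0", "other")] <- "other"
  out
}

.label_to_code <- function(lab) {
  c(work = "1", other = "0", missing = "")[lab]
}

#' Construct a labelled narrative corpus
#'
#' @param record_id Character vector of unique record identifiers.
#' @param activity_label Character vector in `{"work", "other", "missing"}`.
#' @param narrative Character vector of injury descriptions (`NA` becomes
#'   the empty string; text longer than `max_chars` is truncated with a
#'   warning).
#' @param provenance Free-text source tag.
#' @param max_chars Maximum narrative length (default 255, the triage field
#'   width).
#' @return An object of class `labeled_corpus` (a data frame with columns
#'   `record_id`, `activity_label`, `narrative` and a `provenance`
#'   attribute). Iteration order is construction order.
#' @export
labeled_corpus <- function(record_id, activity_label, narrative,
                           provenance = "unspecified", max_chars = 255L) {
  record_id <- as.character(record_id)
  activity_label <- as.character(activity_label)
  narrative <- as.character(narrative)
  n <- length(record_id)
  stopifnot(length(activity_label) == n, length(narrative) == n)
  if (anyNA(record_id) || !all(nzchar(record_id))) {
    stop("record_id must be non-missing and non-empty")
  }
  if (anyDuplicated(record_id)) {
    dup <- unique(record_id[duplicated(record_id)])
    stop("duplicate record_id values: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad <- !(activity_label %in% c("work", "other", "missing"))
  if (any(bad)) {
    stop("activity_label must be one of work/other/missing")
  }
  narrative[is.na(narrative)] <- ""
  too_long <- nchar(narrative) > max_chars
  if (any(too_long)) {
    warning(sum(too_long), " narrative(s) longer than ", max_chars,
            " characters were truncated")
    narrative[too_long] <- substr(narrative[too_long], 1L, max_chars)
  }
  out <- data.frame(record_id = record_id,
                    activity_label = activity_label,
                    narrative = narrative,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("labeled_corpus", "data.frame")
  out
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus> ", nrow(x), " record(s); source: ",
      attr(x, "provenance"), "\n", sep = "")
  tab <- table(factor(x$activity_label,
                      levels = c("work", "other", "missing")))
  cat("  labels: work ", tab[["work"]], ", other ", tab[["other"]],
      ", missing ", tab[["missing"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.labeled_corpus <- function(object, ...) {
  list(n = nrow(object),
       labels = table(factor(object$activity_label,
                             levels = c("work", "other", "missing"))),
       n_empty_narrative = sum(!nzchar(object$narrative)),
       provenance = attr(object, "provenance"))
}

.subset_corpus <- function(corpus, idx) {
  out <- as.data.frame(corpus)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(corpus, "provenance")
  class(out) <- c("labeled_corpus", "data.frame")
  out
}

#' Read a labelled narrative corpus from a delimited file
#'
#' Expects three columns in order: record ID, activity label, narrative.
#' Labels `1`/`work` map to work and `0`/`other` to other
#' (case-insensitive); any other value — including blanks — maps to missing.
#' Missing-label rows are retained on load; they are excluded (and counted)
#' only at evaluation time. No row is ever dropped by the loader.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default comma; use `"\t"` for TSV).
#' @param header Does the file carry a header row?
#' @param quote Quote character for fields containing the delimiter.
#' @param max_chars Narrative truncation limit (default 255).
#' @param provenance Source tag recorded on the corpus (defaults to `path`).
#' @return A [labeled_corpus()].
#' @export
read_corpus <- function(path, delim = ",", header = TRUE, quote = "\"",
                        max_chars = 255L, provenance = path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  nf <- utils::count.fields(path, sep = delim, quote = quote,
                            comment.char = "", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  bad <- which(nf != 3L)
  if (length(bad)) {
    stop("expected 3 columns but found ", nf[bad[1]], " on row ", bad[1],
         if (length(bad) > 1L) paste0(" (and ", length(bad) - 1L,
                                      " more row(s))") else "")
  }
  df <- utils::read.table(path, sep = delim, quote = quote, header = header,
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE, fill = FALSE,
                          na.strings = character(),
                          encoding = "UTF-8")
  if (ncol(df) != 3L) stop("expected 3 columns, found ", ncol(df))
  labeled_corpus(record_id = df[[1L]],
                 activity_label = .parse_activity_label(df[[2L]]),
                 narrative = df[[3L]],
                 provenance = provenance,
                 max_chars = max_chars)
}

#' Write a labelled corpus back to a delimited file
#'
#' Labels are written in the binary source coding (1 = work, 0 = other,
#' blank = missing); fields containing the delimiter are quoted, so
#' `read_corpus(write_corpus(x))` round-trips IDs, labels and narratives.
#'
#' @param corpus A [labeled_corpus()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, delim = ",") {
  stopifnot(inherits(corpus, "labeled_corpus"))
  df <- data.frame(record_id = corpus$record_id,
                   activity_code = unname(.label_to_code(corpus$activity_label)),
                   narrative = corpus$narrative,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write per-record method outputs next to the gold label
#'
#' One row per record: ID, gold label, and one column per supplied flag or
#' score vector. Every flag vector must cover every record ID.
#'
#' @param corpus A [labeled_corpus()].
#' @param flags Named list of vectors (logical or numeric), each named by
#'   `record_id`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(corpus, flags, path, delim = ",") {
  stopifnot(inherits(corpus, "labeled_corpus"), is.list(flags))
  if (is.null(names(flags)) || !all(nzchar(names(flags)))) {
    stop("flags must be a named list of per-record vectors")
  }
  out <- data.frame(record_id = corpus$record_id,
                    activity_label = corpus$activity_label,
                    stringsAsFactors = FALSE)
  for (nm in names(flags)) {
    v <- flags[[nm]]
    missing_ids <- setdiff(corpus$record_id, names(v))
    if (length(missing_ids)) {
      stop("flag set '", nm, "' is missing ", length(missing_ids),
           " record_id(s): ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    out[[nm]] <- unname(v[corpus$record_id])
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return A data frame with `record_id`, `activity_label` and one column
#'   per method.
#' @export
read_predictions <- function(path, delim = ",") {
  if (!file.exists(path)) stop("predictions file not found: ", path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", encoding = "UTF-8")
  df$record_id <- as.character(df$record_id)
  df
}
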