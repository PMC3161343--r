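# Evaluation against the coded activity label: confusion counts,
# sensitivity, specificity, positive predictive value, and cross-method
# overlap counts. The coded activity label is the measurement standard;
# records with a missing label are excluded from evaluation and counted.

#' Sensitivity, specificity and PPV from confusion counts
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `ppv = tp/(tp+fp)`. A ratio with a zero denominator is reported as `NA`
#' (with a message), never silently as zero.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return Named numeric vector `c(sensitivity, specificity, ppv)` at full
#'   precision.
#' @examples
#' metrics_from_counts(12457, 1916, 8962, 184946)
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  cts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!all(is.finite(cts)) || any(cts < 0) || any(cts != round(cts))) {
    stop("counts must be non-negative whole numbers")
  }
  ratio <- function(num, den, what) {
    if (den == 0) {
      message(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    ppv = ratio(tp, tp + fp, "ppv"))
}

#' Evaluate a flag map against the coded activity label
#'
#' Cross-tabulates the per-record flags with the gold label over records
#' carrying a work/other label; missing-label records are excluded and
#' counted in `n_excluded_missing`, so
#' `tp + fp + fn + tn + n_excluded_missing` equals the corpus size.
#'
#' @param flags Named logical vector covering every `record_id` (errors
#'   otherwise, listing the missing IDs).
#' @param corpus A [labeled_corpus()].
#' @return Object of class `eval_result`: a list with the four confusion
#'   counts, `n_excluded_missing`, and `sensitivity`/`specificity`/`ppv`.
#' @export
evaluate_flags <- function(flags, corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (is.null(names(flags))) stop("flags must be named by record_id")
  miss <- setdiff(corpus$record_id, names(flags))
  if (length(miss)) {
    stop("flags missing ", length(miss), " record_id(s): ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) " ..." else "")
  }
  f <- as.logical(flags[corpus$record_id])
  lab <- corpus$activity_label
  labelled <- lab %in% c("work", "other")
  gold <- lab[labelled] == "work"
  fl <- f[labelled]
  tp <- sum(fl & gold)
  fp <- sum(fl & !gold)
  fn <- sum(!fl & gold)
  tn <- sum(!fl & !gold)
  m <- suppressMessages(metrics_from_counts(tp, fp, fn, tn))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_excluded_missing = sum(!labelled),
                 sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 ppv = m[["ppv"]]),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, digits = 3L, ...) {
  cat("<eval_result>\n")
  cat("  counts: tp ", x$tp, ", fp ", x$fp, ", fn ", x$fn, ", tn ", x$tn,
      " (", x$n_excluded_missing, " missing-label excluded)\n", sep = "")
  cat("  sensitivity ", round(x$sensitivity, digits),
      ", specificity ", round(x$specificity, digits),
      ", PPV ", round(x$ppv, digits), "\n", sep = "")
  invisible(x)
}

#' Overlap (Venn) region counts for several flag sets and the gold set
#'
#' Partitions the labelled records by membership in each flag set and in the
#' gold work-coded set, and counts every region (including the
#' all-negative one), so the counts sum to the number of labelled records.
#'
#' @param flag_sets Named list (>= 2 entries) of named logical vectors over
#'   a common record-ID domain (errors on domain mismatch).
#' @param corpus A [labeled_corpus()]; missing-label records are excluded.
#' @return Data frame with one logical membership column per set, a
#'   `work_code` column for the gold set, and a `count` column.
#' @export
overlap_counts <- function(flag_sets, corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"), is.list(flag_sets),
            length(flag_sets) >= 2L)
  if (is.null(names(flag_sets)) || !all(nzchar(names(flag_sets)))) {
    stop("flag_sets must be a named list")
  }
  ids <- corpus$record_id
  for (nm in names(flag_sets)) {
    sym <- c(setdiff(ids, names(flag_sets[[nm]])),
             setdiff(names(flag_sets[[nm]]), ids))
    if (length(sym)) {
      stop("flag set '", nm, "' does not cover the corpus IDs; ",
           "symmetric difference has ", length(sym), " ID(s)")
    }
  }
  labelled <- corpus$activity_label %in% c("work", "other")
  ids <- ids[labelled]
  M <- vapply(flag_sets, function(v) as.logical(v[ids]),
              logical(length(ids)))
  M <- cbind(M, work_code = corpus$activity_label[labelled] == "work")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), ncol(M)))
  names(combos) <- colnames(M)
  pat <- apply(M, 1L, paste, collapse = ".")
  cpat <- apply(combos, 1L, paste, collapse = ".")
  tab <- table(factor(pat, levels = cpat))
  combos$count <- as.integer(tab)
  combos
}

#' Summary evaluation report over several methods
#'
#' One row per method: confusion counts plus the three metrics, the layout
#' used for reporting case-identification results.
#'
#' @param flag_list Named list of flag maps (named logical vectors).
#' @param corpus A [labeled_corpus()].
#' @return Data frame with columns `method`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
evaluation_report <- function(flag_list, corpus) {
  stopifnot(is.list(flag_list), length(flag_list) >= 1L,
            !is.null(names(flag_list)))
  rows <- lapply(names(flag_list), function(nm) {
    e <- evaluate_flags(flag_list[[nm]], corpus)
    data.frame(method = nm, tp = e$tp, fp = e$fp, fn = e$fn, tn = e$tn,
               sensitivity = e$sensitivity, specificity = e$specificity,
               ppv = e$ppv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published reference confusion counts
#'
#' Confusion counts reported for each text-interrogation method in the
#' published QISU 2002-2007 evaluation (208,281 labelled emergency
#' department presentations, 21,419 work-coded), against the triage-assigned
#' activity code. Useful for recomputing the published sensitivity,
#' specificity and PPV figures via [metrics_from_counts()].
#'
#' @return Data frame with columns `method`, `tp`, `fp`, `fn`, `tn`.
#' @export
reference_counts <- function() {
  data.frame(
    method = c("keyword", "index", "keyword_or_index",
               "concept_binary", "concept_adjusted"),
    tp = c(12457L, 13252L, 17004L, 17299L, 16424L),
    fp = c(1916L, 23434L, 24416L, 13894L, 8699L),
    fn = c(8962L, 8167L, 4415L, 4120L, 4995L),
    tn = c(184946L, 163428L, 162446L, 172968L, 178163L),
    stringsAsFactors = FALSE
  )
}
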