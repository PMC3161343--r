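# End-to-end pipeline: simulate (or load) a corpus, run the three
# interrogation approaches, evaluate all five classification techniques
# against the coded activity label, and write the report files.

#' Pipeline configuration
#'
#' Defaults follow the study design: review sample of 1000, index frequency
#' threshold 5, concept generality 10, automatic cutoff calibration.
#'
#' @param out_dir Output directory for report files (created if absent);
#'   `NULL` suppresses all file output.
#' @param corpus_path Optional path to a corpus file; `NULL` simulates one.
#' @param annotations_path Optional path to an annotation file (required
#'   when `corpus_path` is given and the index stage runs).
#' @param n_records Records to simulate when no corpus file is given.
#' @param seed Master seed; stage seeds are derived from it.
#' @param generator [generator_params()] used when simulating (its
#'   `n_records`/`seed` are taken from the arguments above).
#' @param keyword_pattern Keyword for the basic search.
#' @param n_review Manual-review sample size (default 1000).
#' @param min_frequency Index frequency threshold (default 5).
#' @param headings_used Annotation headings mined for the index.
#' @param concept [concept_params()] for the concept classifier.
#' @param cutoff `"auto"` (calibrate from the ProbableOtherActivity group)
#'   or a positive number.
#' @param verbose Emit progress messages?
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = NULL,
                       corpus_path = NULL,
                       annotations_path = NULL,
                       n_records = 200000L,
                       seed = 1L,
                       generator = NULL,
                       keyword_pattern = "work",
                       n_review = 1000L,
                       min_frequency = 5L,
                       headings_used = default_index_headings(),
                       concept = concept_params(),
                       cutoff = "auto",
                       verbose = FALSE) {
  if (is.null(generator)) {
    generator <- generator_params(n_records = n_records, seed = seed)
  }
  if (!identical(cutoff, "auto")) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  }
  structure(list(out_dir = out_dir, corpus_path = corpus_path,
                 annotations_path = annotations_path,
                 n_records = as.integer(n_records), seed = as.integer(seed),
                 generator = generator, keyword_pattern = keyword_pattern,
                 n_review = as.integer(n_review),
                 min_frequency = as.integer(min_frequency),
                 headings_used = headings_used, concept = concept,
                 cutoff = cutoff, verbose = verbose),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full interrogation pipeline
#'
#' Stages: obtain corpus (simulate or load), keyword search, review-sample
#' draw and index construction, index and union flags, concept model
#' (learn, score, binary and four-way classification, cutoff calibration,
#' adjusted classification), evaluation of all five techniques, and overlap
#' counts of the union text search, the adjusted concept classification and
#' the work activity code. With `out_dir` set, writes `flags.csv`,
#' `report.csv` (one row per technique), `overlap.csv`, `index.tsv` and
#' `run_log.txt`; the log records seeds, parameters and exclusion counts,
#' enough to reproduce every report byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the corpus, flags, scores, cutoff
#'   calibration, report, and overlap table.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- if (config$verbose) message else function(...) invisible(NULL)

  if (is.null(config$corpus_path)) {
    say("simulating ", config$n_records, " records (seed ", config$seed, ")")
    sim <- .stage("simulate", generate_corpus(config$generator))
    corpus <- sim$corpus
    annotations <- sim$annotations
  } else {
    say("reading corpus from ", config$corpus_path)
    corpus <- .stage("read", read_corpus(config$corpus_path))
    if (is.null(config$annotations_path)) {
      stop("pipeline stage 'read' failed: annotations_path is required ",
           "when corpus_path is given", call. = FALSE)
    }
    annotations <- .stage("read", read_annotations(config$annotations_path))
  }

  say("keyword search")
  kw <- .stage("keyword",
               keyword_flag_corpus(corpus, config$keyword_pattern))

  say("index construction (review sample n = ", config$n_review, ")")
  idx_obj <- .stage("index", {
    smp <- select_review_sample(corpus, kw, n = config$n_review,
                                seed = config$seed + 1L)
    ann <- annotations[annotations$record_id %in% smp$record_id, ,
                       drop = FALSE]
    build_index(ann, headings_used = config$headings_used,
                min_frequency = config$min_frequency)
  })
  ix <- .stage("index", index_flag_corpus(corpus, idx_obj))
  un <- .stage("union", union_flag(kw, ix))

  say("concept classifier")
  model <- .stage("concept", learn_concept_model(corpus, config$concept))
  scores <- .stage("concept", score_corpus(model, corpus))
  binary <- classify_binary(scores)
  four <- classify_four_way(scores)
  gold <- stats::setNames(corpus$activity_label, corpus$record_id)
  calib <- if (identical(config$cutoff, "auto")) {
    .stage("calibrate", calibrate_cutoff(scores, gold))
  } else {
    list(cutoff = config$cutoff, group = "ProbableOtherActivity",
         summary = NULL)
  }
  adj <- .stage("adjust",
                apply_adjusted_classification(four, scores, calib$cutoff))

  say("evaluation")
  flags <- list(keyword = kw, index = ix, keyword_or_index = un,
                concept_binary = binary, concept_adjusted = adj$flag)
  report <- .stage("evaluate", evaluation_report(flags, corpus))
  overlap <- .stage("overlap", overlap_counts(
    list(text_search = un, concept_adjusted = adj$flag), corpus))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_predictions(corpus, flags, p("flags.csv"))
    utils::write.csv(report, p("report.csv"), row.names = FALSE)
    utils::write.csv(overlap, p("overlap.csv"), row.names = FALSE)
    write_index(idx_obj, p("index.tsv"))
    n_missing <- sum(corpus$activity_label == "missing")
    log_lines <- c(
      paste0("seed: ", config$seed),
      paste0("corpus: ", if (is.null(config$corpus_path)) "simulated"
             else config$corpus_path),
      paste0("n_records: ", nrow(corpus)),
      paste0("n_missing_label_excluded_from_evaluation: ", n_missing),
      paste0("keyword_pattern: ", config$keyword_pattern),
      paste0("n_review: ", config$n_review),
      paste0("index_min_frequency: ", config$min_frequency),
      paste0("index_terms: ", nrow(idx_obj)),
      paste0("concept_generality: ", config$concept$generality),
      paste0("concept_min_term_frequency: ",
             config$concept$min_term_frequency),
      paste0("concept_margin_floor: ", config$concept$margin_floor),
      paste0("concepts_learned: ", length(model$concepts)),
      paste0("cutoff_mode: ", if (identical(config$cutoff, "auto"))
        "auto" else "fixed"),
      paste0("cutoff: ", format(calib$cutoff, digits = 10)),
      paste0("n_recoded: ", adj$n_recoded)
    )
    writeLines(log_lines, p("run_log.txt"))
  }

  invisible(list(corpus = corpus, annotations = annotations,
                 index = idx_obj, model = model, scores = scores,
                 flags = flags, four_way = four, calibration = calib,
                 n_recoded = adj$n_recoded, report = report,
                 overlap = overlap))
}
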