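#!/usr/bin/env Rscript
# Stage 4 — tag-supervised concept classifier.
#
# Learns concepts (generality 10, unrestricted concept count) from the
# coded activity tags, scores every record for the work and other tags,
# classifies by the binary and four-way probability rules, calibrates the
# adjusted cutoff as |mean| + SD of the score difference for work-coded
# records in the probable-other group, and applies the adjusted
# classification.

library(worknarr)

out_dir <- "results/analysis"
corpus <- read_corpus(file.path(out_dir, "corpus.csv"))

model <- learn_concept_model(corpus, concept_params())
print(model)

scores <- score_corpus(model, corpus)
binary <- classify_binary(scores)
four <- classify_four_way(scores)
print(table(four))

gold <- stats::setNames(corpus$activity_label, corpus$record_id)
cal <- calibrate_cutoff(scores, gold)
cat("probable-other group score differences by activity code:\n")
print(cal$summary, digits = 4)
cat("calibrated cutoff (|mean| + SD, work-coded):",
    round(cal$cutoff, 3), "\n")

po <- as.character(four) == "ProbableOtherActivity"
tt <- compare_groups_ttest(scores$diff[po & gold == "work"],
                           scores$diff[po & gold == "other"])
cat(sprintf("pooled t-test, work vs other within probable-other: t(%d) = %.2f, p %s\n",
            tt$df, tt$t, format.pval(tt$p, digits = 2)))

adj <- apply_adjusted_classification(four, scores, cal$cutoff)
cat("recoded", adj$n_recoded,
    "probable-other records to probable-work under the cutoff\n")

write_predictions(corpus,
                  list(concept_binary = binary,
                       concept_adjusted = adj$flag,
                       score_work = stats::setNames(scores$score_work,
                                                    scores$record_id),
                       score_other = stats::setNames(scores$score_other,
                                                     scores$record_id)),
                  file.path(out_dir, "concept_flags.csv"))
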