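#!/usr/bin/env Rscript
# Stage 2 — basic keyword search.
#
# Flags every narrative containing "work" as a case-insensitive substring
# (so worker / work-related / workplace all match, and negation phrases do
# not exclude). Evaluates against the coded activity label and writes the
# flags for the later union stage.

library(worknarr)

out_dir <- "results/analysis"
corpus <- read_corpus(file.path(out_dir, "corpus.csv"))

kw <- keyword_flag_corpus(corpus, verbose = TRUE)
ev <- evaluate_flags(kw, corpus)
print(ev)

write_predictions(corpus, list(keyword = kw),
                  file.path(out_dir, "keyword_flags.csv"))
cat("keyword search: high specificity but misses",
    round(100 * (1 - ev$sensitivity)), "% of work-coded cases;",
    "suitable for harvesting a clean sample, not for incidence counts\n")
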