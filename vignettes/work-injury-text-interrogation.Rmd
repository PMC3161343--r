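---
title: "Interrogating triage narratives for work-related injury: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrogating triage narratives for work-related injury: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worknarr)
```

## The problem

Emergency-department injury surveillance systems code the patient's
activity at the time of injury; "working for an income" is the category
that makes occupational-injury surveillance possible. Most routine ED data
carry no such code — only a free-text injury description of at most 255
characters written by the triage nurse. `worknarr` implements three ways of
interrogating that text to flag *potentially* work-related cases, and an
evaluation layer that measures each against a coded activity label treated
as the standard. "Potentially" is doing real work in that sentence: the
design goal is case *ascertainment*, so the presence of target
words/phrases/concepts is sufficient to flag, and negation phrases ("not
working", "not work-related") never rule a case out — they occur inside
genuinely work-related narratives.

## Text normalization

All classifiers share one deterministic normalization:

* **Tokenization** splits on any non-alphanumeric run and folds case.
  Numerals are kept (ages and times can discriminate, and dropping them
  loses information for no gain).
* Each narrative is one undivided context block. Triage text is not prose;
  no sentence segmentation exists anywhere in the package.
* **Stemming** uses the Porter suffix-stripping algorithm, implemented in
  the package and pinned by golden tests, so *work/works/working* collapse
  to the single term *work*. Stemming is deterministic and idempotent.
* **Stop-listing** removes a standard English function-word list, *minus*
  a retained-override list of body parts (back, face, feet, ...), injury
  mechanisms (cut, fall, ...) and injurious objects (saw, hammer, ...).
  Ordinary stop-lists throw several of these away ("back", "saw"), which
  would be ruinous in injury text. The override membership is a design
  artifact of this package — the categories are standard, the exact list
  is ours and is user-replaceable (`load_stoplist()`).

Keyword and index matching deliberately run on the **raw case-folded
narrative**, not the token stream, so hyphens and punctuation can never
block a substring match ("work-related", "(work)").

## Keyword search

`keyword_flag()` is substring matching on `work`. Substring — not token —
semantics is a considered choice: it catches *worker*, *workshop*,
*woodwork* and accepts the resulting false positives, trading a little
specificity for simplicity and sensitivity to compounds. The match is
monotone: appending text can never unflag a record.

## Index search

The index exists to catch work-coded cases whose narrative never says
"work". `select_review_sample()` draws those cases (default n = 1000 —
large enough to harvest a broad vocabulary, small enough to review by
hand); a human reviewer annotates each with extracted keywords under
sixteen fixed headings; `build_index()` then:

1. restricts to the five work-specific headings (activity task, object
   involved, work location, occupation, safety/preventative devices);
2. reduces each keyword to its smallest searchable stem;
3. merges entries where one stem is a prefix of another, summing
   frequencies (*weld* absorbs *welder*);
4. drops merged stems with pooled frequency below 5;
5. orders by descending frequency.

Two numerical choices deserve a note:

* **Search stems must be substrings of their surface forms.** The Porter
  stem of *factory* is `factori`, which never occurs in text. The index
  stem is therefore the Porter stem trimmed back to the longest prefix it
  shares with the surface word (`factor`), guaranteeing the stem matches
  its own variants under substring search. Multi-word phrases ("job
  site", "hard hat") are kept verbatim — lower-cased,
  whitespace-normalized — because stemming an interior word would break
  phrase matching; they match across single internal spaces.
* **Merge before threshold.** Whether the <5 exclusion applies before or
  after stem merging is genuinely open; merging first is implemented,
  because the threshold's purpose (keep the index small and wieldy)
  applies to the final entries, and merging first lets variants pool their
  evidence (*welding* 3 + *welder* 4 survives as *weld* 7).

Index construction is permutation-invariant, and the union flag is the
exact set union of the keyword and index flags.

## The concept classifier

This is an open re-implementation of tag-supervised concept scoring as a
specified behavioural contract — frequency/co-occurrence concepts,
learning from the coded tags, per-tag relevance that can be positive for
both tags at once — not a numeric replication of any proprietary engine.

**Learning** (`learn_concept_model()`):

* *Seeds*: every stop-listed stem with document frequency at or above
  `min_term_frequency` (default 5) seeds a concept; the number of concepts
  is unrestricted by default (`max_concepts = Inf`).
* *Thesaurus*: each concept adopts up to `generality` (default 10, so
  concepts stay tight) co-occurring stems. A member must (a) co-occur with
  the seed at `lift_threshold` (default 2) times its base rate — plain
  conditional frequency would adopt globally common injury terms into
  every concept — and (b) lean toward the concept's own tag. The
  tag-agreement condition is what "learning concepts associated with each
  group independently" means operationally: without it, class-neutral
  terms that merely share narratives with a work term leak work evidence
  into plainly non-work records. Member weight is the conditional
  frequency P(member | seed); the seed itself has weight 1.
* *Class association*: the smoothed share of **seed-containing** training
  records carrying each label, with add-one smoothing
  ((n_work + 1)/(n + 2); the two associations always sum to 1). Estimating
  on seed-containing records rather than any-member matches keeps the
  estimate from being diluted toward the base rate by weak thesaurus
  members. Smoothing prevents degenerate 0/1 associations on small
  corpora; its visible cost is that exact duplication of the training
  corpus shifts associations slightly (0.75 to 0.83 on a 2-record
  concept), which the tests acknowledge rather than hide.
* *Discrimination filter*: concepts with margin
  |assoc_work − assoc_other| below `margin_floor` (default 0.1) are
  dropped; survivors are assigned to the tag with the larger association
  (a margin-zero tie would go to work, but the default floor removes
  ties).
* Records with a missing activity label are ignored during learning.
  A single-label corpus is an error: class associations are undefined.

**Scoring** (`score_corpus()`): a concept matches a record when any member
stem occurs in its stop-listed stem set; it contributes
(class association) × (weight of the best-matching member) to the score of
its tag. Scores are unnormalized sums: a text-rich record can score well
above 1, and the empirically calibrated cutoffs below inherit that scale.
Empty or evidence-free narratives score exactly (0, 0).

**Classification**: binary acceptance is `score_work > 0`. The four-way
rules partition the score plane: work-only evidence is `WorkActivity`,
both-positive with work ≥ other is `ProbableWorkActivity` (ties go to the
work side, per the "higher than or equal to" rule), both-positive with
work < other is `ProbableOtherActivity`, and everything else —
including the no-evidence point (0, 0) — is `OtherActivity`. Assigning
(0, 0) to `OtherActivity` mirrors how uninformative narratives behave in
practice: no text interrogation method can identify them, and defaulting
them to the majority class makes that failure visible in sensitivity
rather than invisibly inflating the flagged pool.

**Cutoff calibration** (`calibrate_cutoff()`): within the
`ProbableOtherActivity` group, the score difference of work-coded records
is summarized and the cutoff set to |mean| + SD (sample, n−1 SD —
conventional for reported summary statistics). `ProbableOtherActivity`
records with |diff| strictly below the cutoff are recoded to
`ProbableWorkActivity`; no other class is ever touched, and the flagged
count is monotone in the cutoff. On the published group moments
(mean −0.83, SD 0.63) the stated construction yields **1.46**, while the
originally applied cutoff was **1.47** (which equals the *other*-group
mean magnitude). The package computes the stated formula and accepts any
explicit override; it does not guess which the original intent was.

The group comparison uses a pooled-variance two-sample t-test
(df = nA + nB − 2), consistent with the degrees of freedom reported in
the original analysis; `stats::t.test(var.equal = TRUE)` does the work,
and the tests check it against the hand-computed pooled formula.

## The synthetic generator

`generate_corpus()` emulates the class-conditional structure of the
surveillance corpus these methods were designed for, with defaults
calibrated to published marginal rates:

| parameter | default | source of the value |
|---|---|---|
| work prevalence | 0.103 | published prevalence |
| P(keyword &#124; work) | 0.5816 | published keyword rate |
| P(keyword &#124; other) | 0.0103 | published keyword rate |
| P(term &#124; work, keyword) | 0.699 | implied by keyword/index/union counts |
| P(term &#124; work, no keyword) | 0.507 | implied by the same counts; consistent with the 522/1000 review-sample rate |
| P(term &#124; other) | 0.1254 | published index-term rate |
| missing labels | 10 | published exclusion count |
| negation / empty / misspelling rates | 0.03 / 0.02 / 0.02 | unpublished; set to plausible nuisance levels |

The conditional index rate among keyword-positive work records is an
extra parameter beyond the obvious four: without it the published union
rate (0.794 among work cases) is not reproducible from the marginals,
because keyword and index presence are strongly positively associated in
work narratives.

Narratives are assembled from templates — injury phrase + planted
keyword/term/negation phrases + activity context + optional temporal
tail. Work terms carry class-conditional sampling weights so that term
specificity is heterogeneous (job site, factory, forklift, mine,
construction, labour, client are highly work-specific; truck, station,
office, boss are ambiguous), mirroring real index behaviour where a few
terms are nearly diagnostic and others mostly generate false positives.
Planting discipline keeps the calibration exact: negation phrases
containing "work" are only added to already-keyword-positive records,
empty narratives only replace unplanted ones, and misspellings (single
character edits) only touch never-planted tokens and are rejected if they
would fabricate the keyword or a work term.

**What passing tests on synthetic data show — and don't.** The generator
reproduces the published *flag rates by construction*; when the keyword
classifier measures sensitivity ≈ 0.58 on a generated corpus, that
validates the flag→evaluate pipeline mechanics, not the epidemiology of
any real ED population. Real triage text has abbreviation conventions,
typo distributions, and topic correlations no template mixture captures,
so concept-classifier metrics on synthetic data indicate qualitative
behaviour (ordering of methods, direction of the cutoff adjustment), not
transportable operating characteristics.

## Degenerate inputs and tie-breaks, collected

* Loader: never drops a row; narratives are truncated at 255 characters
  with a warning; unparseable labels become *missing*; duplicate IDs are
  fatal; every row is otherwise treated as a distinct presentation (the
  original handling of duplicate presentations is unstated).
* Evaluation: zero-denominator metrics are reported as `NA` with a
  message, never as 0.
* Four-way ties (work = other > 0) go to `ProbableWorkActivity`.
* Adjusted recoding uses a strict inequality (|diff| < cutoff).
* `calibrate_cutoff()` requires ≥ 2 work-coded records in the target
  group; an all-equal group gives SD 0 and cutoff |mean|.
* `build_index()` errors on an empty post-restriction annotation set and
  when no stem reaches the frequency threshold.

## Problem sizes

The test suite and the acceptance script choose sizes that make sampling
noise negligible relative to the quantities asserted: 200,000 records for
the calibrated-rate checks (binomial SE on the keyword sensitivity
≈ 0.003), 20,000 for vocabulary-recovery checks under disjoint class
vocabularies, 100,000 for generator goodness-of-fit, and ≤ 10-record
corpora (500 random cases) for the exact brute-force scoring oracle.

## Known limitations

* The shipped default index mixes the seven published high-specificity
  terms with synthetic vocabulary; the full 50-term operational index was
  never published. Users with real data should build their own.
* The concept classifier reproduces a behavioural contract, not any
  proprietary engine's numeric output; its "probability" scale is an
  unnormalized relevance sum.
* Substring semantics accept incidental matches (*network* contains
  *work*); whether such matches mattered in the original corpus is
  unknowable from the published record.
* No spelling correction or abbreviation expansion: misspelled terms are
  simply missed unless a stem happens to survive the typo.
* No negation scoping anywhere, by design.
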