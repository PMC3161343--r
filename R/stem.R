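# Porter (1980) suffix-stripping stemmer, implemented in base R.
# Only lower-case alphabetic tokens of length >= 3 are altered; anything
# containing digits or other characters passes through unchanged, which keeps
# the stemmer total over raw triage tokens (ages, times, codes).

.vowel_set <- c("a", "e", "i", "o", "u")

# TRUE where the letter acts as a consonant; 'y' is a consonant at the start
# of a word or after a vowel, and a vowel after a consonant.
.cons_mask <- function(ch) {
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    cons[i] <- if (ch[i] %in% .vowel_set) {
      FALSE
    } else if (ch[i] == "y") {
      i == 1L || !cons[i - 1L]
    } else {
      TRUE
    }
  }
  cons
}

# Porter's measure m: number of VC sequences in the [C](VC)^m[V] form.
.measure <- function(s) {
  if (!nzchar(s)) return(0L)
  v <- rle(.cons_mask(strsplit(s, "", fixed = TRUE)[[1]]))$values
  if (length(v) < 2L) return(0L)
  sum(!v[-length(v)] & v[-1L])
}

.has_vowel <- function(s) {
  nzchar(s) && any(!.cons_mask(strsplit(s, "", fixed = TRUE)[[1]]))
}

.ends_double_cons <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1L] && .cons_mask(ch)[n]
}

# *o condition: ends consonant-vowel-consonant, final consonant not w, x, y.
.ends_cvc <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cons <- .cons_mask(ch)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(ch[n] %in% c("w", "x", "y"))
}

.ends <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw >= ns && substring(w, nw - ns + 1L) == suf
}

.stem_part <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

# Rule tables for steps 2-4, ordered longest suffix first so the longest
# matching suffix is the one (and only one) tried.
.rule_table <- function(...) {
  x <- c(...)
  d <- data.frame(suffix = names(x), repl = unname(x), stringsAsFactors = FALSE)
  d[order(-nchar(d$suffix), d$suffix), , drop = FALSE]
}

.step2_rules <- .rule_table(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.step3_rules <- .rule_table(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)

.step4_rules <- .rule_table(
  al = "", ance = "", ence = "", er = "", ic = "", able = "", ible = "",
  ant = "", ement = "", ment = "", ent = "", ion = "", ou = "", ism = "",
  ate = "", iti = "", ous = "", ive = "", ize = ""
)

.apply_rules <- function(w, rules, m_min) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suffix[i]
    if (.ends(w, suf)) {
      st <- .stem_part(w, suf)
      ok <- .measure(st) > m_min
      if (ok && suf == "ion") ok <- .ends(st, "s") || .ends(st, "t")
      if (ok) w <- paste0(st, rules$repl[i])
      return(w)
    }
  }
  w
}

.porter1 <- function(w) {
  if (nchar(w) < 3L || grepl("[^a-z]", w)) return(w)

  # step 1a: plurals
  if (.ends(w, "sses")) {
    w <- .stem_part(w, "es")
  } else if (.ends(w, "ies")) {
    w <- paste0(.stem_part(w, "ies"), "i")
  } else if (!.ends(w, "ss") && .ends(w, "s")) {
    w <- .stem_part(w, "s")
  }

  # step 1b: -eed / -ed / -ing
  fired <- FALSE
  if (.ends(w, "eed")) {
    if (.measure(.stem_part(w, "eed")) > 0L) w <- .stem_part(w, "d")
  } else if (.ends(w, "ed")) {
    st <- .stem_part(w, "ed")
    if (.has_vowel(st)) {
      w <- st
      fired <- TRUE
    }
  } else if (.ends(w, "ing")) {
    st <- .stem_part(w, "ing")
    if (.has_vowel(st)) {
      w <- st
      fired <- TRUE
    }
  }
  if (fired) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.ends_double_cons(w) &&
               !(.ends(w, "l") || .ends(w, "s") || .ends(w, "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.measure(w) == 1L && .ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i when a vowel precedes
  if (.ends(w, "y") && .has_vowel(.stem_part(w, "y"))) {
    w <- paste0(.stem_part(w, "y"), "i")
  }

  w <- .apply_rules(w, .step2_rules, 0L)
  w <- .apply_rules(w, .step3_rules, 0L)
  w <- .apply_rules(w, .step4_rules, 1L)

  # step 5a: drop terminal e
  if (.ends(w, "e")) {
    st <- .stem_part(w, "e")
    m <- .measure(st)
    if (m > 1L || (m == 1L && !.ends_cvc(st))) w <- st
  }
  # step 5b: -ll -> -l for m > 1
  if (.ends(w, "l") && .ends_double_cons(w) && .measure(w) > 1L) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  w
}

#' Stem tokens with the Porter algorithm
#'
#' Reduces grammatical variants of a word to a single term, so that e.g.
#' "work", "works" and "working" are all represented by the stem "work".
#' Stemming is deterministic and idempotent. Tokens shorter than three
#' characters or containing non-alphabetic characters are returned unchanged.
#'
#' @param tokens Character vector of tokens (case is folded first).
#' @return Character vector of stems, same length as `tokens`.
#' @examples
#' porter_stem(c("working", "works", "work", "injuries"))
#' @export
porter_stem <- function(tokens) {
  if (!length(tokens)) return(character())
  low <- tolower(as.character(tokens))
  u <- unique(low)
  stems <- vapply(u, .porter1, character(1), USE.NAMES = FALSE)
  stems[match(low, u)]
}
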