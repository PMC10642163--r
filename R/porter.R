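# Porter stemming algorithm (M.F. Porter, 1980), implemented over single
# lowercase words. Words of length <= 2 are returned unchanged.

.p_vowels <- c("a", "e", "i", "o", "u")

# consonant test for position i in a character split of the word:
# y counts as a vowel when preceded by a consonant
.p_is_cons <- function(chs, i) {
  ch <- chs[i]
  if (ch %in% .p_vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chs, i - 1L))
  }
  TRUE
}

.p_types <- function(word) {
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chs), function(i) .p_is_cons(chs, i), logical(1))
}

# m of [C](VC)^m[V]: number of vowel-run -> consonant-run transitions
.p_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  runs <- rle(.p_types(word))$values
  if (length(runs) < 2L) return(0L)
  sum(runs[-1L] & !runs[-length(runs)])
}

.p_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.p_types(word))
}

# *d: ends with a double consonant
.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && .p_types(word)[n]
}

# *o: ends cvc where the final c is not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  t <- .p_types(word)
  last <- substr(word, n, n)
  t[n - 2L] && !t[n - 1L] && t[n] && !(last %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  ns <- nchar(suffix)
  nw <- nchar(word)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.p_chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# apply the first matching rule of a (suffix -> replacement) table, subject
# to a measure condition on the remaining stem; returns word unchanged when
# the longest matching suffix fails its condition (per-step longest match)
.p_rule_step <- function(word, rules, min_m) {
  for (k in seq_len(nrow(rules))) {
    suf <- rules$suffix[k]
    if (.p_ends(word, suf)) {
      stem <- .p_chop(word, nchar(suf))
      if (.p_measure(stem) > min_m) {
        return(paste0(stem, rules$repl[k]))
      }
      return(word)
    }
  }
  word
}

.p_step2_rules <- data.frame(
  suffix = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
  repl = c("ate", "tion", "ence", "ance", "ize", "able", "al",
           "ent", "e", "ous", "ize", "ate", "ate", "al",
           "ive", "ful", "ous", "al", "ive", "ble"),
  stringsAsFactors = FALSE
)
.p_step2_rules <- .p_step2_rules[order(-nchar(.p_step2_rules$suffix)), ]

.p_step3_rules <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  repl = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)
.p_step3_rules <- .p_step3_rules[order(-nchar(.p_step3_rules$suffix)), ]

.p_step4_suffixes <- c("ement", "ance", "ence", "able", "ible", "ment",
                       "ant", "ent", "ion", "ism", "ate", "iti", "ous",
                       "ive", "ize", "al", "er", "ic", "ou")
.p_step4_suffixes <- .p_step4_suffixes[order(-nchar(.p_step4_suffixes))]

.p_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 1a
  if (.p_ends(word, "sses")) {
    word <- .p_chop(word, 2L)
  } else if (.p_ends(word, "ies")) {
    word <- paste0(.p_chop(word, 3L), "i")
  } else if (!.p_ends(word, "ss") && .p_ends(word, "s")) {
    word <- .p_chop(word, 1L)
  }

  # step 1b
  stripped <- FALSE
  if (.p_ends(word, "eed")) {
    stem <- .p_chop(word, 3L)
    if (.p_measure(stem) > 0L) word <- .p_chop(word, 1L)
  } else if (.p_ends(word, "ed")) {
    stem <- .p_chop(word, 2L)
    if (.p_has_vowel(stem)) {
      word <- stem
      stripped <- TRUE
    }
  } else if (.p_ends(word, "ing")) {
    stem <- .p_chop(word, 3L)
    if (.p_has_vowel(stem)) {
      word <- stem
      stripped <- TRUE
    }
  }
  if (stripped) {
    if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.p_double_cons(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- .p_chop(word, 1L)
    } else if (.p_measure(word) == 1L && .p_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.p_ends(word, "y") && .p_has_vowel(.p_chop(word, 1L))) {
    word <- paste0(.p_chop(word, 1L), "i")
  }

  # steps 2 and 3 (condition m > 0)
  word <- .p_rule_step(word, .p_step2_rules, 0L)
  word <- .p_rule_step(word, .p_step3_rules, 0L)

  # step 4 (condition m > 1; "ion" additionally requires stem ending s or t)
  for (suf in .p_step4_suffixes) {
    if (.p_ends(word, suf)) {
      stem <- .p_chop(word, nchar(suf))
      ok <- .p_measure(stem) > 1L
      if (ok && suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # step 5a
  if (.p_ends(word, "e")) {
    stem <- .p_chop(word, 1L)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) word <- stem
  }

  # step 5b
  if (.p_measure(word) > 1L && .p_double_cons(word) &&
      substr(word, nchar(word), nchar(word)) == "l") {
    word <- .p_chop(word, 1L)
  }

  word
}

#' Stem words with the Porter algorithm
#'
#' Reduces English words to their stems so that morphological variants of
#' the same medical term ("hearing", "hear"; "months", "month") collapse to
#' one token before any similarity computation or feature counting. Input
#' is expected to be lowercase alphabetic; other words are stemmed on a
#' best-effort basis.
#'
#' @param words Character vector of single words.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("hearing", "months", "caresses", "relational"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, .p_stem_word, character(1), USE.NAMES = FALSE)
}
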