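# Porter (1980) suffix-stripping stemmer, implemented in full because review
# preprocessing depends on stem equivalence classes (stem completion maps each
# class back to its most frequent surface form).

.porter_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# consonant mask: a,e,i,o,u are vowels; y is a consonant at position 1 or when
# the preceding letter is a vowel, otherwise a vowel
.porter_cons <- function(chs) {
  n <- length(chs)
  out <- logical(n)
  for (i in seq_len(n)) {
    ch <- chs[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      out[i] <- FALSE
    } else if (ch == "y") {
      out[i] <- if (i == 1) TRUE else !out[i - 1]
    } else {
      out[i] <- TRUE
    }
  }
  out
}

# measure m of a stem: number of vowel-group -> consonant-group transitions
# in the [C](VC)^m[V] decomposition
.porter_m <- function(w) {
  if (!nzchar(w)) return(0L)
  v <- !.porter_cons(.porter_chars(w))
  g <- rle(v)$values
  if (length(g) < 2) return(0L)
  sum(g[-length(g)] & !g[-1])
}

.porter_has_vowel <- function(w) {
  if (!nzchar(w)) return(FALSE)
  any(!.porter_cons(.porter_chars(w)))
}

.porter_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  chs <- .porter_chars(w)
  chs[n] == chs[n - 1] && .porter_cons(chs)[n]
}

# stem ends consonant-vowel-consonant, final consonant not w, x or y
.porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  chs <- .porter_chars(w)
  cons <- .porter_cons(chs)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(chs[n] %in% c("w", "x", "y"))
}

.ends <- function(w, s) {
  nw <- nchar(w); ns <- nchar(s)
  nw >= ns && substring(w, nw - ns + 1) == s
}

.chop <- function(w, n) substring(w, 1, nchar(w) - n)

.porter_step1 <- function(w) {
  # step 1a
  if (.ends(w, "sses")) {
    w <- .chop(w, 2)
  } else if (.ends(w, "ies")) {
    w <- paste0(.chop(w, 3), "i")
  } else if (!.ends(w, "ss") && .ends(w, "s")) {
    w <- .chop(w, 1)
  }
  # step 1b
  grew <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m(.chop(w, 3)) > 0) w <- .chop(w, 1)
  } else if (.ends(w, "ed") && .porter_has_vowel(.chop(w, 2))) {
    w <- .chop(w, 2); grew <- TRUE
  } else if (.ends(w, "ing") && .porter_has_vowel(.chop(w, 3))) {
    w <- .chop(w, 3); grew <- TRUE
  }
  if (grew) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !(.ends(w, "l") || .ends(w, "s") || .ends(w, "z"))) {
      w <- .chop(w, 1)
    } else if (.porter_m(w) == 1 && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  # step 1c
  if (.ends(w, "y") && .porter_has_vowel(.chop(w, 1))) {
    w <- paste0(.chop(w, 1), "i")
  }
  w
}

.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

# apply the longest matching suffix rule; replace only if m(stem) > 0
.porter_replace <- function(w, rules) {
  lens <- vapply(rules, function(r) nchar(r[[1]]), integer(1))
  for (r in rules[order(-lens)]) {
    if (.ends(w, r[[1]])) {
      stem <- .chop(w, nchar(r[[1]]))
      if (.porter_m(stem) > 0) w <- paste0(stem, r[[2]])
      return(w)
    }
  }
  w
}

.step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
  "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

.porter_step4 <- function(w) {
  for (s in .step4_suffixes[order(-nchar(.step4_suffixes))]) {
    if (.ends(w, s)) {
      stem <- .chop(w, nchar(s))
      ok <- .porter_m(stem) > 1
      if (s == "ion") ok <- ok && (.ends(stem, "s") || .ends(stem, "t"))
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

.porter_step5 <- function(w) {
  if (.ends(w, "e")) {
    a <- .chop(w, 1)
    m <- .porter_m(a)
    if (m > 1 || (m == 1 && !.porter_cvc(a))) w <- a
  }
  if (.porter_m(w) > 1 && .porter_double_cons(w) && .ends(w, "l")) {
    w <- .chop(w, 1)
  }
  w
}

.porter_one <- function(w) {
  if (nchar(w) <= 2) return(w)
  w <- .porter_step1(w)
  w <- .porter_replace(w, .step2_rules)
  w <- .porter_replace(w, .step3_rules)
  w <- .porter_step4(w)
  .porter_step5(w)
}

#' Porter stemmer
#'
#' Reduces inflected English words to their stem with the classic Porter
#' (1980) suffix-stripping algorithm. Words of one or two characters are
#' returned unchanged. Input is expected lowercase and alphabetic; the
#' stemmer is the basis for the stem-completion step of preprocessing.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("erections", "flushing", "relational"))
#' @export
porter_stem <- function(words) {
  if (!length(words)) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .porter_one, character(1), USE.NAMES = TRUE)
  unname(stems[words])
}
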