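# Porter (1980) suffix-stripping stemmer.  Hand-written because the method's
# bag-of-stems features are defined over Porter-style stems and no stemming
# backend is a package dependency; the implementation follows the original
# five-step algorithm.

.porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.porter_is_cons(chars, i - 1L))
  }
  TRUE
}

# m = number of VC sequences in [C](VC)^m[V]
.porter_measure <- function(word) {
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .porter_is_cons(chars, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  m <- 0L
  # count V followed by C transitions
  for (i in seq_along(runs)) {
    if (i > 1L && runs[i] && !runs[i - 1L]) m <- m + 1L
  }
  m
}

.porter_has_vowel <- function(word) {
  chars <- strsplit(word, "")[[1]]
  any(!vapply(seq_along(chars), function(i) .porter_is_cons(chars, i), logical(1)))
}

.porter_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  .porter_is_cons(chars, n)
}

# cvc ending where final c is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  if (!.porter_is_cons(chars, n) || .porter_is_cons(chars, n - 1L) ||
      !.porter_is_cons(chars, n - 2L)) {
    return(FALSE)
  }
  !(chars[n] %in% c("w", "x", "y"))
}

.porter_replace <- function(word, suffix, repl, min_m = 0L) {
  stem <- substr(word, 1L, nchar(word) - nchar(suffix))
  if (.porter_measure(stem) > min_m - 1L) paste0(stem, repl) else word
}

.porter_step1 <- function(w) {
  # 1a
  if (endsWith(w, "sses")) {
    w <- sub("sses$", "ss", w)
  } else if (endsWith(w, "ies")) {
    w <- sub("ies$", "i", w)
  } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
    w <- sub("s$", "", w)
  }
  # 1b
  did_1b <- FALSE
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (.porter_measure(stem) > 0L) w <- sub("eed$", "ee", w)
  } else if (endsWith(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (.porter_has_vowel(stem)) { w <- stem; did_1b <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (.porter_has_vowel(stem)) { w <- stem; did_1b <- TRUE }
  }
  if (did_1b) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_ends_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.porter_measure(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  # 1c
  if (endsWith(w, "y") && .porter_has_vowel(substr(w, 1L, nchar(w) - 1L))) {
    w <- sub("y$", "i", w)
  }
  w
}

.porter_step2_map <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.porter_step3_map <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = ""
)

.porter_step4_sfx <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter_apply_map <- function(w, map, min_m = 1L) {
  sfx <- names(map)[order(nchar(names(map)), decreasing = TRUE)]
  for (s in sfx) {
    if (endsWith(w, s)) {
      stem <- substr(w, 1L, nchar(w) - nchar(s))
      if (.porter_measure(stem) >= min_m) w <- paste0(stem, map[[s]])
      return(w)
    }
  }
  w
}

.porter_step4 <- function(w) {
  sfx <- .porter_step4_sfx[order(nchar(.porter_step4_sfx), decreasing = TRUE)]
  for (s in sfx) {
    if (endsWith(w, s)) {
      stem <- substr(w, 1L, nchar(w) - nchar(s))
      ok <- .porter_measure(stem) > 1L
      if (s == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

.porter_step5 <- function(w) {
  if (endsWith(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- .porter_measure(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }
  if (.porter_measure(w) > 1L && .porter_ends_double_cons(w) &&
      endsWith(w, "l")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}

.porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  if (!grepl("^[a-z]+$", word)) return(word)  # hyphenated/numeric left alone
  w <- .porter_step1(word)
  w <- .porter_apply_map(w, .porter_step2_map)
  w <- .porter_apply_map(w, .porter_step3_map)
  w <- .porter_step4(w)
  .porter_step5(w)
}

#' Porter-stem a vector of tokens
#'
#' Applies the classic five-step Porter suffix-stripping algorithm to each
#' lower-case token.  Tokens containing non-alphabetic characters (hyphenated
#' compounds, numbers) are returned unchanged, as are tokens of length 1-2.
#'
#' @param tokens character vector of lower-case tokens.
#' @return character vector of stems, aligned with `tokens`.
#' @examples
#' stem_tokens(c("infections", "infection", "disturbances"))
#' @export
stem_tokens <- function(tokens) {
  vapply(tokens, .porter_stem_one, character(1), USE.NAMES = FALSE)
}
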