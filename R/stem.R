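#' Porter stem of a word
#'
#' Implementation of the classic Porter (1980) suffix-stripping algorithm,
#' the stemmer whose output matches the stem feature used by the tagger
#' (e.g. \code{compositions -> composit}, \code{oxide -> oxid},
#' \code{hyaluronic -> hyaluron}).  Input is lower-cased first; words of
#' two characters or fewer, and tokens containing non-letters, are returned
#' unchanged (lower-cased).
#'
#' @param words Character vector of tokens.
#' @return Character vector of stems, same length as \code{words}.
#' @examples
#' porter_stem(c("compositions", "containing", "tocopherols"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (is.na(w) || nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5a(w)
  p_step5b(w)
}

# consonant map: y is a consonant iff at word start or preceded by a vowel
p_cons <- function(w) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cons <- !(ch %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (ch[i] == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
  }
  cons
}

# measure m: number of vowel->consonant transitions in [C](VC){m}[V]
p_m <- function(w) {
  if (!nzchar(w)) return(0L)
  cons <- p_cons(w)
  sum(cons[-1] & !cons[-length(cons)])
}

p_has_vowel <- function(w) nzchar(w) && any(!p_cons(w))

p_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) && p_cons(w)[n]
}

# *o condition: ends cvc where the final consonant is not w, x or y
p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- p_cons(w)
  last <- substr(w, n, n)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(last %in% c("w", "x", "y"))
}

p_ends <- function(w, s) {
  nchar(w) > nchar(s) && substring(w, nchar(w) - nchar(s) + 1L) == s
}

p_chop <- function(w, s) substr(w, 1L, nchar(w) - nchar(s))

p_step1a <- function(w) {
  if (p_ends(w, "sses")) return(paste0(p_chop(w, "sses"), "ss"))
  if (p_ends(w, "ies")) return(paste0(p_chop(w, "ies"), "i"))
  if (p_ends(w, "ss")) return(w)
  if (p_ends(w, "s")) return(p_chop(w, "s"))
  w
}

p_step1b <- function(w) {
  if (p_ends(w, "eed")) {
    stem <- p_chop(w, "eed")
    if (p_m(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  hit <- FALSE
  if (p_ends(w, "ed") && p_has_vowel(p_chop(w, "ed"))) {
    w <- p_chop(w, "ed"); hit <- TRUE
  } else if (p_ends(w, "ing") && p_has_vowel(p_chop(w, "ing"))) {
    w <- p_chop(w, "ing"); hit <- TRUE
  }
  if (hit) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (p_m(w) == 1L && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

p_step1c <- function(w) {
  if (p_ends(w, "y") && p_has_vowel(p_chop(w, "y")))
    return(paste0(p_chop(w, "y"), "i"))
  w
}

# suffix tables: longest matching suffix decides; its m-condition then gates
p_rule_table <- function(w, rules, cond) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (p_ends(w, s)) {
      stem <- p_chop(w, s)
      if (cond(stem, s)) return(paste0(stem, rules[[s]]))
      return(w)
    }
  }
  w
}

p_step2 <- function(w) {
  rules <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  p_rule_table(w, as.list(rules), function(stem, s) p_m(stem) > 0L)
}

p_step3 <- function(w) {
  rules <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  p_rule_table(w, as.list(rules), function(stem, s) p_m(stem) > 0L)
}

p_step4 <- function(w) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (s in sufs[order(-nchar(sufs))]) {
    if (p_ends(w, s)) {
      stem <- p_chop(w, s)
      ok <- p_m(stem) > 1L
      if (s == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) return(stem)
      return(w)
    }
  }
  w
}

p_step5a <- function(w) {
  n <- nchar(w)
  if (substr(w, n, n) == "e") {
    stem <- substr(w, 1L, n - 1L)
    m <- p_m(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) return(stem)
  }
  w
}

p_step5b <- function(w) {
  if (p_m(w) > 1L && p_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l")
    return(substr(w, 1L, nchar(w) - 1L))
  w
}
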