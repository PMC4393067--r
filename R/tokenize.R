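#' Tokenize text for chemical entity recognition
#'
#' Splits a character string into tokens while keeping systematic chemical
#' names intact.  Standard word tokenizers fragment names such as
#' \code{"1,2-dimethylbenzene"} at every comma and hyphen; here a maximal run
#' of non-alphanumeric, non-whitespace characters is kept \emph{inside} a
#' token whenever it is immediately flanked by alphanumeric characters on
#' both sides.  Any other punctuation (sentence punctuation, unmatched
#' brackets, quotes) separates tokens and is dropped: the returned sequence
#' contains only tokens holding at least one alphanumeric character.
#'
#' Rules, in full:
#' \itemize{
#'   \item whitespace always separates tokens;
#'   \item a run of punctuation/symbol characters with an alphanumeric
#'     character directly before and after it (e.g. the \code{",2-"} in
#'     \code{"1,2-dimethylbenzene"}, primes, internal parentheses and
#'     brackets) stays inside the token;
#'   \item all remaining punctuation (a terminal \code{"."}, a comma before
#'     a space, ...) is detached and not emitted as a token;
#'   \item digits adjacent to letters stay attached (\code{"H2O"} is one
#'     token).
#' }
#'
#' @param text A single character string (may be empty or \code{NA}).
#' @return A data frame with one row per token and columns \code{text},
#'   \code{start}, \code{end}.  Offsets are 0-based, half-open
#'   \code{[start, end)} character positions into \code{text}, strictly
#'   increasing and non-overlapping, so
#'   \code{substr(text, start + 1, end) == text} row-wise.
#' @examples
#' tokenize("1,2-dimethylbenzene was added.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  # token = alnum block, optionally chained through internal punctuation runs
  pat <- "[[:alnum:]]+(?:[^[:alnum:][:space:]]+[[:alnum:]]+)*"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(text = regmatches(text, list(m))[[1]],
             start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}
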