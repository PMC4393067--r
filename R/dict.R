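#' Dictionary-based chemical entity recognizer
#'
#' Exact-match baseline in the style of dictionary pipelines: every
#' maximal, token-boundary-aligned occurrence of any lexicon descriptor
#' (name or synonym) in the text becomes a mention carrying the matched
#' term's identifier, so recognition and resolution happen in one step.
#' Matching is case-insensitive and never fires inside a word.  Where
#' candidate matches overlap, the longest match wins; ties are broken
#' leftmost-first, then by lexicographically smallest term id.  Because
#' matching is purely lexical, descriptors that are also common English
#' words ("can", "group", "all") are matched wherever they occur -- the
#' characteristic false-positive mode of dictionary recognizers.
#'
#' @param lexicon A \code{chem_lexicon}.
#' @param text Document text.
#' @param doc_id Document id for the emitted mentions.
#' @return Mention data frame, non-overlapping and in document order; each
#'   row's \code{surface} equals (case-insensitively) a descriptor of its
#'   \code{lexicon_id} and \code{score} is 1 for a name match, 0.8 for a
#'   synonym match.
#' @export
dict_recognize <- function(lexicon, text, doc_id = "doc") {
  tokens <- tokenize(text)
  if (nrow(tokens) == 0 || nrow(lexicon) == 0) return(mentions())
  tok_lc <- tolower(tokens$text)
  # descriptor table: token word sequences keyed by first word
  entries <- dict_entries(lexicon)
  if (!nrow(entries$tab)) return(mentions())
  first_word <- vapply(entries$words, `[`, "", 1)
  by_first <- split(seq_along(entries$words), first_word)
  n <- nrow(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    cand <- by_first[[tok_lc[i]]]
    best <- NULL
    if (!is.null(cand)) {
      for (k in cand) {
        wseq <- entries$words[[k]]
        L <- length(wseq)
        if (i + L - 1L > n) next
        if (!all(tok_lc[i:(i + L - 1L)] == wseq)) next
        s <- tokens$start[i]; e <- tokens$end[i + L - 1L]
        slice <- substring(text, s + 1L, e)
        if (tolower(slice) != tolower(entries$tab$descriptor[k])) next
        key <- list(len = L, id = entries$tab$term_id[k],
                    kind = entries$tab$kind[k], s = s, e = e, slice = slice)
        if (is.null(best) || key$len > best$len ||
            (key$len == best$len && (key$id < best$id ||
              (key$id == best$id && key$kind == "name" &&
               best$kind != "name"))))
          best <- key
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- best
      # advance past the consumed tokens
      i <- which(tokens$start >= best$e)[1]
      if (is.na(i)) break
    } else i <- i + 1L
  }
  if (!length(out)) return(mentions())
  mentions(doc_id,
           start = vapply(out, `[[`, 0, "s"),
           end = vapply(out, `[[`, 0, "e"),
           surface = vapply(out, `[[`, "", "slice"),
           lexicon_id = vapply(out, `[[`, "", "id"),
           score = ifelse(vapply(out, `[[`, "", "kind") == "name", 1, 0.8))
}

dict_entries <- function(lexicon) {
  descriptor <- character(); term_id <- character(); kind <- character()
  for (i in seq_len(nrow(lexicon))) {
    d <- descriptors_of(lexicon, i)
    descriptor <- c(descriptor, d)
    term_id <- c(term_id, rep(lexicon$term_id[i], length(d)))
    kind <- c(kind, c("name", rep("synonym", length(d) - 1L)))
  }
  words <- lapply(descriptor, function(d) tolower(tokenize(d)$text))
  keep <- lengths(words) > 0L
  list(tab = data.frame(descriptor = descriptor[keep],
                        term_id = term_id[keep], kind = kind[keep],
                        stringsAsFactors = FALSE),
       words = words[keep])
}

#' Run the dictionary recognizer over a corpus
#'
#' @param lexicon A \code{chem_lexicon}.
#' @param corpus A \code{chem_corpus}.
#' @return Named list \code{doc_id -> mention data frame}.
#' @export
dict_recognize_corpus <- function(lexicon, corpus) {
  stats::setNames(lapply(corpus, function(d)
    dict_recognize(lexicon, d$text, d$doc_id)),
    vapply(corpus, `[[`, "", "doc_id"))
}
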