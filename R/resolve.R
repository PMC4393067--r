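#' Resolve a surface string to a lexicon term: exact stage
#'
#' Case-folded whole-string comparison of the surface against every
#' descriptor.  A match to a term's name scores 1.0; a match to a synonym
#' scores 0.8.  When several terms share the descriptor, the
#' lexicographically smallest term id wins; a name match is preferred over
#' a synonym match.
#'
#' @param surface Query string.
#' @param index A \code{chem_vocab_index} from [build_index()].
#' @return One-row data frame with columns \code{term_id}, \code{score},
#'   \code{match_kind} (\code{"name-exact"} or \code{"synonym-exact"}) and
#'   \code{matched_descriptor}, or \code{NULL} when no descriptor equals
#'   the surface.
#' @export
resolve_exact <- function(surface, index) {
  key <- tolower(trimws(surface))
  if (!nzchar(key)) return(NULL)
  hit <- index$name_of[[key]]
  if (!is.null(hit))
    return(resolution_row(min(hit), 1.0, "name-exact", key, index))
  hit <- index$syn_of[[key]]
  if (!is.null(hit))
    return(resolution_row(min(hit), 0.8, "synonym-exact", key, index))
  NULL
}

resolution_row <- function(term_id, score, match_kind, key, index) {
  descs <- index$terms[[term_id]]$descriptor
  matched <- descs[tolower(descs) == key]
  data.frame(term_id = term_id, score = score, match_kind = match_kind,
             matched_descriptor = if (length(matched)) matched[1] else key,
             stringsAsFactors = FALSE)
}

#' Resolve a surface string: partial (weighted Jaccard) stage
#'
#' The query is tokenized, lower-cased and stopword-filtered like the
#' lexicon descriptors.  Every descriptor sharing at least one word with
#' the query is scored with the evidence-content-weighted Jaccard
#' similarity
#' \deqn{Sim = desc \times \frac{\sum_{w \in q \cap t_d} EC(w)}
#'                              {\sum_{w \in t_d} EC(w)}}
#' where \eqn{t_d} is the descriptor's word set, \eqn{desc} is 1 for a
#' name and 0.8 for a synonym, and EC is the evidence content from
#' [build_index()].  Query words absent from the lexicon vocabulary
#' contribute nothing; descriptors whose words all have EC 0 (words present
#' in every term) are unrankable and skipped with a warning.  Per term only
#' the best-scoring descriptor is kept; results are ranked by score, ties
#' broken name-before-synonym, then fewer descriptor words, then smallest
#' term id.
#'
#' @param surface Query string.
#' @param index A \code{chem_vocab_index}.
#' @return Data frame of ranked candidates (columns as [resolve_exact()]),
#'   zero rows when nothing shares a word with the query.
#' @export
resolve_partial <- function(surface, index) {
  empty <- data.frame(term_id = character(), score = numeric(),
                      match_kind = character(),
                      matched_descriptor = character(),
                      stringsAsFactors = FALSE)
  qw <- descriptor_words(surface, index$stopwords)
  if (!length(qw)) {
    warning("query '", surface, "' reduces to an empty word set")
    return(empty)
  }
  qw <- intersect(qw, names(index$ec))
  if (!length(qw)) return(empty)
  cand <- unique(unlist(index$terms_of[qw], use.names = FALSE))
  rows <- list()
  skipped_zero <- FALSE
  for (id in cand) {
    t <- index$terms[[id]]
    best <- NULL
    for (j in seq_along(t$words)) {
      wd <- t$words[[j]]
      shared <- intersect(qw, wd)
      if (!length(shared)) next
      denom <- sum(index$ec[wd])
      if (denom == 0) { skipped_zero <- TRUE; next }
      w_desc <- if (t$kind[j] == "name") 1 else 0.8
      score <- w_desc * sum(index$ec[shared]) / denom
      if (score <= 0) next
      key <- list(score = score, kind = t$kind[j], nw = length(wd),
                  descriptor = t$descriptor[j])
      if (is.null(best) || key$score > best$score ||
          (key$score == best$score &&
           (rank_kind(key$kind) < rank_kind(best$kind) ||
            (key$kind == best$kind && key$nw < best$nw))))
        best <- key
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = id, score = best$score,
        match_kind = paste0("partial-", best$kind),
        matched_descriptor = best$descriptor, stringsAsFactors = FALSE)
  }
  if (skipped_zero)
    warning("descriptor(s) with zero total evidence content skipped")
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(-out$score, rank_kind(sub("^partial-", "", out$match_kind)),
               vapply(out$matched_descriptor, function(d)
                 length(descriptor_words(d, index$stopwords)), 0L),
               out$term_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rank_kind <- function(kind) ifelse(kind == "name", 1L, 2L)

#' Two-stage resolution of a surface string
#'
#' Exact match first; only when no descriptor equals the (case-folded)
#' surface is the partial-match stage run, and its top-ranked candidate
#' returned.
#'
#' @param surface Query string.
#' @param index A \code{chem_vocab_index}.
#' @return One-row data frame as [resolve_exact()], or \code{NULL} when
#'   neither stage finds a candidate.
#' @export
resolve <- function(surface, index) {
  if (is.na(surface) || !nzchar(trimws(surface))) return(NULL)
  hit <- resolve_exact(surface, index)
  if (!is.null(hit)) return(hit)
  ranked <- withCallingHandlers(resolve_partial(surface, index),
                                warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(ranked) == 0) return(NULL)
  ranked[1, , drop = FALSE]
}

#' Resolve every mention in a prediction set
#'
#' Convenience wrapper used after CRF recognition: attaches
#' \code{lexicon_id} and \code{score} to each mention via [resolve()];
#' mentions that cannot be resolved keep \code{lexicon_id = NA}.
#'
#' @param preds Named list \code{doc_id -> mention data frame}.
#' @param index A \code{chem_vocab_index}.
#' @return The prediction list with ids and scores filled in.
#' @export
resolve_mentions <- function(preds, index) {
  lapply(preds, function(df) {
    if (nrow(df) == 0) return(df)
    for (i in seq_len(nrow(df))) {
      r <- resolve(df$surface[i], index)
      if (!is.null(r)) {
        df$lexicon_id[i] <- r$term_id
        df$score[i] <- r$score
      }
    }
    df
  })
}
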