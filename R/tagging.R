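#' @name tagging
#' @title Five-tag encoding of chemical entity spans
#' @description Entity spans are encoded over the token sequence with five
#'   tags: \code{NO} (non-chemical token), \code{NE} (single-token entity),
#'   and \code{S-NE}/\code{M-NE}/\code{E-NE} for the start, middle and end
#'   tokens of a multi-token entity.  A two-token entity is
#'   \code{S-NE, E-NE}; a k-token entity has k-2 \code{M-NE} tokens.
NULL

CHEM_TAGS <- c("NO", "NE", "S-NE", "M-NE", "E-NE")

#' Encode entity spans as a tag sequence
#'
#' @param tokens Token data frame from [tokenize()].
#' @param entities Mention data frame; every entity boundary must coincide
#'   with a token boundary, otherwise an error names the entity and the
#'   offending token.
#' @return Character vector of tags, one per token.
#' @export
spans_to_tags <- function(tokens, entities) {
  tags <- rep("NO", nrow(tokens))
  if (is.null(entities) || nrow(entities) == 0) return(tags)
  for (i in seq_len(nrow(entities))) {
    s <- entities$start[i]; e <- entities$end[i]
    first <- which(tokens$start == s)
    last <- which(tokens$end == e)
    if (length(first) != 1L || length(last) != 1L || last < first) {
      inside <- which(tokens$start < e & tokens$end > s)
      tok_msg <- if (length(inside))
        paste0(" (token '", tokens$text[inside[1]], "' [",
               tokens$start[inside[1]], ",", tokens$end[inside[1]], "))")
      else ""
      stop("entity '", entities$surface[i], "' [", s, ",", e,
           ") is not aligned to token boundaries", tok_msg)
    }
    k <- last - first + 1L
    tags[first:last] <- if (k == 1L) "NE"
      else c("S-NE", rep("M-NE", k - 2L), "E-NE")
  }
  tags
}

#' Decode a tag sequence into entity spans
#'
#' Left-inverse of [spans_to_tags()] on well-formed sequences.  A
#' predicted sequence can be ill-formed; decoding is total, with the
#' following repairs (each logged in the \code{"repairs"} attribute):
#' \itemize{
#'   \item an entity opened by \code{S-NE}/\code{M-NE} but not closed by
#'     \code{E-NE} before a \code{NO}, \code{NE}, \code{S-NE} or the end of
#'     the sequence is closed at its last in-entity token;
#'   \item an orphan \code{M-NE} (no open entity) opens a new entity at
#'     that token;
#'   \item an orphan \code{E-NE} (no open entity) becomes a single-token
#'     entity.
#' }
#'
#' @param tokens Token data frame.
#' @param tags Character vector, one tag per token.
#' @param doc_id Document id attached to the decoded mentions.
#' @param text Optional document text used to recover exact surfaces
#'   (including inter-token characters inside multi-token entities).
#' @return Mention data frame; attribute \code{"repairs"} holds a character
#'   vector describing any repairs applied.
#' @export
tags_to_spans <- function(tokens, tags, doc_id = "doc", text = NULL) {
  if (length(tags) != nrow(tokens))
    stop("length(tags) must equal the number of tokens: ",
         length(tags), " vs ", nrow(tokens))
  bad <- setdiff(unique(tags), CHEM_TAGS)
  if (length(bad)) stop("unknown tags: ", paste(bad, collapse = ", "))
  repairs <- character()
  spans <- list()
  open <- NA_integer_  # index of first token of the open entity
  close_open <- function(last) {
    spans[[length(spans) + 1L]] <<- c(open, last)
    open <<- NA_integer_
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "NO") {
      if (!is.na(open)) {
        repairs <- c(repairs, paste0("dangling entity closed at token ", i - 1L))
        close_open(i - 1L)
      }
    } else if (t == "NE") {
      if (!is.na(open)) {
        repairs <- c(repairs, paste0("dangling entity closed at token ", i - 1L))
        close_open(i - 1L)
      }
      open <- i; close_open(i)
    } else if (t == "S-NE") {
      if (!is.na(open)) {
        repairs <- c(repairs, paste0("dangling entity closed at token ", i - 1L))
        close_open(i - 1L)
      }
      open <- i
    } else if (t == "M-NE") {
      if (is.na(open)) {
        repairs <- c(repairs, paste0("orphan M-NE opens entity at token ", i))
        open <- i
      }
    } else { # E-NE
      if (is.na(open)) {
        repairs <- c(repairs, paste0("orphan E-NE as single-token entity at token ", i))
        open <- i
      }
      close_open(i)
    }
  }
  if (!is.na(open)) {
    repairs <- c(repairs, paste0("dangling entity closed at token ", length(tags)))
    close_open(length(tags))
  }
  if (length(spans)) {
    first <- vapply(spans, `[`, 0, 1)
    last <- vapply(spans, `[`, 0, 2)
    start <- tokens$start[first]
    end <- tokens$end[last]
    surface <- if (!is.null(text)) substring(text, start + 1L, end)
      else vapply(seq_along(first), function(k)
        paste(tokens$text[first[k]:last[k]], collapse = " "), character(1))
    out <- mentions(doc_id, start, end, surface)
  } else out <- mentions()
  attr(out, "repairs") <- repairs
  out
}

#' Per-token feature sets for the sequence tagger
#'
#' Each token is represented by four features: its Porter \code{stem}, its
#' \code{prefix} and \code{suffix} (first/last three characters, the whole
#' token when shorter), and \code{is_number} (optional sign, digits, at
#' most one decimal point or comma).  Features are computed on the
#' lower-cased token, independently of context, and deterministically.
#'
#' @param tokens Token data frame or character vector of token texts.
#' @return Data frame with columns \code{stem}, \code{prefix},
#'   \code{suffix}, \code{is_number}, one row per token.
#' @examples
#' extract_features(c("compositions", "zinc", "12.5"))
#' @export
extract_features <- function(tokens) {
  txt <- if (is.data.frame(tokens)) tokens$text else tokens
  txt <- tolower(txt)
  n <- nchar(txt)
  data.frame(
    stem = porter_stem(txt),
    prefix = substr(txt, 1L, pmin(3L, n)),
    suffix = substr(txt, pmax(1L, n - 2L), n),
    is_number = grepl("^[+-]?[0-9]+([.,][0-9]+)?$", txt),
    stringsAsFactors = FALSE)
}

#' Read / write tagged token sequences (CoNLL-style)
#'
#' One token per line as \code{token TAB tag}; documents separated by a
#' blank line.  Used for training-data interchange.
#'
#' @param docs_tags List of data frames with columns \code{text},
#'   \code{tag}.
#' @param path File path.
#' @return For the reader, a list of data frames.
#' @export
write_tagged <- function(docs_tags, path) {
  blocks <- vapply(docs_tags, function(d)
    paste(paste(d$text, d$tag, sep = "\t"), collapse = "\n"), character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tagged
#' @export
read_tagged <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  grp <- cumsum(!nzchar(lines))
  lapply(split(lines[nzchar(lines)], grp[nzchar(lines)]), function(b) {
    parts <- strsplit(b, "\t", fixed = TRUE)
    data.frame(text = vapply(parts, `[`, "", 1),
               tag = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  })
}
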