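#' Construct an entity mention table
#'
#' Entity mentions are stored as a data frame with one row per mention:
#' \code{doc_id}, 0-based half-open character offsets \code{start} and
#' \code{end}, the \code{surface} string, an optional \code{lexicon_id}
#' (\code{NA} when the mention is not mapped to the lexicon, e.g.
#' \code{"CHEBI:16236"} when it is) and an optional confidence
#' \code{score} in [0, 1].
#'
#' @param doc_id,start,end,surface,lexicon_id,score Vectors, recycled to a
#'   common length.
#' @return A mention data frame in document order (sorted by \code{start}).
#' @export
mentions <- function(doc_id = character(), start = integer(), end = integer(),
                     surface = character(), lexicon_id = NA_character_,
                     score = NA_real_) {
  n <- max(length(doc_id), length(start), length(end), length(surface))
  df <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   surface = rep_len(as.character(surface), n),
                   lexicon_id = rep_len(as.character(lexicon_id), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  bad <- !is.na(df$lexicon_id) & !grepl("^[A-Za-z]+:[0-9]+$", df$lexicon_id)
  if (any(bad))
    stop("lexicon_id must match PREFIX:digits; offending: ",
         paste(unique(df$lexicon_id[bad]), collapse = ", "))
  if (any(df$end <= df$start))
    stop("mention spans must satisfy end > start")
  df
}

#' Construct an annotated document
#'
#' @param doc_id Document identifier (string).
#' @param text Full document text.
#' @param entities Mention data frame (see [mentions()]); gold entities must
#'   lie within the text, match their surface slice, and be mutually
#'   non-overlapping.
#' @return An object of class \code{chem_doc}.
#' @export
annotated_document <- function(doc_id, text, entities = mentions()) {
  doc <- structure(list(doc_id = as.character(doc_id),
                        text = as.character(text),
                        entities = entities),
                   class = "chem_doc")
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  e <- doc$entities
  if (nrow(e) == 0) return(invisible(doc))
  if (any(e$doc_id != doc$doc_id))
    stop("document ", doc$doc_id, ": entity rows carry a different doc_id")
  if (any(e$start < 0) || any(e$end > nchar(doc$text)))
    stop("document ", doc$doc_id, ": entity span outside text")
  slice <- substring(doc$text, e$start + 1L, e$end)
  bad <- which(slice != e$surface)
  if (length(bad))
    stop("document ", doc$doc_id, ": surface/span mismatch at [",
         e$start[bad[1]], ",", e$end[bad[1]], "): expected '",
         slice[bad[1]], "' got '", e$surface[bad[1]], "'")
  if (nrow(e) > 1) {
    ord <- order(e$start)
    if (any(e$start[ord][-1] < e$end[ord][-nrow(e)]))
      stop("document ", doc$doc_id, ": overlapping gold entities")
  }
  invisible(doc)
}

#' @exportS3Method base::print
print.chem_doc <- function(x, ...) {
  cat("<chem_doc>", x$doc_id, "-", nchar(x$text), "chars,",
      nrow(x$entities), "entities\n")
  invisible(x)
}

new_corpus <- function(docs) {
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  structure(docs, class = "chem_corpus")
}

#' @exportS3Method base::print
print.chem_corpus <- function(x, ...) {
  n_ent <- sum(vapply(x, function(d) nrow(d$entities), 0L))
  n_map <- sum(vapply(x, function(d) sum(!is.na(d$entities$lexicon_id)), 0L))
  cat("<chem_corpus> ", length(x), " documents, ", n_ent, " entities (",
      n_map, " mapped to the lexicon)\n", sep = "")
  invisible(x)
}

#' @export
`[.chem_corpus` <- function(x, i) new_corpus(unclass(x)[i])

#' Read a standoff-annotated corpus from a directory
#'
#' The on-disk layout is one plain-text UTF-8 file per document
#' (\code{<doc_id>.txt}) plus a single \code{annotations.tsv} holding
#' tab-separated records \code{doc_id, start, end, surface, lexicon_id}
#' (header line present; \code{"-"} encodes an absent lexicon id; offsets
#' 0-based half-open).  Every record is validated against its document
#' slice; a mismatch aborts with the offending document and offsets.
#'
#' @param path Directory containing the corpus.
#' @return A \code{chem_corpus}: a named list of [annotated_document()]s.
#' @export
read_corpus <- function(path) {
  if (!dir.exists(path)) stop("no such corpus directory: ", path)
  txts <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("corpus directory holds no .txt documents: ", path)
  ann_path <- file.path(path, "annotations.tsv")
  ann <- if (file.exists(ann_path)) {
    utils::read.delim(ann_path, stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "integer",
                                     "character", "character"),
                      quote = "", comment.char = "")
  } else {
    data.frame(doc_id = character(), start = integer(), end = integer(),
               surface = character(), lexicon_id = character())
  }
  ann$lexicon_id[ann$lexicon_id == "-"] <- NA_character_
  docs <- lapply(txts, function(f) {
    doc_id <- sub("\\.txt$", "", basename(f))
    text <- readChar(f, file.info(f)$size, useBytes = FALSE)
    Encoding(text) <- "UTF-8"
    rows <- ann[ann$doc_id == doc_id, , drop = FALSE]
    annotated_document(doc_id, text,
                       mentions(rows$doc_id, rows$start, rows$end,
                                rows$surface, rows$lexicon_id))
  })
  orphan <- setdiff(unique(ann$doc_id), sub("\\.txt$", "", basename(txts)))
  if (length(orphan))
    stop("annotations reference missing documents: ",
         paste(orphan, collapse = ", "))
  new_corpus(docs)
}

#' Write a corpus in the standoff directory layout
#'
#' Inverse of [read_corpus()]: read after write is the identity on the data
#' model, and writing an unchanged corpus a second time is byte-identical.
#'
#' @param corpus A \code{chem_corpus} or list of \code{chem_doc}.
#' @param path Output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  for (doc in corpus) validate_document(doc)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    con <- file(file.path(path, paste0(doc$doc_id, ".txt")),
                open = "wb")
    writeChar(enc2utf8(doc$text), con, eos = NULL, useBytes = TRUE)
    close(con)
  }
  ann <- do.call(rbind, c(lapply(corpus, `[[`, "entities"),
                          list(make.row.names = FALSE)))
  if (is.null(ann) || nrow(ann) == 0)
    ann <- mentions()
  ann <- ann[order(ann$doc_id, ann$start, ann$end), , drop = FALSE]
  out <- ann[, c("doc_id", "start", "end", "surface", "lexicon_id")]
  out$lexicon_id[is.na(out$lexicon_id)] <- "-"
  utils::write.table(out, file.path(path, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
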