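#' English stopword list used for vocabulary indexing
#'
#' A fixed, versioned list of common English function words removed from
#' descriptors and query strings before evidence-content computation.
#' Deliberately small and free of chemistry-bearing words (\code{"acid"},
#' \code{"group"}, \code{"oxide"} are never stopwords).
#'
#' @return Character vector of lower-case stopwords.
#' @export
chem_stopwords <- function() {
  c("a", "an", "the", "and", "or", "of", "in", "on", "for", "with", "to",
    "by", "at", "from", "as", "is", "are", "was", "were", "be", "been",
    "being", "it", "its", "this", "that", "these", "those", "which", "who",
    "whom", "what", "when", "where", "how", "not", "no", "nor", "but", "if",
    "then", "than", "so", "such", "both", "each", "other", "into", "over",
    "under", "between", "through", "during", "about", "any", "some", "most",
    "more", "very", "can", "will", "just", "also", "there", "here", "out",
    "up", "down", "own", "same", "after", "before", "via")
}

#' Load a chemical lexicon
#'
#' Reads a ChEBI-style lexicon: every term has a unique identifier, a
#' primary name, and zero or more synonyms.  Two on-disk formats are
#' supported: OBO 1.2 flat files (\code{[Term]} stanzas with \code{id:},
#' \code{name:} and \code{synonym:} lines; \code{is_obsolete: true} stanzas
#' are skipped; all synonym scopes are treated equally) and a TSV dialect
#' with columns \code{id TAB name TAB pipe-separated synonyms} (no header).
#'
#' @param path File to read.
#' @param format \code{"obo"}, \code{"tsv"}, or \code{"auto"} (by file
#'   extension, default).
#' @return A \code{chem_lexicon}: data frame with columns \code{term_id},
#'   \code{name}, and list-column \code{synonyms}.
#' @export
load_lexicon <- function(path, format = c("auto", "obo", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "tsv"
  lex <- if (format == "obo") parse_obo(path) else parse_lexicon_tsv(path)
  dup <- lex$term_id[duplicated(lex$term_id)]
  if (length(dup))
    stop("duplicate term ids in lexicon: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(lex$name) | is.na(lex$name)))
    stop("term without a name: ",
         paste(lex$term_id[!nzchar(lex$name) | is.na(lex$name)], collapse = ", "))
  class(lex) <- c("chem_lexicon", "data.frame")
  lex
}

new_lexicon <- function(term_id, name, synonyms) {
  df <- data.frame(term_id = as.character(term_id), name = as.character(name),
                   stringsAsFactors = FALSE)
  df$synonyms <- synonyms
  class(df) <- c("chem_lexicon", "data.frame")
  df
}

#' @exportS3Method base::print
print.chem_lexicon <- function(x, ...) {
  cat("<chem_lexicon> ", nrow(x), " terms, ",
      sum(lengths(x$synonyms)), " synonyms\n", sep = "")
  invisible(x)
}

parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character(); nms <- character(); syns <- list()
  for (k in seq_along(starts)) {
    if (trimws(lines[starts[k]]) != "[Term]") next
    body <- lines[(starts[k] + 1L):ends[k]]
    get <- function(key) {
      v <- body[startsWith(body, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    if (length(grep("^is_obsolete: *true", body))) next
    id <- get("id"); nm <- get("name")
    if (!length(id)) next
    if (!length(nm)) stop("OBO term without a name: ", id[1])
    sv <- get("synonym")
    # synonym: "text" SCOPE [xrefs]
    sv <- regmatches(sv, regexpr('(?<=^")[^"]*', sv, perl = TRUE))
    ids <- c(ids, id[1]); nms <- c(nms, nm[1])
    syns <- c(syns, list(unique(sv)))
  }
  new_lexicon(ids, nms, syns)
}

parse_lexicon_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  nms <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  syns <- lapply(parts, function(p) {
    if (length(p) >= 3 && nzchar(p[3]))
      unique(strsplit(p[3], "|", fixed = TRUE)[[1]]) else character()
  })
  new_lexicon(ids, nms, syns)
}

#' Write a lexicon in the TSV dialect
#' @param lexicon A \code{chem_lexicon}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- vapply(seq_len(nrow(lexicon)), function(i) {
    paste(lexicon$term_id[i], lexicon$name[i],
          paste(lexicon$synonyms[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

descriptors_of <- function(lexicon, i) {
  c(lexicon$name[i], lexicon$synonyms[[i]])
}

descriptor_words <- function(text, stopwords) {
  w <- unique(tolower(tokenize(text)$text))
  setdiff(w, stopwords)
}

#' Build the vocabulary index with per-word evidence content
#'
#' Every descriptor (name or synonym) of every term is tokenized with
#' [tokenize()], lower-cased and stopword-filtered.  The frequency count of
#' a word is the number of \emph{distinct} terms containing it in any
#' descriptor -- a word appearing in several descriptors of one term counts
#' once, so heavily synonymous terms carry no extra weight.  With
#' \code{f(w) = count(w) / n_terms}, the evidence content is
#' \code{EC(w) = -log f(w)}: a word present in every term has EC 0, a word
#' unique to one of N terms has EC log N.  Rare words therefore dominate
#' the partial-match score.
#'
#' A term whose descriptors all reduce to empty word sets after stopword
#' filtering would be unreachable; it is indexed on its raw lower-cased
#' words instead, with a warning.
#'
#' @param lexicon A \code{chem_lexicon} (non-empty).
#' @param stopwords Character vector of stopwords
#'   (default [chem_stopwords()]).
#' @param log_base Base of the logarithm in EC (default \code{exp(1)}).
#'   Partial-match scores are invariant to this choice; only reported EC
#'   values change.
#' @return A \code{chem_vocab_index} with components \code{ec} (named
#'   numeric), \code{terms_of} (word -> character vector of term ids),
#'   \code{terms} (per-term descriptor word sets and kinds),
#'   \code{name_of}/\code{syn_of} (case-folded exact lookup tables),
#'   \code{n_terms}, \code{stopwords}, \code{log_base}.
#' @export
build_index <- function(lexicon, stopwords = chem_stopwords(),
                        log_base = exp(1)) {
  stopifnot(nrow(lexicon) > 0)
  stopwords <- tolower(stopwords)
  terms <- vector("list", nrow(lexicon))
  names(terms) <- lexicon$term_id
  count <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lexicon))) {
    descs <- descriptors_of(lexicon, i)
    kinds <- c("name", rep("synonym", length(descs) - 1L))
    words <- lapply(descs, descriptor_words, stopwords = stopwords)
    if (all(lengths(words) == 0L)) {
      warning("term ", lexicon$term_id[i],
              ": all descriptors are stopwords; indexing raw words")
      words <- lapply(descs, function(d) unique(tolower(tokenize(d)$text)))
    }
    terms[[i]] <- list(descriptor = descs, kind = kinds, words = words)
    for (w in unique(unlist(words)))
      assign(w, c(if (exists(w, count, inherits = FALSE))
        get(w, count) else character(), lexicon$term_id[i]), envir = count)
  }
  n_terms <- nrow(lexicon)
  vocab <- ls(count)
  terms_of <- lapply(vocab, get, envir = count)
  names(terms_of) <- vocab
  cnt <- lengths(terms_of)
  ec <- -log(cnt / n_terms, base = log_base)
  names(ec) <- vocab
  structure(list(ec = ec, terms_of = terms_of, terms = terms,
                 name_of = exact_table(lexicon, names = TRUE),
                 syn_of = exact_table(lexicon, names = FALSE),
                 n_terms = n_terms, stopwords = stopwords,
                 log_base = log_base),
            class = "chem_vocab_index")
}

# case-folded descriptor string -> term ids
exact_table <- function(lexicon, names = TRUE) {
  keys <- character(); vals <- character()
  for (i in seq_len(nrow(lexicon))) {
    d <- if (names) lexicon$name[i] else lexicon$synonyms[[i]]
    if (length(d)) {
      keys <- c(keys, tolower(d))
      vals <- c(vals, rep(lexicon$term_id[i], length(d)))
    }
  }
  split(vals, keys)
}

#' @exportS3Method base::print
print.chem_vocab_index <- function(x, ...) {
  cat("<chem_vocab_index> ", x$n_terms, " terms, ", length(x$ec),
      " vocabulary words (log base ", format(x$log_base), ")\n", sep = "")
  invisible(x)
}

#' Persist / restore a vocabulary index
#'
#' The index is stored as a single JSON document so it can be inspected
#' and diffed; [read_index()] restores an identical object.
#'
#' @param index A \code{chem_vocab_index}.
#' @param path JSON file path.
#' @return \code{path} invisibly; for [read_index()], the index.
#' @export
write_index <- function(index, path) {
  jsonlite::write_json(
    list(ec = as.list(index$ec), terms_of = index$terms_of,
         terms = index$terms, name_of = index$name_of,
         syn_of = index$syn_of, n_terms = index$n_terms,
         stopwords = index$stopwords, log_base = index$log_base),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  idx <- list(
    ec = unlist(lapply(raw$ec, as.numeric)),
    terms_of = lapply(raw$terms_of, function(v) unlist(v, use.names = FALSE)),
    terms = lapply(raw$terms, function(t) list(
      descriptor = unlist(t$descriptor, use.names = FALSE),
      kind = unlist(t$kind, use.names = FALSE),
      words = lapply(t$words, function(v)
        as.character(unlist(v, use.names = FALSE))))),
    name_of = lapply(raw$name_of, function(v) unlist(v, use.names = FALSE)),
    syn_of = lapply(raw$syn_of, function(v) unlist(v, use.names = FALSE)),
    n_terms = as.integer(raw$n_terms[[1]]),
    stopwords = unlist(raw$stopwords, use.names = FALSE),
    log_base = as.numeric(raw$log_base[[1]]))
  names(idx$ec) <- names(raw$ec)
  structure(idx, class = "chem_vocab_index")
}
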