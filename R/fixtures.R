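#' Configuration for synthetic lexicons and corpora
#'
#' The generator emulates the structure of an annotated patent-style gold
#' standard at desk scale: documents of short template sentences embedding
#' chemical-like mentions with exact character offsets, a fraction of which
#' are mapped to a generated ChEBI-style lexicon.  Entity strings are built
#' from chemical morphology (stems such as \code{"chlor"}, \code{"benz"}
#' plus suffixes such as \code{"-ol"}, \code{"-ate"}, \code{"-ide"}, and
#' multiword patterns like \code{"<stem>ic acid"} or
#' \code{"zinc oxide"}-style element/anion pairs), while background words
#' come from a disjoint, non-chemical vocabulary -- so by default entity
#' and background tokens have separable suffix distributions.
#' \code{background_overlap} injects unannotated chemical-like words into
#' the background at the given rate, degrading that separability.
#'
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param n_terms Number of lexicon terms.
#' @param n_docs Number of documents.
#' @param entities_per_doc Length-2 integer range of mentions per document.
#' @param synonym_rate Probability that a term carries synonyms.
#' @param multiword_rate Probability that a generated name is multiword.
#' @param unmapped_rate Probability that a corpus mention is an
#'   out-of-lexicon chemical with no lexicon id; the default 0.463 leaves
#'   53.7\% of mentions mapped, the mapped fraction typical of a curated
#'   patent gold standard.
#' @param background_overlap Probability that a background word is replaced
#'   by an unannotated chemical-like word (0 = fully separable).
#' @param chemical_suffix_pool Suffixes used for single-word chemical
#'   names.
#' @param background_vocab Non-chemical background vocabulary.
#' @return A list of class \code{chem_fixture_config}.
#' @export
fixture_config <- function(seed = 1L, n_terms = 50L, n_docs = 10L,
                           entities_per_doc = c(5L, 15L),
                           synonym_rate = 0.3, multiword_rate = 0.3,
                           unmapped_rate = 0.463, background_overlap = 0,
                           chemical_suffix_pool = c("ol", "ane", "ene", "one",
                                                    "ate", "ide", "ine",
                                                    "ose", "yne", "oic"),
                           background_vocab = fixture_background_vocab()) {
  stopifnot(n_terms > 0, n_docs > 0, length(entities_per_doc) == 2,
            all(entities_per_doc > 0),
            synonym_rate >= 0, synonym_rate <= 1,
            multiword_rate >= 0, multiword_rate <= 1,
            unmapped_rate >= 0, unmapped_rate <= 1,
            background_overlap >= 0, background_overlap <= 1)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_docs = as.integer(n_docs),
                 entities_per_doc = as.integer(entities_per_doc),
                 synonym_rate = synonym_rate, multiword_rate = multiword_rate,
                 unmapped_rate = unmapped_rate,
                 background_overlap = background_overlap,
                 chemical_suffix_pool = chemical_suffix_pool,
                 background_vocab = background_vocab),
            class = "chem_fixture_config")
}

fixture_background_vocab <- function() {
  c("the", "a", "of", "and", "was", "with", "in", "to", "is", "for",
    "mixture", "reaction", "process", "product", "method", "sample",
    "treatment", "heated", "stirred", "cooled", "added", "prepared",
    "obtained", "yield", "container", "step", "filtered", "dried",
    "washed", "layer", "residue", "phase", "useful", "formulation",
    "agent", "present", "invention", "example", "preferred", "suitable",
    "amount", "weight", "percent", "range", "comprising", "wherein",
    "thereof", "material", "surface", "coating", "applied", "resulting",
    "described", "further", "under", "slowly", "then", "portion")
}

FIXTURE_STEMS <- c("meth", "eth", "prop", "but", "pent", "hex", "hept",
                   "oct", "non", "dec", "benz", "phen", "tolu", "xyl",
                   "chlor", "brom", "fluor", "iod", "sulf", "amin", "nitr",
                   "carb", "glyc", "oxal", "acet", "form", "lact", "malon",
                   "succin", "tartar", "citr", "fumar", "stear", "ole",
                   "palmit", "myrist", "laur", "capr", "valer", "glut")

FIXTURE_ELEMENTS <- c("zinc", "iron", "copper", "sodium", "potassium",
                      "calcium", "magnesium", "lithium", "barium", "silver")

FIXTURE_ANIONS <- c("oxide", "chloride", "sulfate", "nitrate", "carbonate",
                    "phosphate", "acetate", "citrate", "bromide", "iodide")

with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

fixture_chemical_word <- function(config) {
  stem <- paste0(sample(FIXTURE_STEMS, sample(1:2, 1)), collapse = "")
  paste0(stem, sample(config$chemical_suffix_pool, 1))
}

fixture_name <- function(config) {
  if (stats::runif(1) < config$multiword_rate) {
    if (stats::runif(1) < 0.5)
      paste0(sample(FIXTURE_STEMS, 1), "ic acid")
    else
      paste(sample(FIXTURE_ELEMENTS, 1), sample(FIXTURE_ANIONS, 1))
  } else fixture_chemical_word(config)
}

#' Generate a synthetic chemical lexicon
#'
#' Deterministic given \code{config$seed}: \code{n_terms} terms with
#' sequential ids, unique chemically shaped names and, at
#' \code{synonym_rate}, one or two synonyms formed by prefixing the name
#' with a stereo/locant-style modifier (\code{"d-"}, \code{"alpha-"}, ...).
#'
#' @param config A [fixture_config()].
#' @return A \code{chem_lexicon}.
#' @export
make_lexicon <- function(config = fixture_config()) {
  with_fixture_seed(config$seed, {
    names_ <- character(0)
    guard <- 0L
    while (length(names_) < config$n_terms && guard < 100000L) {
      nm <- fixture_name(config)
      if (!(nm %in% names_)) names_ <- c(names_, nm)
      guard <- guard + 1L
    }
    if (length(names_) < config$n_terms)
      stop("could not generate ", config$n_terms, " unique names; ",
           "enlarge the pools")
    prefixes <- c("d-", "l-", "dl-", "alpha-", "beta-", "gamma-", "ortho-",
                  "para-", "meta-", "n-")
    syns <- lapply(names_, function(nm) {
      if (stats::runif(1) < config$synonym_rate)
        paste0(sample(prefixes, sample(1:2, 1)), nm)
      else character()
    })
    new_lexicon(sprintf("CHEBI:%d", 10000L + seq_along(names_)),
                names_, syns)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Documents are sequences of template sentences over the background
#' vocabulary with chemical mentions embedded at exact character offsets.
#' Each mention is, with probability \code{1 - unmapped_rate}, a descriptor
#' sampled from the lexicon (gold \code{lexicon_id} set; names preferred
#' over synonyms 7:3) and otherwise a freshly generated out-of-lexicon
#' chemical string with no id.  Deterministic given \code{config$seed};
#' the generated documents satisfy all annotated-document invariants and
#' round-trip through [write_corpus()]/[read_corpus()].
#'
#' @param lexicon A \code{chem_lexicon} (non-empty).
#' @param config A [fixture_config()].
#' @return A \code{chem_corpus}.
#' @export
make_corpus <- function(lexicon, config = fixture_config()) {
  stopifnot(nrow(lexicon) > 0)
  all_desc <- tolower(unlist(lapply(seq_len(nrow(lexicon)), function(i)
    descriptors_of(lexicon, i)), use.names = FALSE))
  with_fixture_seed(config$seed + 9973L, {
    docs <- lapply(seq_len(config$n_docs), function(di) {
      doc_id <- sprintf("doc%02d", di)
      n_ent <- sample(seq(config$entities_per_doc[1],
                          config$entities_per_doc[2]), 1)
      words <- character(0)
      ent_rows <- list()
      pos <- 0L  # character position of the next word
      emit <- function(ws) {
        for (w in ws) {
          words <<- c(words, w)
          pos <<- pos + nchar(w) + 1L
        }
      }
      bg <- function(k) {
        ws <- sample(config$background_vocab, k, replace = TRUE)
        if (config$background_overlap > 0) {
          swap <- stats::runif(k) < config$background_overlap
          ws[swap] <- vapply(seq_len(sum(swap)),
                             function(i) fixture_chemical_word(config), "")
        }
        ws
      }
      remaining <- n_ent
      while (remaining > 0L) {
        in_sentence <- min(remaining, sample(1:2, 1))
        emit(bg(sample(3:6, 1)))
        for (k in seq_len(in_sentence)) {
          if (stats::runif(1) < config$unmapped_rate) {
            surf <- fixture_chemical_word(config)
            guard <- 0L
            while (tolower(surf) %in% all_desc && guard < 1000L) {
              surf <- fixture_chemical_word(config); guard <- guard + 1L
            }
            id <- NA_character_
          } else {
            ti <- sample(nrow(lexicon), 1)
            descs <- descriptors_of(lexicon, ti)
            surf <- if (length(descs) > 1 && stats::runif(1) < 0.3)
              sample(descs[-1], 1) else descs[1]
            id <- lexicon$term_id[ti]
          }
          s <- pos
          emit(strsplit(surf, " ", fixed = TRUE)[[1]])
          ent_rows[[length(ent_rows) + 1L]] <-
            data.frame(doc_id = doc_id, start = s,
                       end = pos - 1L, surface = surf, lexicon_id = id,
                       stringsAsFactors = FALSE)
          if (k < in_sentence) emit(bg(sample(2:4, 1)))
        }
        # close the sentence with background words and a period
        emit(bg(sample(2:4, 1)))
        words[length(words)] <- paste0(words[length(words)], ".")
        pos <- pos + 1L
        remaining <- remaining - in_sentence
      }
      ent <- do.call(rbind, ent_rows)
      text <- paste(words, collapse = " ")
      annotated_document(doc_id, text,
                         mentions(ent$doc_id, ent$start, ent$end,
                                  ent$surface, ent$lexicon_id))
    })
    new_corpus(docs)
  })
}

#' Generate lexicon and corpus together
#'
#' @param config A [fixture_config()].
#' @return List with elements \code{lexicon} and \code{corpus}.
#' @export
make_fixture <- function(config = fixture_config()) {
  lexicon <- make_lexicon(config)
  list(lexicon = lexicon, corpus = make_corpus(lexicon, config))
}
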