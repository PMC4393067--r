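# Shared fixtures built in code; nothing is read from disk.

# a small hand-written lexicon exercising names, synonyms and shared words
tiny_lexicon <- function() {
  chemner:::new_lexicon(
    term_id = c("CHEBI:16236", "CHEBI:15377", "CHEBI:27732",
                "CHEBI:28262", "CHEBI:16240"),
    name = c("ethanol", "water", "caffeine",
             "dimethyl sulfoxide", "hydrogen peroxide"),
    synonyms = list(c("ethyl alcohol", "alcohol"),
                    c("H2O", "aqua"),
                    c("1,3,7-trimethylxanthine"),
                    c("DMSO", "methyl sulfoxide"),
                    character()))
}

# memoized default fixture so expensive generation happens once per run
fixture_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, maker) {
    if (!exists(key, env, inherits = FALSE)) assign(key, maker(), env)
    get(key, env, inherits = FALSE)
  }
})

default_fixture <- function() {
  fixture_cache("default", function() make_fixture(fixture_config(seed = 1)))
}

# brute-force per-word term counts: naive triple loop with per-term sets
oracle_word_counts <- function(lexicon, stopwords = chem_stopwords()) {
  counts <- list()
  for (i in seq_len(nrow(lexicon))) {
    seen <- character()
    for (d in c(lexicon$name[i], lexicon$synonyms[[i]])) {
      for (w in setdiff(unique(tolower(tokenize(d)$text)), stopwords))
        seen <- union(seen, w)
    }
    for (w in seen)
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
  }
  counts
}

# brute-force partial-match scorer: enumerate every (term, descriptor) pair
oracle_partial_scores <- function(surface, lexicon, index) {
  qw <- setdiff(unique(tolower(tokenize(surface)$text)), index$stopwords)
  qw <- intersect(qw, names(index$ec))
  best <- list()
  for (i in seq_len(nrow(lexicon))) {
    id <- lexicon$term_id[i]
    descs <- c(lexicon$name[i], lexicon$synonyms[[i]])
    kinds <- c("name", rep("synonym", max(0, length(descs) - 1L)))
    for (j in seq_along(descs)) {
      wd <- setdiff(unique(tolower(tokenize(descs[j])$text)), index$stopwords)
      shared <- intersect(qw, wd)
      if (!length(shared)) next
      denom <- sum(index$ec[wd])
      if (denom == 0) next
      sc <- (if (kinds[j] == "name") 1 else 0.8) * sum(index$ec[shared]) / denom
      if (is.null(best[[id]]) || sc > best[[id]]) best[[id]] <- sc
    }
  }
  best
}

# independent recount of recognition TP by exhaustive greedy re-pairing
oracle_recount_tp <- function(gold, pred, mode) {
  pred_used <- rep(FALSE, nrow(pred))
  tp <- 0L
  g_ord <- order(gold$start, gold$end)
  p_ord <- order(pred$start, pred$end)
  for (gi in g_ord) {
    for (pi in p_ord) {
      if (pred_used[pi]) next
      ok <- switch(mode,
        exact = gold$start[gi] == pred$start[pi] && gold$end[gi] == pred$end[pi],
        left = gold$start[gi] == pred$start[pi],
        right = gold$end[gi] == pred$end[pi],
        left_right = gold$start[gi] == pred$start[pi] ||
          gold$end[gi] == pred$end[pi],
        partial = gold$start[gi] < pred$end[pi] &&
          pred$start[pi] < gold$end[gi])
      if (ok) { pred_used[pi] <- TRUE; tp <- tp + 1L; break }
    }
  }
  tp
}

# random mention set over a document for evaluation property tests
random_predictions <- function(doc, n, seed) {
  set.seed(seed)
  tokens <- tokenize(doc$text)
  if (nrow(tokens) < 2 || n == 0) return(mentions())
  starts <- integer(); ends <- integer()
  pos <- 1L
  while (length(starts) < n && pos < nrow(tokens)) {
    len <- sample(1:2, 1)
    last <- min(pos + len - 1L, nrow(tokens))
    if (stats::runif(1) < 0.6) {
      starts <- c(starts, tokens$start[pos])
      ends <- c(ends, tokens$end[last])
    }
    pos <- last + sample(1:3, 1)
  }
  if (!length(starts)) return(mentions())
  mentions(doc$doc_id, starts, ends,
           substring(doc$text, starts + 1L, ends))
}
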