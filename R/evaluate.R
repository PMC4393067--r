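#' @name evaluation
#' @title Boundary-matching evaluation of entity recognition and resolution
#' @description Predicted mentions are scored against gold mentions under
#'   five boundary assessments of decreasing strictness: \code{exact}
#'   (both boundaries agree), \code{left} (left boundary agrees),
#'   \code{right} (right boundary agrees), \code{left_right} (either
#'   boundary agrees) and \code{partial} (the spans overlap at all).
#'   Matching is one-to-one: a gold mention consumes at most one
#'   prediction and vice versa, so a single true-positive count serves
#'   both precision and recall.
NULL

EVAL_MODES <- c("exact", "left", "right", "left_right", "partial")

mode_admissible <- function(g_start, g_end, p_start, p_end, mode) {
  switch(mode,
         exact = g_start == p_start & g_end == p_end,
         left = g_start == p_start,
         right = g_end == p_end,
         left_right = g_start == p_start | g_end == p_end,
         partial = g_start < p_end & p_start < g_end,
         stop("unknown assessment mode: ", mode))
}

#' One-to-one matching of gold and predicted mentions
#'
#' Greedy pairing in document order: gold mentions are visited left to
#' right and each takes the leftmost admissible unmatched prediction.
#'
#' @param gold,pred Mention data frames for the \emph{same} document.
#' @param mode One of \code{"exact"}, \code{"left"}, \code{"right"},
#'   \code{"left_right"}, \code{"partial"}.
#' @return Data frame with columns \code{gold} and \code{pred} holding row
#'   indices of the matched pairs.
#' @export
match_mentions <- function(gold, pred, mode = EVAL_MODES) {
  mode <- match.arg(mode)
  if (nrow(gold) && nrow(pred) &&
      (length(unique(gold$doc_id)) > 1 || length(unique(pred$doc_id)) > 1 ||
       gold$doc_id[1] != pred$doc_id[1]))
    stop("match_mentions() operates on a single document at a time")
  pairs <- data.frame(gold = integer(), pred = integer())
  if (!nrow(gold) || !nrow(pred)) return(pairs)
  og <- order(gold$start, gold$end)
  op <- order(pred$start, pred$end)
  used <- rep(FALSE, nrow(pred))
  for (gi in og) {
    adm <- mode_admissible(gold$start[gi], gold$end[gi],
                           pred$start[op], pred$end[op], mode)
    k <- which(adm & !used[op])
    if (length(k)) {
      pi <- op[k[1]]
      used[pi] <- TRUE
      pairs <- rbind(pairs, data.frame(gold = gi, pred = pi))
    }
  }
  pairs
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build an evaluation report from pooled counts
#'
#' Precision, recall and F-measure as percentages:
#' P = 100 tp / n_pred (0 when n_pred = 0), R = 100 tp / n_gold,
#' F = 2PR/(P+R) (0 when P + R = 0), with F computed from the unrounded
#' P and R.  The print method rounds half-up to two decimals.
#'
#' @param tp True-positive count.
#' @param n_pred Total predicted mentions.
#' @param n_gold Total gold mentions.
#' @param mode Assessment mode label.
#' @param method Optional method label.
#' @return One-row data frame of class \code{chem_eval_report} with
#'   columns \code{mode}, \code{method}, \code{tp}, \code{n_pred},
#'   \code{n_gold}, \code{precision}, \code{recall}, \code{f_measure}
#'   (unrounded percentages).
#' @export
eval_report <- function(tp, n_pred, n_gold, mode = "exact", method = "") {
  precision <- if (n_pred > 0) 100 * tp / n_pred else 0
  recall <- if (n_gold > 0) 100 * tp / n_gold else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(data.frame(mode = mode, method = method, tp = tp,
                       n_pred = n_pred, n_gold = n_gold,
                       precision = precision, recall = recall,
                       f_measure = f, stringsAsFactors = FALSE),
            class = c("chem_eval_report", "data.frame"))
}

#' @exportS3Method base::print
print.chem_eval_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("precision", "recall", "f_measure"))
    y[[cl]] <- sprintf("%.2f", round_half_up(y[[cl]], 2))
  names(y) <- c("Assessment", "Method", "TP", "Predicted", "Gold",
                "Precision", "Recall", "F-measure")
  print(y, row.names = FALSE)
  invisible(x)
}

check_same_docs <- function(corpus, preds) {
  gd <- vapply(corpus, `[[`, "", "doc_id")
  if (!setequal(gd, names(preds)))
    stop("gold and prediction document sets differ: gold has {",
         paste(setdiff(gd, names(preds)), collapse = ", "),
         "}, predictions have {",
         paste(setdiff(names(preds), gd), collapse = ", "), "}")
  gd
}

#' Recognition evaluation over a corpus
#'
#' A true positive is a gold/predicted pair matched under the chosen
#' boundary assessment, pooled over documents.
#'
#' @param corpus Gold \code{chem_corpus}.
#' @param preds Named list \code{doc_id -> mention data frame}.
#' @param mode Assessment mode.
#' @return A \code{chem_eval_report}.
#' @export
recognition_report <- function(corpus, preds, mode = EVAL_MODES) {
  mode <- match.arg(mode)
  ids <- check_same_docs(corpus, preds)
  tp <- 0L; n_pred <- 0L; n_gold <- 0L
  for (id in ids) {
    g <- corpus[[id]]$entities; p <- preds[[id]]
    tp <- tp + nrow(match_mentions(g, p, mode))
    n_pred <- n_pred + nrow(p); n_gold <- n_gold + nrow(g)
  }
  eval_report(tp, n_pred, n_gold, mode)
}

#' Identification (recognition + resolution) evaluation
#'
#' As [recognition_report()], but a matched pair counts as a true positive
#' only when the predicted lexicon id equals the gold lexicon id.  Gold
#' mentions without a lexicon mapping should be removed beforehand with
#' [filter_mapped()], mirroring evaluation on the mapped subset of a gold
#' standard.
#'
#' @inheritParams recognition_report
#' @return A \code{chem_eval_report}.
#' @export
identification_report <- function(corpus, preds, mode = EVAL_MODES) {
  mode <- match.arg(mode)
  ids <- check_same_docs(corpus, preds)
  tp <- 0L; n_pred <- 0L; n_gold <- 0L
  for (id in ids) {
    g <- corpus[[id]]$entities; p <- preds[[id]]
    pairs <- match_mentions(g, p, mode)
    if (nrow(pairs))
      tp <- tp + sum(!is.na(g$lexicon_id[pairs$gold]) &
                     !is.na(p$lexicon_id[pairs$pred]) &
                     g$lexicon_id[pairs$gold] == p$lexicon_id[pairs$pred])
    n_pred <- n_pred + nrow(p); n_gold <- n_gold + nrow(g)
  }
  eval_report(tp, n_pred, n_gold, mode)
}

#' Restrict a corpus to lexicon-mapped gold mentions
#'
#' @param corpus A \code{chem_corpus}.
#' @return The corpus with unmapped gold mentions dropped.
#' @export
filter_mapped <- function(corpus) {
  new_corpus(lapply(corpus, function(d) {
    d$entities <- d$entities[!is.na(d$entities$lexicon_id), , drop = FALSE]
    rownames(d$entities) <- NULL
    d
  }))
}

#' Resolution evaluation restricted to the intersection of two systems
#'
#' Isolates resolution quality from recognition quality: the evaluation
#' set is the set of gold mentions recognized (matched under \code{mode})
#' by \emph{both} systems.  For each system, the true positives are the
#' members of that set whose predicted mapping agrees with gold; precision
#' is taken over the evaluation set and recall over the full mapped gold
#' subset.
#'
#' @param corpus Gold \code{chem_corpus} (mapped subset, see
#'   [filter_mapped()]).
#' @param preds_a,preds_b Prediction lists of the two systems.
#' @param mode Assessment mode.
#' @param methods Labels for the two systems.
#' @return List with elements \code{a} and \code{b}
#'   (\code{chem_eval_report}s) and \code{n_both} (the evaluation-set
#'   size).
#' @export
restricted_resolution_report <- function(corpus, preds_a, preds_b,
                                         mode = EVAL_MODES,
                                         methods = c("A", "B")) {
  mode <- match.arg(mode)
  ids <- check_same_docs(corpus, preds_a)
  check_same_docs(corpus, preds_b)
  n_both <- 0L; tp_a <- 0L; tp_b <- 0L; n_gold <- 0L
  for (id in ids) {
    g <- corpus[[id]]$entities
    n_gold <- n_gold + nrow(g)
    pa <- preds_a[[id]]; pb <- preds_b[[id]]
    ma <- match_mentions(g, pa, mode)
    mb <- match_mentions(g, pb, mode)
    both <- intersect(ma$gold, mb$gold)
    n_both <- n_both + length(both)
    if (length(both)) {
      ia <- ma$pred[match(both, ma$gold)]
      ib <- mb$pred[match(both, mb$gold)]
      agree <- function(p, pi) !is.na(g$lexicon_id[both]) &
        !is.na(p$lexicon_id[pi]) & g$lexicon_id[both] == p$lexicon_id[pi]
      tp_a <- tp_a + sum(agree(pa, ia))
      tp_b <- tp_b + sum(agree(pb, ib))
    }
  }
  list(a = eval_report(tp_a, n_both, n_gold, mode, methods[1]),
       b = eval_report(tp_b, n_both, n_gold, mode, methods[2]),
       n_both = n_both)
}

#' Full five-assessment report table
#'
#' @param corpus Gold corpus.
#' @param preds Prediction list.
#' @param kind \code{"recognition"} or \code{"identification"}.
#' @param method Method label.
#' @return A \code{chem_eval_report} with five rows, one per assessment.
#' @export
evaluation_table <- function(corpus, preds,
                             kind = c("recognition", "identification"),
                             method = "") {
  kind <- match.arg(kind)
  fn <- if (kind == "recognition") recognition_report else identification_report
  rows <- lapply(EVAL_MODES, function(m) fn(corpus, preds, m))
  out <- do.call(rbind, rows)
  out$method <- method
  class(out) <- c("chem_eval_report", "data.frame")
  out
}
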