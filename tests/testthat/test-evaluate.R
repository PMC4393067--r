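test_that("mode predicates admit exactly the documented pairs", {
  g <- mentions("d", 10L, 20L, "abcdefghij")
  same <- mentions("d", 10L, 20L, "abcdefghij")
  right_only <- mentions("d", 14L, 20L, "efghij")
  disjoint <- mentions("d", 25L, 30L, "vwxyz")
  for (m in c("exact", "left", "right", "left_right", "partial"))
    expect_equal(nrow(match_mentions(g, same, m)), 1L, info = m)
  hits <- vapply(c("exact", "left", "right", "left_right", "partial"),
                 function(m) nrow(match_mentions(g, right_only, m)), 0L)
  expect_equal(unname(hits), c(0L, 0L, 1L, 1L, 1L))
  for (m in c("exact", "left", "right", "left_right", "partial"))
    expect_equal(nrow(match_mentions(g, disjoint, m)), 0L, info = m)
})

test_that("matching is one-to-one: no mention is counted twice", {
  g <- mentions("d", c(0L, 10L), c(5L, 15L), c("aaaaa", "bbbbb"))
  p <- mentions("d", 0L, 15L, "aaaaa bbbb")
  # one prediction overlapping two golds can only pair once in partial mode
  expect_equal(nrow(match_mentions(g, p, "partial")), 1L)
  p2 <- mentions("d", c(0L, 2L), c(5L, 7L), c("aaaaa", "aaabb"))
  # two predictions overlapping one gold: the leftmost pairs, once
  pairs <- match_mentions(g[1, ], p2, "partial")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$pred, 1L)
})

test_that("cross-document mention lists are rejected", {
  g <- mentions("d1", 0L, 5L, "aaaaa")
  p <- mentions("d2", 0L, 5L, "aaaaa")
  expect_error(match_mentions(g, p, "exact"), "single document")
})

test_that("precision, recall and F recompute published-style table rows", {
  # full-corpus recognition, dictionary row, exact assessment
  r <- eval_report(5868, 18683, 18061)
  expect_equal(chemner:::round_half_up(r$precision, 2), 31.41)
  expect_equal(chemner:::round_half_up(r$recall, 2), 32.49)
  expect_equal(chemner:::round_half_up(r$f_measure, 2), 31.94)
  # machine-learning row, recall side and F from unrounded P and R
  r <- eval_report(9094, 13832, 18061)
  expect_equal(chemner:::round_half_up(r$recall, 2), 50.35)
  expect_equal(chemner:::round_half_up(r$f_measure, 2), 57.03)
})

test_that("degenerate counts give zero scores without dividing by zero", {
  r <- eval_report(0, 0, 10)
  expect_equal(r$precision, 0)
  expect_equal(r$recall, 0)
  expect_equal(r$f_measure, 0)
  r <- eval_report(0, 5, 0)
  expect_equal(r$f_measure, 0)
})

test_that("F never exceeds max(P, R) and is symmetric in P and R", {
  set.seed(4)
  for (i in 1:50) {
    tp <- sample(0:50, 1)
    np <- tp + sample(0:50, 1)
    ng <- tp + sample(0:50, 1)
    r <- eval_report(tp, np, ng)
    expect_lte(r$f_measure, max(r$precision, r$recall) + 1e-9)
    swapped <- eval_report(tp, ng, np)
    expect_equal(swapped$f_measure, r$f_measure)
    expect_true(r$precision >= 0 && r$precision <= 100)
    expect_true(r$recall >= 0 && r$recall <= 100)
  }
})

test_that("pooled recognition reports equal a brute-force recount", {
  fx <- default_fixture()
  preds <- lapply(fx$corpus, function(d)
    random_predictions(d, n = 8, seed = 100 + nchar(d$doc_id) + d$entities$start[1]))
  names(preds) <- names(fx$corpus)
  for (m in c("exact", "left", "right", "left_right", "partial")) {
    rep <- recognition_report(fx$corpus, preds, m)
    tp_oracle <- sum(vapply(names(fx$corpus), function(id)
      oracle_recount_tp(fx$corpus[[id]]$entities, preds[[id]], m), 0L))
    expect_equal(rep$tp, tp_oracle, info = m)
    expect_equal(rep$n_gold,
                 sum(vapply(fx$corpus, function(d) nrow(d$entities), 0L)))
  }
})

test_that("relaxing the assessment never lowers the true-positive count", {
  fx <- default_fixture()
  pred_sets <- list(
    dict = dict_recognize_corpus(fx$lexicon, fx$corpus),
    noisy = {
      p <- lapply(fx$corpus, function(d) random_predictions(d, 10, 7))
      names(p) <- names(fx$corpus); p
    })
  for (preds in pred_sets) {
    tp <- vapply(c("exact", "left", "right", "left_right", "partial"),
                 function(m) recognition_report(fx$corpus, preds, m)$tp, 0)
    expect_lte(tp[["exact"]], tp[["left"]])
    expect_lte(tp[["exact"]], tp[["right"]])
    expect_lte(tp[["left"]], tp[["left_right"]])
    expect_lte(tp[["right"]], tp[["left_right"]])
    expect_lte(tp[["left_right"]], tp[["partial"]])
  }
})

test_that("identification never counts more true positives than recognition", {
  fx <- default_fixture()
  mapped <- filter_mapped(fx$corpus)
  preds <- dict_recognize_corpus(fx$lexicon, mapped)
  for (m in c("exact", "partial")) {
    rec <- recognition_report(mapped, preds, m)
    idn <- identification_report(mapped, preds, m)
    expect_lte(idn$tp, rec$tp)
    expect_equal(idn$n_gold, rec$n_gold)
  }
  # a span match with the wrong id is not an identification TP
  g <- chemner:::new_corpus(list(annotated_document(
    "d", "trehalose sample",
    mentions("d", 0L, 9L, "trehalose", "CHEBI:27082"))))
  p <- list(d = mentions("d", 0L, 9L, "trehalose", "CHEBI:16551"))
  expect_equal(recognition_report(g, p, "exact")$tp, 1L)
  expect_equal(identification_report(g, p, "exact")$tp, 0L)
})

test_that("doc id mismatches between gold and predictions are errors", {
  fx <- default_fixture()
  preds <- dict_recognize_corpus(fx$lexicon, fx$corpus)
  expect_error(recognition_report(fx$corpus, preds[-1], "exact"), "differ")
})

test_that("restricted resolution evaluates only jointly recognized mentions", {
  text <- "zinc oxide with trehalose and ethanol mixed"
  gold <- chemner:::new_corpus(list(annotated_document(
    "d", text,
    mentions("d", c(0L, 16L, 30L), c(10L, 25L, 37L),
             c("zinc oxide", "trehalose", "ethanol"),
             c("CHEBI:1", "CHEBI:2", "CHEBI:3")))))
  # system A recognizes all three, one with a wrong id
  pa <- list(d = mentions("d", c(0L, 16L, 30L), c(10L, 25L, 37L),
                          c("zinc oxide", "trehalose", "ethanol"),
                          c("CHEBI:1", "CHEBI:9", "CHEBI:3")))
  # system B misses ethanol entirely
  pb <- list(d = mentions("d", c(0L, 16L), c(10L, 25L),
                          c("zinc oxide", "trehalose"),
                          c("CHEBI:1", "CHEBI:2")))
  out <- restricted_resolution_report(gold, pa, pb, "exact")
  expect_equal(out$n_both, 2L)           # zinc oxide + trehalose
  expect_equal(out$a$tp, 1L)             # A got trehalose wrong
  expect_equal(out$b$tp, 2L)
  expect_equal(out$a$precision, 100 * 1 / 2)
  expect_equal(out$b$recall, 100 * 2 / 3)
})

test_that("identical correct systems score 100 precision on the intersection", {
  fx <- default_fixture()
  mapped <- filter_mapped(fx$corpus)
  perfect <- lapply(mapped, function(d) d$entities)
  names(perfect) <- names(mapped)
  out <- restricted_resolution_report(mapped, perfect, perfect, "exact")
  n_gold <- sum(vapply(mapped, function(d) nrow(d$entities), 0L))
  expect_equal(out$n_both, n_gold)
  expect_equal(out$a$precision, 100)
  expect_equal(out$a$recall, 100 * out$n_both / n_gold)
})

test_that("five-row evaluation tables carry all assessments", {
  fx <- default_fixture()
  preds <- dict_recognize_corpus(fx$lexicon, fx$corpus)
  tab <- evaluation_table(fx$corpus, preds, "recognition", "dictionary")
  expect_equal(tab$mode, c("exact", "left", "right", "left_right", "partial"))
  expect_true(all(tab$method == "dictionary"))
})
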