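test_that("the oligomeric-salt sentence is tagged NO,S-NE,M-NE,E-NE,NO,NO,NE", {
  text <- "an oligomeric amdioamine salt and an amidoquat"
  toks <- tokenize(text)
  ents <- mentions("d", c(3L, 37L), c(29L, 46L),
                   c("oligomeric amdioamine salt", "amidoquat"))
  expect_equal(spans_to_tags(toks, ents),
               c("NO", "S-NE", "M-NE", "E-NE", "NO", "NO", "NE"))
  # and decoding recovers the exact character spans
  back <- tags_to_spans(toks, spans_to_tags(toks, ents), "d", text)
  expect_equal(back$start, ents$start)
  expect_equal(back$end, ents$end)
  expect_equal(back$surface, ents$surface)
})

test_that("the cosmetic sentence reproduces the full printed feature table", {
  text <- "cosmetic compositions containing colostrum, tocopherols, zinc oxide and hyaluronic acid"
  toks <- tokenize(text)
  ents <- mentions("d",
                   start = c(44L, 57L, 72L),
                   end = c(55L, 67L, 87L),
                   surface = c("tocopherols", "zinc oxide", "hyaluronic acid"))
  expect_equal(spans_to_tags(toks, ents),
               c("NO", "NO", "NO", "NO", "NE", "S-NE", "E-NE", "NO",
                 "S-NE", "E-NE"))
  feats <- extract_features(toks)
  expect_equal(feats$stem,
               c("cosmet", "composit", "contain", "colostrum", "tocopherol",
                 "zinc", "oxid", "and", "hyaluron", "acid"))
  expect_equal(feats$prefix,
               c("cos", "com", "con", "col", "toc", "zin", "oxi", "and",
                 "hya", "aci"))
  expect_equal(feats$suffix,
               c("tic", "ons", "ing", "rum", "ols", "inc", "ide", "and",
                 "nic", "cid"))
  expect_false(any(feats$is_number))
})

test_that("sequences without entities are all NO and decode to nothing", {
  toks <- tokenize("nothing chemical to see here")
  expect_equal(spans_to_tags(toks, mentions()), rep("NO", 5))
  expect_equal(nrow(tags_to_spans(toks, rep("NO", 5))), 0L)
})

test_that("entity boundaries inside a token are rejected with context", {
  toks <- tokenize("dimethylbenzene here")
  expect_error(
    spans_to_tags(toks, mentions("d", 0L, 8L, "dimethyl")),
    "dimethyl.*not aligned.*dimethylbenzene")
})

test_that("tags_to_spans requires one tag per token and known tags", {
  toks <- tokenize("a b c")
  expect_error(tags_to_spans(toks, c("NO", "NO")), "length")
  expect_error(tags_to_spans(toks, c("NO", "XX", "NO")), "unknown tags")
})

test_that("every invalid two-tag pattern is repaired per the documented table", {
  toks <- tokenize("alpha beta")
  dec <- function(tags) {
    out <- tags_to_spans(toks, tags)
    m <- unname(as.matrix(out[, c("start", "end")]))
    storage.mode(m) <- "integer"
    list(spans = m, repaired = length(attr(out, "repairs")) > 0)
  }
  span1 <- matrix(c(0L, 5L), 1)         # first token only
  span2 <- matrix(c(6L, 10L), 1)        # second token only
  span12 <- matrix(c(0L, 10L), 1)       # both tokens as one entity
  both <- rbind(span1, span2)           # two single-token entities
  cases <- list(
    # valid patterns first: no repairs
    list(c("NO", "NO"),     matrix(integer(), 0, 2), FALSE),
    list(c("NE", "NO"),     span1, FALSE),
    list(c("NO", "NE"),     span2, FALSE),
    list(c("NE", "NE"),     both, FALSE),
    list(c("S-NE", "E-NE"), span12, FALSE),
    # dangling starts
    list(c("S-NE", "NO"),   span1, TRUE),
    list(c("S-NE", "NE"),   both, TRUE),
    list(c("S-NE", "S-NE"), both, TRUE),
    list(c("S-NE", "M-NE"), span12, TRUE),   # closed at sequence end
    list(c("NO", "S-NE"),   span2, TRUE),
    list(c("NE", "S-NE"),   both, TRUE),
    # orphan middles: open an entity at that token
    list(c("M-NE", "NO"),   span1, TRUE),
    list(c("M-NE", "NE"),   both, TRUE),
    list(c("M-NE", "E-NE"), span12, TRUE),
    list(c("M-NE", "M-NE"), span12, TRUE),
    list(c("M-NE", "S-NE"), both, TRUE),
    list(c("NO", "M-NE"),   span2, TRUE),
    list(c("NE", "M-NE"),   both, TRUE),
    # orphan ends: single-token entity
    list(c("E-NE", "NO"),   span1, TRUE),
    list(c("E-NE", "E-NE"), both, TRUE),
    list(c("NO", "E-NE"),   span2, TRUE),
    list(c("NE", "E-NE"),   both, TRUE),
    list(c("E-NE", "NE"),   both, TRUE),
    list(c("E-NE", "S-NE"), both, TRUE),
    list(c("E-NE", "M-NE"), both, TRUE),
    list(c("S-NE", "E-NE"), span12, FALSE))
  for (cs in cases) {
    got <- dec(cs[[1]])
    expect_equal(got$spans, cs[[2]], info = paste(cs[[1]], collapse = ","))
    expect_equal(got$repaired, cs[[3]], info = paste(cs[[1]], collapse = ","))
  }
})

test_that("span encoding and decoding are inverse on generated corpora", {
  fx <- default_fixture()
  for (doc in fx$corpus) {
    toks <- tokenize(doc$text)
    tags <- spans_to_tags(toks, doc$entities)
    # grammar of valid sequences: M-NE/E-NE only after S-NE or M-NE
    prev <- c("NO", tags[-length(tags)])
    expect_true(all(!(tags %in% c("M-NE", "E-NE")) |
                    prev %in% c("S-NE", "M-NE")))
    expect_false(tags[length(tags)] == "S-NE")
    back <- tags_to_spans(toks, tags, doc$doc_id, doc$text)
    expect_length(attr(back, "repairs"), 0)
    expect_equal(back$start, doc$entities$start)
    expect_equal(back$end, doc$entities$end)
    expect_equal(back$surface, doc$entities$surface)
  }
})

test_that("number detection matches the documented numeric pattern", {
  feats <- extract_features(c("123", "12.5", "12,5", "-7", "+3.14",
                              "H2O", "1,2-diol", "12.5.3", "mg"))
  expect_equal(feats$is_number,
               c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("tagged sequences round-trip through the CoNLL-style format", {
  fx <- default_fixture()
  docs_tags <- lapply(fx$corpus[1:3], function(d) {
    toks <- tokenize(d$text)
    data.frame(text = toks$text, tag = spans_to_tags(toks, d$entities),
               stringsAsFactors = FALSE)
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tagged(docs_tags, f)
  back <- read_tagged(f)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$text, docs_tags[[i]]$text)
    expect_equal(back[[i]]$tag, docs_tags[[i]]$tag)
  }
})
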