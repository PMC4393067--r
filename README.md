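# chemner

Chemical named entity recognition and resolution to a ChEBI-style lexicon,
in R.

Chemical mentions pervade patents and the biomedical literature, but two
obstacles make them hard to mine: the space of compound names is open-ended
(new chemicals are synthesized constantly, so no dictionary is complete),
and chemical nomenclature is wildly ambiguous (one compound may appear as a
trivial name, a systematic name, a formula, or a registry number).
`chemner` implements both of the classic strategies side by side, plus the
apparatus needed to compare them fairly:

* a **dictionary-independent sequence tagger**: a linear-chain conditional
  random field (CRF) over a five-tag encoding of entity boundaries, using
  only surface features of each token — its Porter stem, three-character
  prefix and suffix, and a numeric-token flag;
* a **dictionary baseline**: exact, longest-match recognition of lexicon
  descriptors in text, where resolution comes for free (each match carries
  its term id) but common-word synonyms ("can", "group", "all") produce
  characteristic false positives;
* a **two-stage lexical resolver** that maps a recognized string to a term
  identifier with a confidence score;
* a **five-mode boundary-matching evaluator** (exact, left, right,
  left/right, partial) for recognition, identification (recognition +
  resolution) and intersection-restricted resolution;
* a **synthetic corpus and lexicon generator**, so everything above is
  testable end to end without downloading any external resource.

## The resolution model

Descriptors of a term are its name and synonyms.  In a preprocessing step
every descriptor is tokenized, lower-cased and stopword-filtered, and each
vocabulary word *w* receives an *evidence content*

```
EC(w) = -log f(w),     f(w) = (number of terms containing w) / (number of terms)
```

where a word occurring in several descriptors of one term is counted once.
Ubiquitous words carry no evidence (EC = 0); a word unique to one of *N*
terms carries EC = log *N*.

Resolution of a surface string is exact match first: if the case-folded
string equals a term's name the score is **1.0**, if it equals a synonym,
**0.8**.  Only when the exact stage fails does the partial stage run: every
descriptor *t<sub>d</sub>* sharing a word with the query *q* is scored with
the evidence-weighted Jaccard similarity

```
Sim_PM(q, t_d) = desc × Σ_{w ∈ q ∩ t_d} EC(w) / Σ_{w ∈ t_d} EC(w)
```

with *desc* = 1 for names and 0.8 for synonyms, and the best-scoring
descriptor wins.  Rare shared words therefore dominate the ranking, and
the score is invariant to the logarithm base used for EC.

## Worked example

Everything below is runnable as-is: the corpus and lexicon are generated,
not downloaded.

```r
library(chemner)

fx <- make_fixture(fixture_config(seed = 42, n_docs = 4, n_terms = 30))
fx$corpus
#> <chem_corpus> 4 documents, 44 entities (28 mapped to the lexicon)

idx <- build_index(fx$lexicon)
resolve(paste(fx$lexicon$name[2], "crystals"), idx)
#>       term_id score   match_kind matched_descriptor
#> 1 CHEBI:10002     1 partial-name         iodoxaline
```

The query "iodoxaline crystals" matches no descriptor exactly, so the
partial stage runs; the query's words fully cover the name "iodoxaline"
(and "crystals" is not a vocabulary word), giving the maximal score 1 for
a name match.

```r
dict <- dict_recognize_corpus(fx$lexicon, fx$corpus)
recognition_report(fx$corpus, dict, "exact")
#>  Assessment Method TP Predicted Gold Precision Recall F-measure
#>       exact        28        28   44    100.00  63.64     77.78
```

The dictionary recognizes exactly the 28 mentions that exist in the
lexicon — perfect precision on this clean corpus, but it cannot see the 16
out-of-lexicon mentions, capping recall at 63.6%.  The CRF has no such
ceiling:

```r
model <- crf_train(fx$corpus[1:3], crf_config())
model
#> <chem_crf> linear-chain CRF, 629 features, trained on 3 documents
#>   template stem-prefix-suffix-number/w1/v1, l2 = 0.1, max_iter = 200, seed = 42

head(predict(model, fx$corpus[[4]]), 3)
#>   doc_id start end    surface lexicon_id score
#> 1  doc04    43  53 iodoxaline       <NA>    NA
#> 2  doc04    84  93  myristate       <NA>    NA
#> 3  doc04   242 252 ethpropide       <NA>    NA
```

Predicted mentions carry no lexicon id — resolution is a separate step
(`resolve_mentions(preds, idx)`).  For an unbiased protocol over a whole
corpus use `leave_one_out()`, which tags every document with a model
trained on all the others.

```r
evaluation_table(fx$corpus[4],
                 list(doc04 = predict(model, fx$corpus[[4]])),
                 "recognition", "crf")
#>  Assessment Method TP Predicted Gold Precision Recall F-measure
#>       exact    crf  6         6   10    100.00  60.00     75.00
#>        left    crf  6         6   10    100.00  60.00     75.00
#>       right    crf  6         6   10    100.00  60.00     75.00
#>  left_right    crf  6         6   10    100.00  60.00     75.00
#>     partial    crf  6         6   10    100.00  60.00     75.00
```

A command-line wrapper with `simulate`, `build-index`, `train`, `tag`,
`tag-dict`, `resolve`, `evaluate` and `loocv` subcommands is installed at
`system.file("scripts", "chemner", package = "chemner")`.

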