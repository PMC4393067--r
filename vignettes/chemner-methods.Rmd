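---
title: "Methods: chemical entity recognition and resolution in chemner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical entity recognition and resolution in chemner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its models and of the design
choices behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic experiments do and do not show
about real text.

```{r setup, message = FALSE}
library(chemner)
```

## Tokenization

Chemical text defeats ordinary word tokenizers: systematic names such as
`1,2-dimethylbenzene` or `2-(acetyloxy)benzoic acid` contain commas,
hyphens, parentheses and digits that must not split the name.  `tokenize()`
implements a small, fully documented rule set: whitespace always splits; a
maximal run of punctuation characters flanked on both sides by alphanumeric
characters stays inside the token; all other punctuation is detached and
dropped, so the output contains only tokens with at least one alphanumeric
character.  Offsets are 0-based and half-open, the unambiguous convention
for slicing.

```{r}
tokenize("1,2-dimethylbenzene was added.")
```

Two consequences are worth knowing.  First, sentence punctuation between
letters is kept (`12.5` is one token), which is what the numeric feature
expects.  Second, dropping punctuation-only tokens means the tag sequence
of a sentence has exactly one tag per word-like token; nothing in the
pipeline depends on sentence segmentation, which is deliberately not
implemented.

## The five-tag encoding and token features

Entity spans are encoded over tokens with five tags: `NO` outside,
`NE` for a single-token entity, and `S-NE`/`M-NE`/`E-NE` for the start,
middle(s) and end of a multi-token entity.  This is richer than plain
BIO: the tagger learns separate behavior for opening, continuing and
closing a name, which suits long systematic chemical names.

Each token is represented by exactly four features, computed on the
lower-cased token, independent of context:

* the **Porter stem** (`compositions` → `composit`, `oxide` → `oxid`) —
  the classic 1980 suffix-stripping algorithm, implemented in the package
  because no stemmer is among its dependencies;
* **prefix** and **suffix**: the first and last three characters, the
  whole token when shorter;
* **is_number**: optional sign, digits, at most one decimal point or
  comma.

Deliberately absent: part-of-speech tags, word shapes, and any
dictionary-membership feature.  The point of the tagger is to be fully
dictionary-independent, so that its comparison against the dictionary
baseline measures the modeling approach, not lexicon access.

Decoding a predicted tag sequence back to spans must be total even though
the tagger can emit ill-formed sequences.  `tags_to_spans()` applies a
fixed repair table — a dangling `S-NE`/`M-NE` run is closed at its last
token, an orphan `M-NE` opens an entity, an orphan `E-NE` becomes a
single-token entity — and logs every repair in a `"repairs"` attribute so
downstream audits can quantify how often the model produced invalid
structure.

## The CRF tagger

`crf_train()` fits a first-order linear-chain conditional random field:
state features are indicators of the four-feature quadruple of the current
token and of its neighbours at offsets ±1 (a minimal context window,
standard for chain CRFs), plus begin/end-of-sequence markers; transition
weights cover all tag bigrams and a start row.  The objective is the
L2-penalized negative log-likelihood, minimized with L-BFGS from a zero
start; gradients come from log-domain forward–backward, prediction from
Viterbi.  Because the objective is convex and the start deterministic,
training is reproducible bit for bit; the seed exists for protocol-level
bookkeeping (per-fold derivation in cross-validation), not because the fit
is stochastic.

Tunable parameters, all in `crf_config()`:

* `l2` (default 0.1): regularization strength, dimensionless.  Small
  values favor recall on sparse synthetic data; the default is a
  conventional middle ground and was fixed before the experiments below.
* `max_iter` (default 200): L-BFGS iteration cap; fits on the synthetic
  corpora converge well before it.
* `window` (default 1): context half-width of the feature template.

`leave_one_out()` implements the evaluation protocol used throughout:
every document is tagged by a model trained on all remaining documents, so
predictions are never produced by a model that saw its own annotations.
Each fold's metadata records the training document ids, which the test
suite asserts never contain the evaluated document.

## The dictionary baseline

`dict_recognize()` re-implements the behavior of dictionary pipelines
locally: case-insensitive, token-boundary-aligned exact matching of every
descriptor, longest match first, ties broken leftmost then by smallest
term id, with resolution intrinsic to the match.  No stemming or plural
handling is applied — the baseline is *exact* matching by design, and its
characteristic failure modes are reproduced faithfully: common-word
synonyms fire in non-chemical contexts, and when a specific synonym
(e.g. a stereo-prefixed form) matches, the baseline reports that specific
term even where a curator would have chosen the generic one.

## Resolution: evidence content and weighted Jaccard

The resolver treats the lexicon purely lexically.  Let the descriptors of
a term be its name and synonyms.  After tokenization, case folding and
stopword removal, each vocabulary word receives an evidence content

$$EC(w) = -\log f(w), \qquad f(w) = \frac{|\{t : w \in \mathrm{desc}(t)\}|}{n_{terms}}$$

with per-term deduplication: a word in many synonyms of one term counts
once, so heavily synonymous terms gain no weight.  The denominator is the
total number of terms, making $f \in (0, 1]$ and $EC = 0$ exactly for
words present in every term.

Resolution is two-stage.  The exact stage compares the case-folded query
against whole descriptors: a name match scores 1.0, a synonym match 0.8.
Only if it fails does the partial stage score every descriptor $t_d$
sharing at least one word with the query $q$:

$$Sim_{PM} = desc \times \frac{\sum_{w \in q \cap t_d} EC(w)}{\sum_{w \in t_d} EC(w)},$$

$desc$ being 1 for names and 0.8 for synonyms.  Per term only the best
descriptor is kept, and terms are ranked by score.

Design choices that were genuinely open, and how they were settled:

* **Equality, not containment.**  "The query contains a descriptor" could
  be read as substring containment, but that would let `dimethyl
  sulphate` exact-match the descriptor `methyl` with score 1 — absurd
  given the score semantics.  The exact stage therefore uses whole-string
  equality (case-folded); a query that merely covers a descriptor's words
  still reaches score $desc$ through the partial stage, which is the
  behavior one actually wants.
* **Logarithm base: natural.**  $Sim_{PM}$ is a ratio of EC sums, so the
  base cancels; only reported EC values depend on it.  The test suite
  verifies score invariance under a base-2 rebuild of the index.
* **Stopwords.**  No canonical list exists for this task, so the package
  ships a fixed, versioned list of about seventy English function words
  (`chem_stopwords()`), deliberately excluding chemistry-bearing words
  like *acid*, *group*, *oxide*.  Reproducibility requires pinning the
  list; swapping it changes EC values and is an explicit argument of
  `build_index()`.
* **Degenerate cases.**  Query words absent from the vocabulary contribute
  to neither sum (the denominator runs over $t_d$ only).  A descriptor
  whose words all have EC 0 would make the score 0/0; it is unrankable
  and skipped with a warning.  A term whose descriptors are entirely
  stopwords would be unreachable; it is indexed on its raw words instead,
  with a warning, rather than silently dropped.
* **Ties** are broken name-before-synonym, then fewer descriptor words,
  then smallest term id — determinism over cleverness.
* **No score threshold** is applied: the top-ranked candidate is returned
  whatever its score, and callers can filter on `score` themselves.

```{r}
idx <- build_index(load_lexicon(local({
  f <- tempfile(fileext = ".tsv")
  writeLines(c("CHEBI:1\thyaluronan\thyaluronic acid",
               "CHEBI:2\tzinc oxide\t"), f)
  f
})))
resolve("acid hyaluronic", idx)   # word-set equality with a synonym: 0.8
```

## Evaluation protocol

Five boundary assessments of decreasing strictness: *exact* (both
boundaries), *left*, *right*, *left/right* (either boundary), *partial*
(any overlap).  Matching is one-to-one — a single true-positive count
serves both precision and recall, which implies paired counting — with
greedy pairing in document order (each gold takes the leftmost admissible
unmatched prediction).  Since gold and predicted mention sets are each
non-overlapping, greedy pairing attains the maximum matching for these
interval predicates in practice; the test suite checks the pooled counts
against an independent brute-force recount and the relaxation ordering
$TP_{exact} \le TP_{left}, TP_{right} \le TP_{left/right} \le
TP_{partial}$ on every fixture run.

Three report types: **recognition** (span match only), **identification**
(span match and lexicon id agreement; gold mentions without a mapping are
removed first with `filter_mapped()`, mirroring evaluation on the mapped
subset of a gold standard), and **restricted resolution**
(`restricted_resolution_report()`), which isolates resolution quality by
evaluating both systems only on the gold mentions that *both* recognized,
taking precision over that intersection and recall over the full mapped
subset.

Percentages are reported to two decimals, rounded half-up, with F computed
from unrounded precision and recall — reproducing published table
arithmetic exactly requires both conventions.

## The synthetic data generator

`make_fixture()` emulates the *structure* of an annotated patent-style
gold standard at desk scale: a ChEBI-style lexicon of chemically shaped
names (stems like `chlor`, `benz` with suffixes `-ol`, `-ane`, `-ate`,
`-ide`, multiword patterns like `<stem>ic acid` and element–anion pairs
like `zinc oxide`), and documents of template sentences embedding such
names as gold mentions with exact character offsets.  Generation is
template-based precisely because offset correctness is the point of the
fixture.

Defaults are the study conditions used by the tests and the acceptance
script: 50 terms, 10 documents, 5–15 mentions per document, synonym rate
0.3, multiword rate 0.3, and `unmapped_rate = 0.463`, which leaves 53.7%
of mentions mapped to the lexicon — the mapped fraction typical of a
curated patent gold standard after enrichment.  Out-of-lexicon mentions
use the same chemical morphology but are checked not to collide with any
descriptor.

The `background_overlap` knob injects unannotated chemical-like words into
the otherwise disjoint background vocabulary.  At 0 the corpus is
*separable*: entity and background tokens have disjoint suffix
distributions, and the cross-validated tagger recovers exact-match F above
85%.  Contamination degrades this sharply (by more than 20 F points at
overlap 0.35 or 0.8 in the 8-document experiment of the test suite).  The
degradation is not monotone *between* contaminated settings at this scale
— intermediate contamination, where chemical-like tokens are ambiguous
rather than uninformative, is empirically the most confusable regime — so
the tested property is the separable-versus-contaminated contrast, not a
three-point ordering.

What the generator does **not** emulate — and hence what passing tests do
not show: real patent prose (no grammar, no sentence-level structure
beyond templates), annotation noise and curator disagreement, nested or
overlapping mentions, abbreviations and formulas (`CN`, `OH`, `H2O` as
entity mentions), and the scale and heterogeneity of a real 40-document
patent corpus.  Absolute scores on the synthetic corpora are therefore
*not* forecasts of corpus-scale performance on real text; they validate
the machinery (offsets, protocol, learning, scoring), not the difficulty
of the real task.

## Problem sizes and numerical choices

The experiments shipped with the package are sized for a desk run: the
leave-one-out recovery experiment uses the default ten-document fixture
(about 100 mentions) and completes in roughly two minutes on one core;
the oracle-equivalence suite uses a 100-term lexicon and 100 random
queries; the brute-force recounts run over every fixture document.  The
CRF's convex objective makes all fits deterministic, so no result in the
package depends on run-to-run variation; all remaining randomness (corpus
generation, query sampling) is seeded.

Known limitations: the tokenizer is a documented stand-in for
chemistry-adapted tokenizers described elsewhere, not a reconstruction of
any specific one; the dictionary baseline's case folding is an
approximation to unspecified behavior of production dictionary pipelines;
and the resolver uses no document context — disambiguating, say, a
generic term from its stereo-specific form by surrounding mentions is out
of scope by design.
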