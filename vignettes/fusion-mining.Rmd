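---
title: "Mining fusion-protein mentions and their interactions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fusion-protein mentions and their interactions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemine)
```

## The problem

Fusion proteins — chimeric products of two parental genes, typical of many
cancers — appear in abstracts under many surface dialects: separator
variants (`BCR-ABL`, `BCR/ABL`, `BCR:ABL`, en/em dashes), case variants
(`bcr-abl`, `Bcr-Abl`), numbered paralogs (`BCR-ABL1`) and historical
aliases (`EWS/FLI-1`, `TEL-AML1`). A tagger that misses dialects loses
recall; one that accepts every hyphenated token drowns in false positives
(`2013-2017`, `dose-response`, `N-methyl-D-aspartate`,
`BCR-ABL-selective`). This package implements a dictionary + rule pipeline
for recognizing and normalizing such mentions, extracting the sentence-level
statements that link a fusion to interaction partners and diseases, and
classifying documents with a bag-of-words Naive Bayes model, together with
the evaluation machinery needed to quantify all of it.

## Pipeline and design choices

### Sentence splitting and tokenization

Sentences are split at terminal punctuation followed by whitespace and a
capital letter or digit, with an abbreviation stop-list (`e.g`, `i.e`,
`fig`, ...). Sentence spans are 0-based, half-open, and tile the body
exactly (inter-sentence whitespace belongs to the preceding span), so every
downstream character offset is unambiguous and annotations round-trip
byte-exactly through JSON.

The tokenizer splits on whitespace and punctuation **except** that internal
hyphens, en/em dashes, slashes and colons joining alphanumeric runs are kept
inside a single token. This is deliberate and load-bearing: fusion dialects
must survive tokenization as single tokens (`bcr:abl`,
`BCR-ABL-selective`). Punctuation tokens are discarded.

### Stemming

Stems are computed with the Porter2 (Snowball English) algorithm,
implemented in the package from the published algorithm definition (regions
R1/R2, steps 0–5, exception lists, y/Y marking). Tokens containing fusion
separator characters are exempt from stemming — their stem is the lowercased
surface — so candidate fusion forms are never mangled. One caveat worth
knowing: like all Porter-family stemmers, Porter2 is not idempotent on every
derivational chain (`proliferation → prolifer`, and stemming `prolifer`
again yields `prolif`). The pipeline only ever applies the stemmer once to
any token, and matches lexicon entries by single-application stems on both
sides, so this has no practical effect.

### Token categories

Tokens are segregated into four categories by precedence:

1. **Literal** — the lowercased surface is on the packaged stopword list;
2. **Function** — the surface or stem matches an action-verb variant or the
   evaluative-adjective list (e.g. *effective*, *inhibitor*);
3. **Biological** — a domain adjective (*small*, *single*, *medical*,
   *chronic*, ...), a gene symbol, or a fusion form;
4. **Miscellaneous** — everything else (*molecule*, *kinase*, *imatinib*,
   *leukemia*, ...).

The precedence and the packaged adjective lists were chosen so that the one
fully worked categorization example in the source literature reproduces
exactly. The prose description there (biological tokens "correspond mainly
to nouns") contradicts its own worked example, in which the Biological
tokens are adjectives and the nouns land in Miscellaneous; we treat the
example as normative and flag the contradiction here rather than silently.
The example also omits the token "most" from all four categories; it is a
stopword here (hence Literal), which is the only reading under which the
example is reproducible in full. Disease terms are deliberately *not*
Biological: the worked example places "leukemia" in Miscellaneous.

### Fusion-mention detection

A token is a fusion mention when

* it has the shape `GENE SEP GENE` with both parts resolving through the
  gene-symbol table (separators: hyphen, en dash, em dash, slash, colon),
  **and** a fusion keyword occurs in the same sentence within a token window
  (default 5, same sentence only — the source method describes co-occurrence
  without a window, so a conservative one was fixed here once); **or**
* the form (or its first two parts) matches the fusion-alias dictionary — a
  dictionary hit needs no keyword.

A fusion embedded in a longer hyphen chain (`BCR-ABL-selective`) is detected
through its first two parts, with the full surface recorded; this keeps the
tokenizer (one token) and the tagger (fusion present) consistent on such
adjectival forms. Whitespace-separated forms ("BCR ABL fusion") are not
detected: the false-positive risk is high and only separator dialects are
attested. Normalization lowercases, maps every separator to a hyphen via
the ordered rule base, resolves aliases, and emits `GENEA-GENEB` uppercase;
it is idempotent, and all dialect variants of a fusion map to one
identifier.

### Interactions and disease links

Within a sentence, each fusion mention is paired with every (action token,
partner gene token) combination; partners are gene tokens that are not
components of any fusion mention in the sentence (no self-partners). A
single verb therefore distributes over coordinated fusion lists ("... bind
NPM-ALK and ATIC-ALK" yields two tuples). Only **verbal** variants of the
action lexicon trigger relations (lemma, -s, -ed, irregular past, -ing).
Nominal variants (-ion, -or, -ence) are in the lexicon for token
categorization but deliberately do not create tuples: in "X induces STAT5
activation" the statement is *induce*, and letting "activation" fire as well
would double-count the evidence with a wrong lemma. Relations are
undirected co-occurrence tuples; no agent/patient roles are assigned.
Disease links additionally require a disease-lexicon term (longest match,
multi-word aware) and carry a MeSH identifier from a packaged term→MeSH
table.

### Lexicons

The supplementary dictionaries of the original resource are unpublished;
the packaged lexicons are recreations seeded from every token the source
literature prints (fusion keywords; the action verbs with curated
morphological variants; the EWS-FLI1 / TMPRSS2-ERG / BCR-ABL alias family
plus other well-known fusions; cancer terms with MeSH ids; an HGNC-style
gene-symbol list of ~60 symbols sufficient for testing). The TSV formats
are documented in `?load_lexicon` so users can substitute full-scale
dictionaries; `expand_morphology()` helps generate variant lists. Gene
symbols that collide with common English words (e.g. MET, KIT) are
deliberately excluded from the packaged list — a full deployment would
handle them with context rules rather than bare dictionary lookup.

## Features and the classifier

Feature extraction stems the text, **blanks recognized entities** to class
placeholders (GENE, FUSION, DISEASE, ACTION; placeholders stay uppercase so
they remain distinct grams) and extracts contiguous n-grams, default orders
1–2 (3–4 available). Blanking generalizes patterns across specific gene
names. Each gram is weighted by the frequency score `T(s,a) = FS(s,a) ×
log10(τ/σ)`; the vocabulary is the top-V grams (default V = 1000) by
max-over-documents score, ties broken lexicographically, filtered at a
minimum score (default 0, i.e. only corpus-wide tokens are excluded since
they score exactly 0). "Similar-length" document representations are
realized as fixed-dimension vectors over this global vocabulary, rescaled
to unit sum; all-zero rows stay zero. The threshold is applied corpus-wide
for vocabulary selection with per-document values — the alternative
(per-document thresholds) would make vectors incomparable across documents.

The classifier is multinomial Naive Bayes with Laplace smoothing α = 1
(the bag-of-words counts make the multinomial event model the natural
choice). Prediction is the arg-max of log prior + Σ count × log
likelihood; exact ties resolve deterministically to the first factor level
(the negative class). Undefined metrics (0/0) are reported as `NA`
("undefined"), never as 0 or 1.

Two evaluation protocols are described inconsistently in the source
literature (a 40%/60% train/test split, and ten equal sub-samples of which
five train and five test); both are implemented rather than resolved:
`cross_validate()` (stratified k-fold, default k = 10, the package default)
and `split_validate()` with `train_frac = 0.4` or `0.5`. Fold assignment is
stratified and fixed by a seed; fold numbers cycle continuously across
classes so every fold is populated even when a class has fewer than k
members. The positional `token_agreement_score()` (fraction of agreeing
positions over labels {n, y, a}) is kept as a separate operation: it is the
convention under which the printed worked example yields 0.75, and it is
*not* the same quantity as set-based precision/recall — conflating them
would corrupt the standard metrics.

An abstract convex-optimization restatement of the training step that
accompanies the source description is internally inconsistent (its symbols
have no operational definition) and is deliberately not implemented;
training is standard Naive Bayes.

## The synthetic-corpus generator

The generator emulates exactly the phenomena the taggers are sensitive to:

* planted fusion mentions rendered in sampled dialects — separator
  {hyphen, slash, colon} × case {upper, lower, title}, uniform by default;
* keyword-supported and alias-only mentions (the planted fusions come from
  the alias table, so both detection routes are exercised);
* interaction sentences "PARTNER VERB FUSION", including coordinated
  "PARTNER VERB FUSION1 and FUSION2" forms (probability 0.25 given an
  interaction), with verbal variants sampled from the action lexicon;
* fusion-causes-disease sentences (probability 0.4);
* distractors at an expected 2 per document: year ranges, hyphenated
  adjectives (*time-dependent*, *cost-effective*), chemical hyphen names,
  standalone gene mentions with no fusion pattern, and fusion keywords with
  no gene pair.

Defaults: 200 documents, alternating positive/negative labels (balanced by
construction, so stratified folds are always well-formed),
`p_interaction = 0.6`. Sentence templates are packaged as data
(`inst/extdata/templates.tsv`) so new distractor families need no code
change. The generator uses a private seeded RNG stream (the caller's
`.Random.seed` is untouched); identical configurations yield byte-identical
MEDLINE, gold-JSON and label files.

What the generator does **not** emulate: real abstract prose (subordinate
clauses, anaphora — "this chimera..."), OCR noise, three-gene fusions,
breakpoint notation, or gene symbols colliding with common words. Perfect
recovery on synthetic corpora therefore demonstrates that the dialect
handling, windowing, normalization and plumbing are correct — not that
real-PubMed precision/recall would be perfect. On real text the binding
constraint is lexicon coverage, which is exactly what the synthetic corpus
holds fixed.

## Numerical and reproducibility notes

* Character offsets are 0-based, half-open, in Unicode code points on the
  raw body; MEDLINE Latin-1 input is transcoded to UTF-8 on read.
* Labeled abstract sections in PubMed XML are concatenated with single
  spaces.
* Overlapping annotation spans resolve outermost-wins everywhere
  (highlighting and blanking), with a warning on drops.
* All file outputs are written with fixed key order and `\n` line endings,
  so identical inputs give byte-identical outputs; run manifests record the
  configuration and input digests.
* Test and example problem sizes: the evaluation suite uses 200-document
  corpora for recovery/classification checks and 10–50 documents for
  plumbing checks; brute-force classifier oracles run on ≤ 5 documents ×
  ≤ 4 grams, where exhaustive plain-arithmetic Bayes computation is exact.

## Known limitations

* Dictionary-bounded recall: an unlisted gene symbol or alias cannot be
  tagged. The lexicon format makes extension trivial, but no learning of
  new entries is attempted.
* Same-sentence co-occurrence is the relation model; there is no syntactic
  parsing, negation or speculation handling ("does not bind" yields a
  tuple).
* Three-gene fusions and breakpoint/exon resolution are out of scope.
* The MeSH assignment is a lookup over packaged disease terms, not an
  ontology traversal.
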