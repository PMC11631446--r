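---
title: "Mining directed brain-region connectivity from text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining directed brain-region connectivity from text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conntext)
```

## The problem

Neuroanatomical connectivity knowledge is scattered across decades of
tracing studies, and the same structure goes by many names — full names,
abbreviations, and nomenclature-specific variants.  `conntext` implements a
text-mining pipeline that (i) recognizes brain-region mentions in tokenized
sentences, (ii) classifies the relation expressed between each pair of
mentions into four directional classes, (iii) normalizes mentions to a
merged ontology dictionary, and (iv) assembles the results into a directed
connectivity knowledge graph whose edges carry sentence-level literature
evidence.

## Pointer-augmented named-entity recognition

Sentences are tagged with the BIO scheme (`B-BrainRegion`,
`I-BrainRegion`, `O`).  On top of the token labels, every entity carries
two *position pointers*: a start tag on its first token and an end tag on
its last.  Both pointer sequences are derivable from the BIO labels
(`derive_pointer_tags()`), and training supervises all three jointly.

A pluggable encoder maps tokens to $H$-dimensional vectors.  Each token
embedding is the sum of a word, a position and a segment component; the
shipped encoder then applies $L$ local mixing layers (a tanh over a
±1-token window per layer, receptive field ±$L$), which is small enough
to train on a laptop in seconds yet propagates the boundary context the
pointer heads need.  Three sigmoid heads produce per-token class
activations $P_l$ (3 label classes), $P_s$ and $P_e$ (2 pointer classes
each); activations are renormalized per row to distributions, and the
training loss over a sentence of $N$ scored tokens is

$$\mathcal{L} = \frac{1}{N}\Big[\mathrm{CE}(P_l) +
  \lambda\,(\mathrm{CE}(P_s) + \mathrm{CE}(P_e))\Big],$$

with $\lambda \ge 0$ the pointer coefficient (default 1.0 — the neutral
choice; exposed in `train_ner()`).  Probabilities inside logarithms are
clamped at $10^{-12}$, so degenerate predictions never produce NaN.

**Decoding.**  How the three heads are reconciled at inference is a
genuine design choice; the default *paired-pointer* rule is: threshold the
renormalized start/end pointer probabilities at 0.5; scan fired starts left
to right; pair each with the nearest fired end at or after it within a
maximum entity length (default 10 tokens); discard the pair if any covered
token's best BIO label is `O`; accept greedily without overlaps.  The rule
is deterministic, and an exhaustive-enumeration oracle in the test suite
verifies the implementation on all short sentences.  A `bio` mode decodes
from the label head alone (argmax, orphan `I` repaired to `B`) and is kept
for ablations.

**Training-corpus features.** `augment_by_repetition()` expands a corpus
by an integer factor with a seeded shuffle.  `trie_denoise()` corrects
annotations against a gazetteer: every maximal longest match of a
dictionary surface form is labeled as one entity, and annotated spans
that overlap such a match are extended/merged into it.  The operation is
idempotent and is this package's operationalization of dictionary-tree
denoising, whose exact mechanism is under-specified in the literature;
longest-match annotation correction is one defensible reading, and the
test suite asserts only the directional claim (denoised training is at
least as good as noisy training on average).

## Marker-based relation classification

For a candidate pair of mentions in one sentence, the tokens are wrapped
in boundary markers — `<s> … </s>` around the first mention, `<o> … </o>`
around the second — and the whole marked sequence is encoded between
`[CLS]` and `[SEP]`.  The four marker tokens are atomic vocabulary items
with their own embeddings (never split), so their encoder outputs
$s_1, s_2, e_1, e_2$ summarize each entity's boundary context.  Each is
affinely projected to $M$ dimensions and the concatenation is mapped to
class scores:

$$P(X) = W_o\,\mathrm{Concat}(W_s^1 s_1 + b_s^1,\; W_s^2 s_2 + b_s^2,\;
  W_e^1 e_1 + b_e^1,\; W_e^2 e_2 + b_e^2) + b_o,$$

followed by a softmax (the head emits unnormalized scores; a softmax is
the natural normalizer for the multi-class cross-entropy).  One
implementation serves both the 2-class connectivity task and the 4-class
directional task (`unconnected`, `undirected`, `output`, `input`) — only
the label set changes.  The subject is always the *earlier* mention;
direction is expressed entirely by the label, which keeps candidate
construction symmetric.  Ties in the predicted distribution resolve to the
lowest class index.  Optional inverse-frequency class weights and an
optional `[CLS]`-augmented head (a fifth projected vector) are available
but off by default; the equation above is the default head.

Sentences whose marked form exceeds the encoder length are truncated
(with a warning); such instances are skipped from the training loss
rather than silently mangled.

## Evaluation

Span-level NER evaluation supports two modes.  *Exact* matching credits a
predicted span only when both boundaries coincide with a gold span.
*Lenient* matching credits a predicted span contained in (or equal to) a
gold span — predicted boundaries may be smaller or equal, never larger.
Each gold span is creditable at most once; matching is greedy in span
order, and because spans within each set are disjoint, the greedy
assignment provably attains the optimum of the brute-force bipartite
matcher (also verified empirically in the tests).  Precision, recall and
F1 use the 0-denominator-gives-0 convention.  NER metrics are
micro-averaged (pooled tp/fp/fn); the 4-class relation task reports
per-class and macro-averaged metrics plus row-normalized confusion
matrices.  `cross_validate()` shuffles units once with a seed, cuts them
into k rotating blocks (each unit tested exactly once) and reports
per-fold metrics with mean ± SD.  Splits can be document-level (whole
documents stay together) or sentence-level; both are supported because
the right unit is corpus-dependent.

## Ontology merging and staged entity linking

Sources are unified when species and normalized canonical name (case-fold,
punctuation stripped, stopwords `of/the/a/an` dropped) match exactly; the
unified entry keeps the first source's id, the union of abbreviations and
synonyms, and a cross-reference table.  Entries sharing an abbreviation
but naming different structures are a collision — they stay separate and
are logged, because short forms are too ambiguous to merge on.  For the
same reason abbreviation *matching* is exact-only, never fuzzy.

Linking runs staged fallbacks, first success wins:

1. **exact** — normalized mention vs names and synonyms, raw mention vs
   abbreviations (score 1);
2. **strip_directional** — remove directional words (rostral, caudal,
   dorsal, …; configurable) and retry exactly, never emptying the mention;
3. **nested** — maximal gazetteer longest-matches strictly inside the
   mention, longest first, each retried exactly.  Nested candidates come
   from the gazetteer trie, with an extension point for plugging an
   external nested-NER tool;
4. **fuzzy_word** — word-level scoring
   $s = w\,\frac{|m \cap t|}{|m|} + (1-w)\,\frac{|m \cap t|}{|t|}$
   over unique stopword-free word sets, $w = 0.5$, acceptance threshold
   0.5 (both configurable; the exact weighting is not pinned down by any
   authority, so the minimal two-sided form is exposed as configuration).
   Candidates sort by score, then fewer term words, then lexicographic id
   — fully deterministic.

A term always scores 1 against itself, so fuzzy linking degenerates to
exact on in-dictionary mentions, and staged coverage can only extend the
exact mapping rate.

## Knowledge-graph assembly

`canonicalize()` orients each classified pair: `output` keeps the
mention order (subject → object), `input` flips it, `undirected` is
stored once in canonical id order as its own relation (rather than
expanded into two directed edges, preserving the evidence distinction),
and `unconnected` yields nothing.  Self-links after normalization are
dropped with a message.  Evidence is deduplicated per (document,
sentence, pair, label) — whether deduplication should be per sentence or
per document is an open corpus-design question; per-sentence is adopted
and documented here.  Mentions that fail linking go to an `unlinked`
side table for observability.  `circuit()` summarizes one region's
partners as inputs / outputs / undirected with evidence counts, and the
graph exports to a TSV edge list plus JSON evidence that round-trips
through `import_graph()`.

## The synthetic study corpus

`generate_ontology()` and `generate_corpus()` build a toy nomenclature
and labeled corpora with known ground truth.  Region names (1–5 words)
compose a name-initial modifier, optional middle modifiers and a head
noun from a closed anatomical-style vocabulary; synonyms are head-noun
variants and abbreviations are uppercase initials (kept collision-free so
synthetic linking stays unambiguous — collisions are exercised separately
with handcrafted fixtures).  Sentences instantiate directional templates
whose trigger words are distinct per class ("projects to" / "receives …
from" / "connected with" / "and").  This is intentional: the tasks are
*separable by construction*, so the parameter-recovery experiments have a
known achievable ceiling and a miss indicts the implementation, not the
task.  The default class mix follows the published directional corpus
frequencies (unconnected 84.9%, undirected 5.3%, output 7.1%, input
2.7%), the default corpus is 100 documents × 20 sentences (2,000
sentences, 6:1:1 document-level splits), and 15% of sentences carry a
single mention as NER-only filler — a realistic rate for sentences
mentioning one structure in isolation.

Boundary noise truncates one boundary token of a configurable fraction of
*training* entity spans; test labels and ground truth stay clean, which
isolates the denoising ablation.  What the generator does **not**
emulate: real prose statistics, vocabulary overlap with actual
neuroanatomy, cross-sentence relations, nested or discontinuous
mentions, and annotator disagreement.  Passing the recovery tests
therefore demonstrates that the models, losses and decoders are
implemented correctly and can fit a separable signal — not that the small
encoder matches pretrained-transformer performance on real corpora, which
would require external data and encoders out of scope here.

## Numerical and reproducibility choices

* All randomness (initialization, shuffling, sampling) flows from
  explicit integer seeds; identical seeds give bitwise-identical models.
* Optimization is per-instance Adam.  Defaults: NER learning rate 0.01,
  6 epochs; RE learning rate 0.005, 10 epochs — on the default synthetic
  corpus both converge with a comfortable margin, and the smaller RE rate
  avoids the oscillation a 4-class softmax head shows at higher rates.
* Epsilon clamps: $10^{-12}$ inside every logarithm.
* Tie-breaks are always deterministic: first maximum for argmax,
  lowest class index for relation ties, lexicographically smallest id for
  linking ambiguity.
* Degenerate inputs: empty corpora, empty gazetteers, empty graphs and
  zero-denominator metrics all have defined behavior (error, identity
  with warning, empty result, and 0 respectively).
* Problem sizes used by the test suite and the acceptance script: the
  2,000-sentence default corpus for single-model recovery, five seeds of
  the same size for the denoising ablation and relation recovery, and
  oracle checks on $10^3$–$10^4$ random cases — together a few minutes of
  CPU.

## Known limitations

* The shipped encoder is a small window encoder; it honours the same
  `encode()` contract as a pretrained biomedical transformer but is not
  one, and no pretrained weights are produced or consumed.
* Candidate relations are intra-sentence only.
* Lenient evaluation uses the containment reading (predicted ⊆ gold);
  start-aligned-overlap readings exist but are not implemented.
* Species stratification of edges is a tag pass-through, not inferred.
* The real merged Allen/NeuroNames/BAMS dictionary is not shipped
  (licensing/curation); the loader accepts any dictionary in the
  documented TSV/JSON schema, and the synthetic ontology stands in for
  tests.
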