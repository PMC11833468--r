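---
title: "Methods: extraction scoring and taxonomy induction for 4M expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction scoring and taxonomy induction for 4M expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourms)
```

`fourms` implements a pipeline for turning short clinical text messages
into (a) evaluated extractions of 4M-framework expressions (What Matters,
Medication, Mentation, Mobility) and (b) a four-level semantic taxonomy of
those expressions. This vignette is the package's account of the methods:
the models and procedures, the parameters that matter, the synthetic data
the tests rely on, and the choices made where the design was genuinely
open.

## Corpus model

A corpus is a tibble of messages (id, resident, facility, sender role,
receiver role, timestamp, free text) plus a table of nursing-home-to-
hospital transfer events. Preprocessing is deliberately minimal:
duplicate removal only. The default duplicate key is *every* field with
whitespace-normalized text — the safest key, which cannot merge two
distinct clinical events that happen to share wording; a narrower
(resident, timestamp, text) key is available for corpora whose export
pipeline duplicates rows with fresh surrogate ids.

Messages are linked to a transfer event when they belong to the same
resident and fall in the half-open window `(transfer_time - window_days,
transfer_time]`, with `window_days = 14` (the two weeks preceding a
transfer). The half-open convention includes a message sent at the
transfer instant and excludes the same instant fourteen days earlier; the
boundary choice is ours, as is treating timestamps as timezone-naive local
time, since message exports typically carry no zone.

## Extraction contract and hallucination screening

Extractors — generative-model adapters or the bundled deterministic
lexicon extractor — emit a JSON object per message mapping each class to a
list of phrases. Parsing is tolerant: missing classes default to empty,
unknown keys are flagged, and a syntactically broken blob becomes an error
record carrying the raw text (never partial counts), because a pipeline
driving a language model must survive malformed output. Decoding settings
(temperature 0, top_p 0.9, top_k 40, seed 418) are carried as opaque
adapter configuration and are inert for non-LLM extractors.

Every span is then screened against its source message. The score is a
fuzzy-substring similarity: `1 - d/m`, where `d` is the minimum edit
distance between the normalized span (length `m`) and any contiguous
substring of the normalized message (an infix alignment — the text's
prefix and suffix are free). A span scoring below `similarity_floor` is
flagged a hallucination, excluded from counts, and retained for audit.
The default floor of 0.85 keeps one-typo variants (a 20-character span
tolerates up to three edits) while rejecting fabricated phrases; a floor
of 1.0 demands an exact normalized substring. Counts count *phrases*, not
tokens, and a phrase planted twice in one message counts twice.

## Gold standard and the agreement battery

Two annotators independently mark (message, class, phrase) spans. A
*difference* is a span present in exactly one set under normalized phrase
matching; spans whose full-string similarity reaches 0.85 are treated as
the same phrase, so near-identical variants ("disfunction" vs
"dysfunction") do not inflate the difference count. Reconciliation takes
the matched intersection plus every adjudicated-accept difference, with
per-phrase provenance (`both`, `A_only_accepted`, `B_only_accepted`);
unadjudicated differences are fatal by design — silent resolution would
corrupt the reference.

Evaluation reduces each (message, class) cell to a binary presence and an
integer count over the gold message universe (zero-content messages carry
explicit zeros) and reports per class: recall, precision, F1, accuracy,
ROC AUC, Cohen's κ, Spearman's ρ, binned κ, and MAE. Numerical choices:

* **AUC** uses the Mann–Whitney rank statistic with midranks. Since binary
  extractors provide no scores, the validated count is the default ranking
  score (more extracted phrases = stronger evidence); this is
  configurable.
* **Binned κ** applies unweighted κ to counts mapped into the ordinal bins
  {0}, {1}, {2}, {3+} by default. The bin spec is exposed because any
  particular binning of sparse counts is a judgment call.
* **Overall κ** is micro-pooled over every (message × class) binary
  decision; the macro average of per-class κ is reported alongside so
  the pooling choice is transparent.
* **Degenerate κ** (expected agreement 1, i.e. both raters constant on
  the same label) returns 1 with a warning rather than 0/0.
* The performance gate is κ ≥ 0.60, per class and overall — the
  conventional lower bound of "moderate" chance-corrected agreement.

Messages where the extractor's multiset of spans differs from gold become
preference pairs: `chosen` is the gold rendered through the same JSON
schema the extractor uses (format-consistent pairs), `rejected` is the
extractor's own output, spans serialized in normalized sort order so the
comparison and the rendering cannot disagree. The train/validation split
is by message id — a message can never contribute a training pair and a
validation pair — and reproducible under a fixed seed.

## Taxonomy induction

Validated spans are grouped into expressions by (class, normalized text)
with message provenance, embedded by a pluggable embedder, and
deduplicated by a greedy first-kept scan: an expression whose cosine
similarity to an already-kept expression reaches 0.95 folds into the
earliest such keeper (provenance unioned). Keep-first in input order makes
the scan reproducible and documented; the default scans within class,
because folding across classes would delete class-specific provenance
(`by_class = FALSE` restores pooled-then-split behavior).

Clustering is agglomerative Ward linkage on Euclidean distance, computed
per class. Heights use the convention `h = sqrt(2 * dESS)` with
`dESS = n_i n_j/(n_i + n_j) * ||c_i - c_j||^2`, so two singletons merge at
their Euclidean distance and thresholds read in embedding-space units; the
scale convention is recorded here because linkage software varies on it.
Cuts apply every merge with height *strictly below* the threshold, and
cluster ids are assigned by smallest member leaf index, which together
with lowest-index tie-breaking makes results platform-independent.

Four strictly decreasing thresholds per class define levels 1–4 under a
level-0 class root. Rather than reading thresholds off a dendrogram by
eye, `suggest_thresholds()` scans the n−1 candidate cut heights and picks,
for each target cluster count, the threshold achieving the closest count
(larger threshold on ties). Because all four cuts come from one tree,
level-(k+1) partitions provably refine level-k partitions.

Labeling proceeds breadth-first. Each candidate label is embedded and
compared with labels already accepted at the same class and level; cosine
≥ 0.9999 — effectively a near-verbatim duplicate — triggers re-labeling
with the colliding labels passed back to the labeler, up to `max_rounds`
(default 3), after which a deterministic numeric suffix disambiguates and
the node is flagged. Member lists handed to a labeler are truncated to the
50 most central members (by distance to the cluster mean) to bound prompt
size for generative labelers. The bundled `keyword_labeler()` (most
frequent informative tokens) is the deterministic reference and test
double; generative labelers plug in behind the same contract.

## Query and summaries

`query_concept()` matches a term by direct quotation (word-boundary
substring of the normalized expression text) and, when an embedder is
supplied, by relatedness — cosine of the term embedding to expression
vectors at or above 0.6 by default. "Related" has no canonical
definition for this task; embedding similarity with an exposed threshold
is our operationalization. The concept graph contains each match's full
ancestor chain to its class root; class components connect only through
genuinely shared clusters (no artificial super-root), matching how
multi-class concepts like pain naturally span the framework. Graphs export
losslessly to GraphML and node-link JSON. Expression nodes serialize with
level 5 (one below the finest cluster level) so round trips never depend
on NA encoding.

Corpus summaries attribute each validated extraction to its message's
sender role and report per-class totals, the sender-role distribution, and
the (sender, receiver, class) cross-tabulation as percentages of all
extractions, with display rounding to one decimal and full precision kept
in the tables.

## The synthetic-data module

The generator emulates the statistical structure the pipeline assumes,
with every ground-truth quantity recorded:

* **Messages** of roughly 10–60 words assembled from a fixed bank of
  4M-free clinical boilerplate plus carrier sentences holding planted
  phrases verbatim. The boilerplate and carrier vocabulary is disjoint
  from the phrase word banks, so a zero-content message can never contain
  a lexicon phrase by accident.
* **Class imbalance**: expected expressions per message default to
  0.35/0.95/0.26/0.16 (What Matters/Medication/Mentation/Mobility) —
  Medication-dominant, qualitatively mirroring the class mix seen in
  nursing-home transfer communication — with 30% of messages forced to
  zero 4M content.
* **Planted hierarchy**: per class, level-1 cluster counts default to
  8/9/4/4 with branching 2×2×2 down to level 4 and 7 phrases per leaf
  (~1400 expressions), the shape used by the recovery tests.
* **Embeddings**: each planted phrase maps to its leaf centroid plus
  isotropic Gaussian noise (σ = 1), deterministic per phrase (noise keyed
  by phrase hash and seed). Sibling groups at level l are separated by
  `5σ · 4^(4-l)`, so within-parent distances are smaller than
  across-parent distances at every level. Unknown text falls back to a
  deterministic pseudo-random unit vector.
* **Roles** default to the 40.5/33.6/9.3/16.6% sender mix
  (nursing staff/APRN/physician/other staff) characteristic of this
  setting.
* **Annotators** start from the planted spans and each drops a span with
  probability `rate`; a span both would drop is reassigned to a single
  random annotator, so every span survives somewhere and truth-adjudicated
  reconciliation restores the planted gold exactly. The difference
  probability per span is therefore `rate(2 − rate)`.

What the generator does **not** emulate: real clinical language (typos,
abbreviations, emotional register, ambiguous references), annotator
biases that correlate across items, extraction boundary ambiguity, or the
anisotropic geometry of real sentence-embedding models. Passing tests
therefore demonstrate the *correctness of the machinery* — metrics equal
their oracles, planted structure is recovered, bookkeeping conserves
counts — not that any particular extractor or embedder will reach a given
κ on real messages.

One geometric consequence worth knowing: hierarchical centroid placement
means same-leaf expressions have cosine similarity near 1, so the
0.95-cosine dedup stage of the full pipeline folds many same-leaf
expressions, as near-duplicates should fold. The planted-hierarchy
recovery checks accordingly run on the undeduplicated expression set.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen to
exercise every property at comfortable statistical power: metric oracles
on 200 fixtures of length ≤ 20; exhaustive Ward comparison on 100
Gaussian fixtures with n ≤ 12 (heights to 1e−9); 500 nesting/monotonicity
trials; dedup oracle fixtures with n ≤ 50; hierarchy recovery on the
default ~1400-expression vocabulary (ARI ≥ 0.9 at every level); identity
and planted-error evaluation on corpora of 500 and 5000 messages
(measured κ within ±0.05 of the closed-form value implied by planted
false-positive/false-negative rates 0.1/0.2). Every random draw flows
from an explicit integer seed; a fixed seed reproduces generator output
byte-identically and pipeline manifests exactly (minus the wall-clock
field).

## Known limitations

* The lexicon extractor matches exactly (after normalization); it is a
  reference implementation and test double, not a competitive extractor.
* `suggest_thresholds()` optimizes cluster *counts*, not cluster quality;
  with weakly separated data, hitting a target count does not imply
  meaningful clusters.
* Annotation diffing pairs leftover spans greedily by best fuzzy score;
  with several highly similar distinct spans in one (message, class) cell
  the pairing, and hence the difference count, can be ambiguous.
* Ward clustering is O(n²) memory through the distance matrix; per-class
  expression sets beyond ~20k will need a chunked or approximate backend.
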