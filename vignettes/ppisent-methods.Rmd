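---
title: "GO-term protein sentences for interaction prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GO-term protein sentences for interaction prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, the
assumptions behind them, the tunable parameters and the design decisions
taken where the design was genuinely open.

## The model

`ppisent` predicts whether two proteins interact from their Gene Ontology
annotations alone — no sequences, no network features. The premise is that
interaction partners are co-annotated: they tend to share, or sit near
each other in, the GO graph. The pipeline turns that premise into a
supervised sentence-pair classification problem.

### Annotation axioms and reliability weights

GAF records are reduced to (protein, term, evidence, reference) tuples;
`NOT`-qualified rows are dropped because they assert the *absence* of an
association. Records with evidence code `IEA` (electronic annotation,
not manually reviewed) or `ND` (no biological data available) are
removed: they are the two codes that carry no experimental or curatorial
support. The survivors are grouped by (protein, term); the group size is
the axiom's **weight**. An annotation independently asserted by several
references is more trustworthy than a singleton, so the duplication count
acts as a reliability index. Two records count as the same axiom iff
protein and term match — aspect and reference deliberately do not enter
the key, because it is precisely the *different references* that should
accumulate weight. `weighted = FALSE` reproduces the unweighted variant
(every retained axiom at weight 1), and the whole pipeline can be run in
either mode for comparison.

### Term vectors

Every edge of the ontology yields one axiom sentence
`child relation parent` (`is_a` or `part_of`; other relation types are
dropped with a count, matching what the Wang measure weights). A
skip-gram model with negative sampling is trained on these sentences —
minimum token count 1, because on axiom corpora every term matters. Only
GO accessions are exported; the relation keywords serve as shared context
tokens during training. Terms that share parents or lie on the same path
obtain similar vectors, which the test suite checks as a property
(sibling cosine exceeds cross-branch cosine in at least 9 of 10 seeds).

Defaults: dimension 200 for production use (32 in the desk-scale
pipeline, see below), window 5 (every in-sentence pair, since sentences
have 3 tokens), 100 epochs (small corpora need many passes), 5 negative
samples, initial learning rate 0.025 decayed linearly. The trainer is
single-threaded and seeded: identical corpus and seed give
bitwise-identical vectors. Out-of-vocabulary terms at sentence-building
time (annotated terms absent from all ontology edges) map to a zero
vector with a warning, keeping prediction total while making corpus /
ontology mismatches visible.

### Protein sentences

A protein is the sorted sequence of its annotated terms, each term
repeated `min(weight, weight_cap)` times in weighted mode. Repetition is
how reliability reaches the encoder without changing the architecture.
The cap (default 10) bounds sentence length: annotation files can repeat
a popular axiom hundreds of times, and unbounded repetition would blow up
encoder input length while adding no information beyond "very reliable".
Token order is canonical (sorted by term id) — GO terms have no
meaningful order within a protein, and a fixed order makes runs
reproducible.

### The sentence-pair classifier

Each sentence matrix (tokens × embedding dim) passes through a stack of
1-D convolutions over the token axis with ReLU; after every layer the
maximum over time is taken per channel, and the pooled features of all
layers are concatenated into a fixed-length embedding (hierarchical
ConvNet pooling). Two sentence embeddings are combined as
`[u, v, |u − v|, u ⊙ v]` — the standard supervised sentence-pair
composition, whose absolute-difference and product blocks expose
similarity structure directly — and classified by a one-hidden-layer
softmax MLP under two-class cross-entropy, trained with Adam. A pair is
labelled positive iff `P(positive) > P(negative)` strictly; an exact tie
is negative.

**Why kernel size 3 is the default.** With max-over-time pooling, a
kernel of width 1 makes the encoder a pure *set* encoder: the pooled
value per channel is the max over per-token features, so repeating a
token any number of times changes nothing. But repetition is exactly how
the weighted sentences carry reliability — under kernel 1 the weighted
and unweighted pipelines are provably identical, and we confirmed they
produce identical predictions. A width-3 kernel sees windows of adjacent
tokens; since sentences are sorted, a term with weight w forms a run of w
identical rows, and runs of different lengths produce different window
multisets. That makes weighting visible while keeping order sensitivity
minimal (the canonical sort removes arbitrary order variation).
`kernel_size = 1` remains available for a strictly permutation-invariant
encoder, and the test suite verifies that invariance at kernel 1.

Other model defaults: two conv layers, channels 64/64 (32/32 at desk
scale), hidden width 128 (64), dropout 0 (determinism by default; seeded
inverted dropout is available), Adam at 1e-3, batch size 2. Published
accounts of this architecture family report best results with batch
sizes of 1 or 2 and are ambiguous between them; both are a single config
field here, with 2 as the default. Training loss per epoch is logged and
the fitted object's `plot` method draws it.

## Baselines

The four structural term-similarity measures share conventions:

* **Resnik**: `IC(MICA)`, the information content of the most
  informative common ancestor. 0 when only the root is shared.
* **Lin**: `2·IC(MICA) / (IC(t₁) + IC(t₂))`, in [0, 1]; an error when
  both terms have zero IC (the ratio is undefined).
* **Pekar**: max over common ancestors c of
  `δ(root, c) / (δ(root, c) + δ(c, t₁) + δ(c, t₂))` with δ the
  *longest*-path length; depth is longest-path throughout the package,
  matching the edge-based measure's convention. The degenerate 0/0 case
  (root against root) is defined as 0.
* **Wang**: S-values decay multiplicatively along parent edges (`is_a`
  0.8, `part_of` 0.6, max over paths); similarity is the common
  ancestors' S-value mass over the two total semantic values.

Information content is annotation-frequency IC,
`−ln(freq(t)/freq(root))` with `freq` counting distinct (protein, term)
pairs over the descendant closure — the standard Resnik corpus IC.
(Variant IC formulas exist; this package fixes the standard one and
documents it, since all downstream measures are ratio- or max-based and
the base/variant only rescales Resnik.) Terms never annotated have *no*
IC: similarity calls touching them raise an error instead of returning
0, because silent zeros mask corpus/ontology mismatches.

Protein-level aggregation: AVG (grand mean over all term pairs), Max,
and BMA — the best-match average, ½(mean of row maxima + mean of column
maxima). A `bma_literal` mode is also shipped: the uncorrected variant
that omits the inner best-match and therefore collapses to a rescaled
AVG. It exists for fidelity comparisons; `bma` is the canonical
aggregator and the default. Cross-namespace term pairs inside an
aggregation are skipped with renormalization over the remaining pairs
(similarity across namespaces is undefined); a pair of proteins
annotated in entirely disjoint namespaces is an error.

Baselines ignore axiom weights — they are structural measures over term
*sets*. For threshold metrics on baseline scores, the decision threshold
is chosen to maximize accuracy on training scores and then applied
unchanged to held-out pairs; the model itself always thresholds
`p_positive` at 0.5 per its decision rule.

## Evaluation

ROC: thresholds at distinct scores descending, tied scores grouped into
one step, trapezoidal area — algebraically the Mann–Whitney probability
that a random positive outscores a random negative, ties counted ½,
which the tests verify exhaustively. PR: same sweep, but the area uses
step-wise (achievable-precision) integration rather than trapezoids,
because linear interpolation between PR points overstates attainable
precision; with all-equal scores the area equals prevalence, as it
should. Degenerate confusion denominators (no predicted positives, no
true positives) yield 0 with a warning rather than NaN.

## The synthetic benchmark generator

The generator emits a complete desk-scale study: an OBO ontology, a GAF
annotation file and a labelled, balanced pair list, all deterministic
under a single seed and all re-parseable by the package's own readers
with zero loss.

* **Ontology**: a random rooted DAG in one namespace; each new term
  attaches to 1–2 earlier terms (acyclic by construction), edges are
  `is_a` with probability 0.7 else `part_of`, and depth is capped.
* **Annotations**: each protein is assigned to a *branch* (a depth-1
  subtree) and draws its true terms from it. Each record gets an
  evidence code at configurable fractions (defaults: 20% IEA, 5% ND;
  the rest EXP/IDA); reliable true annotations acquire `Poisson(dup_rate)`
  extra copies with distinct references. Optional noise terms are drawn
  uniformly from the whole graph and emitted once with a reliable code —
  so when `noise_terms_per_protein > 0`, duplication count correlates
  with correctness, which is the regime where weighting should help.
* **Pairs**: with probability `signal_strength`, a positive pair is
  drawn from one branch and a negative pair from two different branches;
  otherwise either class is drawn uniformly. At `signal_strength = 0`
  both classes are therefore drawn from the *same* distribution and the
  labels carry no information — the cross-branch constraint on negatives
  applies with probability `signal_strength` precisely so this null
  holds exactly.
* **Ledger**: the generator records ground truth (per-code counts, the
  duplication count of every reliable axiom, each protein's branch,
  planted noise terms) as JSON, which the tests use as an independent
  oracle for the filtering and weighting stages.

Branch-level co-annotation was chosen as the interaction signal because
*every* method in the package — embedding-based and structural alike —
can in principle detect it: the fixture discriminates implementations,
not biology. What it does **not** emulate: realistic GO topology
(thousands of terms, heavy-tailed degree), three namespaces,
species-specific annotation bias, shallow-annotation proteins dominating
real GAFs, and curated negatives. Passing tests on this fixture
demonstrate that the machinery works and that the planted signal is
recovered; they do not certify real-data benchmark performance.

Generator defaults define the reference study: 50 terms, depth ≤ 6,
120 proteins with 3–8 true terms each, 100 positive + 100 negative
pairs, full co-annotation signal, duplication rate 1.0. The reliability
benchmark used for the weighted-vs-unweighted comparison sets
`dup_rate = 1.5` and 4 noise terms per protein — noise comparable to,
but not dominating, the true annotation load.

## Numerical and engineering choices

* **Determinism.** Every stochastic step (graph generation, sampling,
  embedding training, parameter init, epoch shuffling, dropout) runs
  under an explicit seed through one RNG helper that restores the
  caller's RNG state. The full pipeline run twice with one seed produces
  byte-identical metrics and predictions, which both the tests and the
  acceptance script verify.
* **Initialization.** Glorot-uniform weights, zero biases; word2vec
  convention for embeddings (uniform input vectors, zero output
  vectors).
* **Tie-breaks.** Max-pooling routes gradients to the first maximal
  position; the prediction tie `p = 0.5` is negative by the strict rule;
  equal scores in ROC/PR collapse into one threshold group.
* **Degenerate inputs.** Empty annotation sets, single-class corpora,
  unannotated proteins, unknown terms and malformed OBO/GAF lines raise
  errors naming the offending entity or line; zero-frequency terms have
  undefined IC by design.
* **Desk-scale problem sizes.** The pipeline defaults and the
  acceptance script use 32-dimensional term vectors, 32/32 conv
  channels, hidden width 64 and 60 epochs on the 200-pair benchmarks —
  sizes chosen so a full multi-seed study is a minutes-scale, single-CPU
  computation while leaving the architecture identical to the production
  configuration.

## Known limitations

* Pure-R training loops are fine at desk scale but not for
  million-pair corpora; the design isolates the encoder so a compiled
  backend could replace it without interface changes.
* The weighting mechanism needs kernel > 1 to be visible (see above);
  users selecting kernel 1 get an order-free encoder in which weighted
  and unweighted modes coincide by construction.
* Annotation propagation to ancestors happens only inside IC
  computation; sentences use direct annotations. Propagated sentences
  would be a different (and much longer) representation.
* Negative pairs generated for positive-only datasets are uniform
  non-positive pairs, degree-agnostic; degree-matched sampling is a
  known refinement not implemented here.
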