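---
title: "Contextual embeddings with causal multihop paths: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual embeddings with causal multihop paths: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pathcoke implements representation learning for clinical knowledge graphs
built from disease, symptom, drug, mechanism, department and body-part
entities. This vignette explains the models it fits, the choices behind
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical decisions a maintainer would want written down.

## The graph and its multihop paths

A knowledge graph is a triple store G = (E, R, S): entities E, a typed
relation vocabulary R (17 clinical relation types by default, e.g.
`disease=>symptom`, `mechanism =>disease` — the stray space in that last
name is part of the source vocabulary and is kept verbatim), and directed
facts S. Beyond single edges, *paths* s → r1 → … → rk → o carry inference
patterns: a drug whose mechanism treats a disease plausibly treats that
disease. Not every path is causal, though — two symptom edges sharing a
head entity merely co-occur. The miner therefore enumerates only
*chainable* paths (the tail of each step is the head of the next, no
entity revisited) and then applies a whitelist of composition rules: an
ordered relation pair (r1, r2) plus a composed label, by default the two
names joined with `"-"` (so a `mechanism` edge followed by a `treat` edge
becomes the pseudo-relation `mechanism-treat`). Longer paths must compose
through a cascade of rules, each consuming the previous composed label.
Filtered paths are deduplicated on (source, label, target) and can be used
two ways: as extra masked training sequences, and as path queries at
evaluation time.

Rule semantics are deliberately a user-supplied configuration: the causal
patterns are domain knowledge, not something the package infers. Cycle
exclusion (no repeated entity) prevents degenerate self-loops from posing
as causal chains.

## The contextual embedding model

The encoder is a small BERT-style transformer over token sequences
(head, relations…, tail). Each token's hidden state is its element
embedding plus a learned positional embedding, layer-normalised
(dropout during training). L post-norm encoder layers follow (multi-head
self-attention, then a position-wise feedforward with ReLU activation —
the original transformer's activation, chosen here also because it is
cheap and exact). Training masks either the first or the last token of
every edge and path sequence (two instances per sequence) and predicts the
masked *entity* with a softmax restricted to the entity vocabulary;
relations and the `[PAD]`/`[MASK]` specials are never candidates. The
output projection is the transposed element-embedding matrix (weight
tying), so an entity's representation serves both encoding and scoring.

Targets are label-smoothed: the true entity receives probability
ε (default 0.8) and every other entity (1 − ε)/(V − 1). The ε parameter is
read as the *target's* share: any small value would make the target nearly
the least likely label, which cannot be the intent of smoothing.
Optimisation is minibatch Adam (learning rate 1e-3, batch 512) on the mean
smoothed cross-entropy; relations inside paths are fed as individual
relation tokens so the relation vocabulary stays closed, while composed
labels are used only for bookkeeping and query grouping.

Defaults are desk-scale: hidden size 64, 2 layers, 4 heads, feedforward
width equal to the hidden size, dropout 0.1. The compiled kernels
(RcppArmadillo) run in single precision — at these sizes the computation
is memory-bandwidth-bound and float halves the traffic — while the R
reference implementation of the same forward/backward pass runs in double
precision; the test suite asserts the two agree, which also guards each
against the other's bugs. All randomness (initialisation, shuffling,
dropout, negative sampling, tie-breaking) flows from explicit integer
seeds; identical seeds give bit-identical models.

## Knowledge distillation

A compact student (fewer layers, optionally narrower) is trained against a
frozen teacher at three levels, all active at once with unit weights by
default:

* **embedding layer**: mean squared error between the student's
  embedding-block output, projected into the teacher's space by a
  trainable matrix W_e, and the teacher's;
* **mapped transformer layers**: with teacher depth T and student depth S
  (T divisible by S), student layer i is supervised by teacher layer
  i·(T/S) — a 4-layer student of a 12-layer teacher maps 1→3, 2→6, 3→9,
  4→12. Each mapped pair contributes the per-head-averaged MSE between
  attention matrices (teacher and student must share the head count; the
  average is undefined otherwise) and the MSE between projected hidden
  states, with one trainable projection per mapped layer. Per-layer losses
  are summed, not averaged; the loss weights let users renormalise.
* **prediction layer**: cross-entropy between the teacher's
  temperature-softened distribution and the student's log-softmax, teacher
  as target. The temperature default is 1 — no canonical value exists for
  this setting — and is exposed in the configuration.

The embedding and hidden-state losses are computed on the batch's
sequence activations (shape: sequence length × width), not on the full
embedding tables; that is what the projection shapes imply and it keeps
the loss on the same data distribution the student will see. When teacher
and student widths match, projections initialise to the identity.

## Baseline scorers

Eight canonical scoring families sit behind one interface for comparison:
TransE, TransH, TransR, TransD (translational distances after the
family's projection), DistMult, ComplEx, SimplE (bilinear; SimplE keeps
two vectors per entity and an inverse relation), and RotatE (relation
phases, unit modulus by construction). Training is the simplest standard
regime — margin ranking with uniform negative sampling, corrupting head
or tail with probability 1/2 — because the point of the baselines is a
calibrated comparison, not state-of-the-art numbers. All analytic
gradients are verified against finite differences in the tests.

## Evaluation protocol

Link prediction scores all entities for both (h, r, ?) and (?, r, t) of
every test triple and ranks the target in the *filtered* setting: other
known-true candidates (over train ∪ valid ∪ test) are removed first.
Ties are broken uniformly at random under the run's seed — optimistic
tie-breaking is known to inflate ranking metrics — and the random
tie-break is the only stochastic element of evaluation. MRR and Hits@N
aggregate over the 2·|test| queries. Path queries mask the terminal entity
of (s, r1, …, rk); each true target is ranked with the query's other
known targets filtered out, ground truth being exhaustive traversal of
the full graph. A closed-form random-ranking expectation
(P(rank ≤ N) = N/m for m filtered candidates) calibrates Hits@N.

## The synthetic generator

Because the clinical corpora behind this class of model are not publicly
deposited, every component is exercised on seeded synthetic data with
*planted* structure:

* entities per category (default 50 each, named `type:idx` — the prefix is
  readable metadata only; typing always comes from the relation schema);
* base edges drawn per relation with Poisson out-degree (mean 3);
* three default 2-hop composition patterns whose conclusion relation
  exists in the schema (drug=>mechanism ∘ mechanism =>disease ⇒
  drug=>disease, and the disease- and symptom-mechanism analogues); for
  every chainable pair the implied closure edge is materialised with
  probability `closure_rate` (0.8), and `holdout_rate` (0.2) of those
  closures are withheld as the test set — so test edges are exactly the
  facts a compositional model should infer;
* noise edges are added last, only on relations that are no rule's
  premise and never duplicating an existing or implied edge. Both
  restrictions exist so the generator's ledger (every chainable pair with
  its witnesses and materialisation status) can be audited by exhaustive
  re-enumeration of the emitted graph, which the tests do.

Case records for the classifier draw 2–5 syndromes per case (8 syndromes,
121 binary symptom features; both counts are parameterised); features are
the union of
the drawn syndromes' fixed symptom sets. Noise *resamples* each bit from
Bernoulli(0.5) with the given probability rather than flipping it: at
noise 1 this makes features exactly independent of labels (a pure flip at
rate 1 would be the deterministic complement — maximally dependent),
giving the null case its intended meaning.

What the generator does not emulate: real co-occurrence statistics,
degree heavy-tails, annotation noise correlated across relations, or
free-text provenance. Passing tests therefore show that the machinery
recovers planted compositional structure under controlled conditions, not
that it reproduces clinical benchmark numbers.

## The syndrome classifier

The `plain` mode is a feedforward network on the 121-bit symptom vector.
The `kge_sequence` mode keeps that branch and adds a bidirectional
recurrent encoder (tanh cells, mean- and max-pooled over the sequence)
over the embeddings of the case's present symptoms, concatenating both
branches before the sigmoid output layer — a DNN *plus* a bidirectional
recurrent KGE branch, which makes the two modes a controlled comparison
of *adding* the embedding pathway to an otherwise identical network. A sequence-only variant was considered and rejected: it discards
the binary vector the baseline uses, so the comparison would confound the
encoder change with an information change (and on near-separable data the
sequence-only arm cannot reach the plain arm's ceiling). Symptom sequences
use canonical C-locale order, so results are invariant to feature-column
permutation; a case with no symptoms contributes one zero `[PAD]`
embedding and is flagged. Folds are stratified by per-case label count.
Metrics: Hamming loss, micro- and macro-averaged precision/recall/F1
(zero-denominator labels score 0 and are counted).

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data sized for a single CPU:
the end-to-end recovery experiments use the generator defaults
(6 × 50 entities, density 3, closure 0.8, holdout 0.2), three seeds, and
100 training epochs; the acceptance script runs the same study at 200
epochs. Layer norm uses eps 1e-6; the RotatE modulus adds 1e-12 inside
the square root; Adam uses (0.9, 0.999, 1e-8); filtered ranks resolve
ties by a single uniform draw among the tied block. Degenerate inputs are
errors with named offenders (unknown relations, malformed TSV lines,
unmapped symptoms), except where a policy is stated (duplicate triples
dropped with a count; split leakage repaired by reassignment to train,
since filtered evaluation is undefined for never-seen tokens).

## Known limitations

* Path mining is exhaustive; graphs far beyond ~10⁵ triples would need a
  sampling miner.
* The transformer kernels are single-threaded by design (deterministic,
  BLAS-bound); GPU-scale replication of published benchmark tables is out
  of scope.
* Rule reliability is binary (whitelist); no weights are learned for
  partially reliable compositions.
* The distillation temperature and loss weights are exposed but not
  tuned; no canonical values exist for this setting.
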