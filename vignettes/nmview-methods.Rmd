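---
title: "Multi-view prediction of Nm sites: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view prediction of Nm sites: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

2′-O-methylation (Nm) adds a methyl group to the ribose 2′-hydroxyl of
any of the four ribonucleosides (Am, Cm, Gm, Um). It is widespread
across RNA species and functionally consequential, but experimental
mapping (e.g. Nm-seq) is slow and expensive, which motivates sequence-based
classifiers. `nmview` implements a multi-view classifier for candidate
Nm sites: each candidate is represented by a fixed 51-nt window (the
site plus 25 nt of flank on each side) and scored by a neural network
that fuses three complementary views of that window.

## The three feature views

For a window of length $L$ (default 51):

* **Sequence view** $X_{seq} \in \{0,1\}^{L\times4}$: one-hot rows in
  the fixed column order A, C, G, U. An `N` encodes as an all-zero row,
  carrying no signal.
* **Chemical view** $X_{chem} \in \{0,1\}^{L\times3}$: per-base bits
  for ring number (purine vs pyrimidine), functional group (amino vs
  keto) and base-pairing strength (weak A:U vs strong G:C), so
  A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1). The triple
  uniquely identifies the base; it is a re-parameterisation of the
  sequence that groups bases by shared chemistry.
* **Structure view** $X_{str} \in \{0,1\}^{L\times L}$: the symmetric
  base-pair matrix of the window's predicted secondary structure,
  parsed from dot-bracket notation ($X_{str}[i,j]=1$ iff bases $i$ and
  $j$ pair). Structures can be supplied from a file, produced by an
  external folder (a hook that shells out to RNAfold), or by the
  built-in deterministic maximum-pairing (Nussinov) folder. The window
  is folded in isolation, not in its transcript context; predicted
  structure on 51-mers is itself noisy, which bounds how much this view
  can contribute.

## The network

Three branches feed a small fully connected head:

* **CNN branches** (sequence and chemical views): a 1-D convolution
  (64 kernels of width 3, zero same-padding) with ReLU, max-pooling of
  width 2 (stride 2), then a linear projection of the flattened maps to
  a 64-dimensional vector ($X_{seq2}$, $X_{chem2}$).
* **Graph attention branch** (structure view): the window becomes a
  graph with one node per position carrying its one-hot base identity;
  edges are the base pairs plus backbone edges $(i, i\pm1)$ and
  self-loops. Two stacked multi-head graph attention layers (8 heads)
  score each edge with
  $e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$,
  normalise with a softmax over each node's neighbourhood, average the
  attention-weighted neighbour features over heads, and apply an ELU,
  producing per-node features $X_{str2} \in \mathbb{R}^{L\times64}$.
* **Cross-attention fusion**: queries from the sequence vector, keys
  and values from the structure nodes —
  $Q = X_{seq2}W_q$, $K = X_{str2}W_k$, $V = X_{str2}W_v$,
  $A = \mathrm{softmax}(QK^\top/\sqrt{D_k})$, $O = AV$. With the pooled
  sequence vector as the single query, $O$ is one 64-vector that blends
  structure features under sequence guidance.
* **Head**: $O$ concatenated with $X_{chem2}$, then
  FC(64) + ReLU + dropout(0.2) and FC(1) + sigmoid. Training minimises
  mean binary cross-entropy with Adam (learning rate 0.0005, batch 64),
  early-stopped on a stratified 10% validation split (patience 10, at
  most 100 epochs), keeping the best-validation parameters.

### Choices the architecture description leaves open

Several wiring details are not pinned down by the published description
of this model family; `nmview` fixes them as follows and treats them as
part of its own design:

* The structure matrix is used as the **edge set** of the graph; node
  features are the one-hot base identities. (The alternative — using
  matrix rows as node features — leaves the attention mechanism without
  a neighbourhood structure.) Backbone edges and self-loops guarantee
  no node has an empty neighbourhood, which the neighbourhood softmax
  requires. The node identities belong to the *structure* view: with
  the sequence view ablated, the graph still knows its bases, but the
  CNN sequence branch is silenced.
* Head outputs are **averaged** (not concatenated), the nonlinearities
  are ELU (layer output) and LeakyReLU slope 0.2 (attention logits) —
  the customary defaults for this layer type. Two attention layers are
  stacked.
* Cross-attention runs in one direction only (sequence queries
  structure); $O$ is reduced by a mean over the query axis before
  concatenation. With the pooled CNN vector as the only query this mean
  is the identity.
* Classification threshold 0.5; hidden head width 64.
* Under ablation, when either the sequence or the structure view is
  off, cross-attention is skipped: remaining branch vectors are
  concatenated directly. A lone structure branch is flattened over
  nodes rather than mean-pooled: the planted structural signal (like
  real stems) lives at specific window positions, and a mean over
  position-agnostic node embeddings cannot see it.

The ablation switches select among the seven view combinations; with
one view the model degenerates to a plain CNN (or GAT) classifier, so
comparisons across combinations attribute performance to views.

## Implementation: two forward paths

The reference forward pass is written in plain R (`nm_forward()`,
`cnn_branch()`, `gat_layer()`, `cross_attention()`) and is the readable
specification of the network. Training runs on a compiled C++ path that
implements the identical computation plus analytic backpropagation;
the test suite asserts the two paths agree to machine precision on all
seven view configurations, checks the graph attention layer against a
brute-force loop evaluation, and verifies the analytic gradients
against central finite differences. The graph attention is evaluated
over an explicit sparse edge list (base pairs + backbone + self-loops,
about 3–4 neighbours per node) rather than a dense $L \times L$
attention matrix.

All randomness — parameter initialisation, validation split, batch
order, dropout masks, fold assignment, permutations — derives from one
master seed per run; two runs with the same seed are bit-identical
under single-threaded BLAS.

## Evaluation protocol

* `compute_metrics()` reports the confusion counts at threshold 0.5
  (standard definitions: TN = negatives predicted negative), ACC,
  precision, recall, F1, MCC, the trapezoidal AUC of the ROC and the
  step-wise area under the precision-recall curve. Tied scores collapse
  to single operating points, making the trapezoidal AUC equal to the
  tie-corrected Mann–Whitney statistic (asserted in the tests).
* `cross_validate()` uses stratified folds (jointly by label and
  subtype, mirroring the proportional construction of the reference
  compendium's test split); repeated rounds reshuffle folds with
  round-specific derived seeds and report means ± sd.
* `permutation_importance()` permutes one window position of one view
  across the held-out samples of each CV fold and reports the AUC drop,
  averaged over folds (positive = important; the sign convention is
  stated in the output header). For the sequence view the probe
  permutes the CNN input row *and* the matching graph node identity —
  they are the same quantity (position p's base), and leaving the node
  copy intact would let the graph leak the identity past the probe.
  Because the chemical code is a bijection of the base identity, a
  trained network may route a sequence motif through either the
  sequence or the chemical branch; motif-recovery checks therefore sum
  the two profiles. Permuting *across samples* is the
  standard estimator; an alternative reading — shuffling positions
  within each sample — is available as `mode = "within"`. For the
  structure view, row and column $p$ are permuted together with one
  sample permutation, preserving symmetry and the zero diagonal.
* `cross_type_matrix()` holds out a stratified test portion, trains on
  each single subtype and on all subtypes pooled, and evaluates every
  model on every subtype's test set (5 × 4 grid of AUC/AUPR), verifying
  train/test disjointness.

## The synthetic benchmark

Real single-base-resolution Nm site compendia are not redistributable,
so the package ships a generator (`simulate_nm()`) whose defaults
define the benchmark conditions used throughout the tests:

* Balanced classes; background bases i.i.d. uniform; every window
  (positive or negative) carries its subtype's base at the center —
  negatives are *hard*, so the center base itself is uninformative.
* Subtype proportions default to the observed composition of the
  mapped human Nm sites (Am 22.1%, Cm 26.1%, Gm 20.5%, Um 31.3%).
* Sequence signal: a degenerate IUPAC motif (default `GGNCU` at 0-based
  offset 23, straddling the center with an `N` over the center slot so
  the subtype constraint is respected) written into positives with
  probability `motif_strength` (default 0.9 — a strong, clearly
  learnable planted signal).
* Structure signal: with probability `struct_signal` (default 0, i.e.
  off unless requested) an 8-bp complementary stem is planted so the
  window folds into a hairpin enclosing the center; the maximum-pairing
  folder then produces systematically different base-pair matrices for
  positives.
* Structures for all windows come from the built-in deterministic
  folder, so fixtures are reproducible without external binaries.

What the generator does *not* emulate: transcript-context folding,
sequencing artefacts, mapping ambiguity, the position-specific
composition around real Nm sites, or class imbalance. Passing the
synthetic recovery tests therefore demonstrates that the pipeline is
correctly wired and can learn planted signal of each kind — it says
nothing about accuracy on real transcriptomes, which requires the
unavailable experimental site lists.

## Problem sizes and numerical notes

The statistical acceptance checks run at deliberate desk scale: the
strong-signal benchmark uses 1000 windows per class with 5-fold
cross-validation; the null control uses 500 per class; the
structure-signal contrast uses 750 per class and the sequence-signal
contrast 300 per class, each with 2-fold cross-validation (the
structure view generalises more slowly than it memorises, so its
contrast needs the larger sample). At these sizes the full protocol completes in
minutes on one CPU while leaving comfortable statistical margins
(chance-level AUC on 1000 null samples has a standard error of about
0.018, well inside the ±0.05 acceptance band).

Numerical choices: probabilities are clamped at $10^{-7}$ inside the
cross-entropy; softmaxes subtract the row maximum before
exponentiation; max-pooling keeps the first arg-max on ties; a trailing
window position that does not fill a pooling window is dropped;
early stopping requires an improvement greater than $10^{-4}$ in
validation loss. Degenerate inputs fail fast with informative errors:
empty metric input, single-class training data, all views disabled,
non-symmetric structure matrices, unbalanced dot-brackets, windows
overrunning their parent sequence.

## Known limitations

* The maximum-pairing fallback folder ignores thermodynamics; for real
  data, attach RNAfold structures via `rnafold_hook()` or precomputed
  dot-bracket files.
* Windows are folded out of transcript context.
* Training is CPU-only and single-threaded by design (determinism);
  wall-clock scales linearly in samples × epochs.
* The cross-attention uses a single pooled sequence query; a per-position
  query matrix is a straightforward extension the current
  head does not implement.
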