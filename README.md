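# nmview

Multi-view prediction of RNA 2′-O-methylation (Nm) sites.

## The problem

2′-O-methylation decorates the ribose 2′-hydroxyl of all four
ribonucleosides (Am, Cm, Gm, Um) and is involved in translation,
splicing, RNA stability and viral immune evasion. Experimental mapping
at single-base resolution (Nm-seq and relatives) is laborious, so
candidate sites are routinely triaged with sequence-based classifiers.
`nmview` is such a classifier, for computational biologists who want a
self-contained, fully testable implementation of a multi-view deep
architecture together with the complete evaluation protocol around it.

## The model

A candidate site is a 51-nt window (site ± 25 nt) represented in three
views, each feeding its own branch:

* one-hot sequence $X_{seq} \in \{0,1\}^{51\times4}$ → 1-D CNN
  (64 kernels, width 3) + max-pool + linear → $X_{seq2} \in \mathbb{R}^{64}$;
* chemical properties $X_{chem} \in \{0,1\}^{51\times3}$ (ring
  count, amino/keto, pairing strength: A=(1,1,1), C=(0,1,0), G=(1,0,0),
  U=(0,0,1)) → a second CNN branch → $X_{chem2} \in \mathbb{R}^{64}$;
* the base-pair matrix $X_{str} \in \{0,1\}^{51\times51}$ of the
  window's predicted secondary structure → a 2-layer, 8-head graph
  attention network over the pairing graph (plus backbone edges and
  self-loops), $e_{ij} = \mathrm{LeakyReLU}(a^\top[Wh_i\|Wh_j])$,
  $\alpha_{ij} = \mathrm{softmax}_j(e_{ij})$ → per-node features
  $X_{str2} \in \mathbb{R}^{51\times64}$.

Sequence and structure are fused by cross-attention
($Q = X_{seq2}W_q$, $K = X_{str2}W_k$, $V = X_{str2}W_v$,
$O = \mathrm{softmax}(QK^\top/\sqrt{D_k})\,V$); $O$ is concatenated
with $X_{chem2}$ and classified by two fully connected layers with a
sigmoid output, trained with binary cross-entropy (Adam, learning rate
5e-4, batch 64, early stopping on a 10% validation split). The
network and its backpropagation are implemented in RcppArmadillo with
a plain-R reference path used as the oracle in the tests.

The package also ships the full evaluation protocol — stratified k-fold
cross-validation with repeated rounds, the seven-way feature-view
ablation, the cross-subtype train/test matrix, per-position permutation
importance — and a synthetic benchmark generator with plantable
sequence motifs and structural (hairpin) class signal, so that every
stage is testable without the (non-redistributable) experimental site
lists.

## Worked example

```r
library(nmview)

# a synthetic benchmark: 200 windows per class, a degenerate GGNCU
# motif planted in 90% of positives around the center
windows <- simulate_nm(n_per_class = 200, seed = 42)
fit     <- nm_train(windows, nm_config(), seed = 42)
fit
#> <nm_fit> views: seq+chem+str; 21 epochs; best val loss 0.3958

# score an independently simulated held-out set
held    <- simulate_nm(n_per_class = 100, seed = 43)
metrics <- compute_metrics(predict(fit, held)$prob, held$label)
metrics
#> <nm_metrics> n = 200
#>   TP 93  FP 5  TN 95  FN 7 (threshold 0.50)
#>   ACC 0.9400  Precision 0.9490  Recall 0.9300  F1 0.9394
#>   MCC 0.8802  AUC 0.9676  AUPR 0.9760
```

The training run stopped after 21 epochs when the validation loss
(0.396, down from 0.721 at initialisation) stopped improving; on the
held-out set the model recovers the planted motif almost perfectly
(AUC 0.97), misclassifying 12 of 200 windows at the 0.5 threshold.
`autoplot(metrics)` draws the ROC and precision-recall curves;
`cross_validate()`, `run_ablation()`, `cross_type_matrix()` and
`permutation_importance()` run the full protocol and all return tidy
tibbles (with `tidy()`/`glance()`/`autoplot()` methods).

Real data enter through `read_sites()` (FASTA + TSV site table),
`build_windows()` and `attach_structures()` (precomputed dot-bracket
file, the built-in maximum-pairing folder, or `rnafold_hook()` which
shells out to ViennaRNA's RNAfold).

A command-line interface wrapping the same functions is installed at
`system.file("cli", "nmview", package = "nmview")` with subcommands
`simulate`, `encode`, `train`, `predict`, `cv`, `ablate`, `crosstype`
and `importance`.

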