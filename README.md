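# resibind

Per-residue prediction of ligand binding — to metal ions, nucleic acids and
small molecules — from protein-language-model (pLM) embeddings and a
predicted 3D structure, using small graph neural networks. The package is
aimed at structural bioinformaticians who have per-residue embeddings and
AlphaFold/ColabFold-style structure predictions for their proteins and want
multi-label binding-residue annotations plus the tooling to train, evaluate
and stress-test such models without any external dataset.

## The model

A protein of length *L* enters the model twice:

* **Node features** — an *L* × *d* embedding matrix from a pLM
  (*d* ∈ {768, 1024, 1536, 2560}), optionally concatenated with a 20-dim
  normalized DSSP feature vector per residue.
* **Structure** — only as a residue contact graph: from the Cα–Cα distance
  map *D*, residues *i, j* are connected iff *D(i,j)* ≤ *T* (default
  *T* = 17 Å), with edge weight *w(i,j)* = max(1 − *D(i,j)*/*T*, ε), so
  spatially close residues exchange messages strongly and residues near the
  cutoff weakly.

The default architecture is two GraphSAGE layers (*d* → 128 → 3),

&nbsp;&nbsp;&nbsp;&nbsp;hᵢ′ = W_self·hᵢ + W_nbr·(Σⱼ wᵢⱼ hⱼ / Σⱼ wᵢⱼ) + b,

with leaky-ReLU, dropout 0.7 between layers and an independent sigmoid per
ligand class; a residue is called binding to class *C* when *p_C* ≥ 0.5
(multi-label, so several classes may fire). Training minimizes binary
cross-entropy with class weights 8.9 / 7.7 / 4.4 (metal / nucleic / small)
on the positive terms to counter the ≈ 90 % non-binding imbalance, with a
5-fold cross-training protocol and an ensemble-mean final predictor.
Three alternative architectures (two-layer GCN, GraphSAGE + MLP head, and a
parallel GraphSAGE/GATv2 branch network concatenating to 160 features) are
implemented with the same interface.

This design buys a large efficiency win: the default model has **263,043**
trainable parameters versus **657,411** for the reference two-layer
sequence CNN at the same channel widths — a **59.99 %** reduction.

All layers, back-propagation and the optimizer are implemented in R on base
matrices plus `Matrix` sparse operators; everything is deterministic under
a seed, on CPU.

## Worked example

Everything below runs in a few seconds from an empty R session; no
downloads. The synthetic fixture generator produces chains with realistic
Cα spacing, pocket-shaped multi-label annotations at ≈ 10 % prevalence, and
embeddings carrying a plantable class signal.

```r
library(resibind)

## architecture arithmetic
cfg <- model_config("sageconv", input_dim = 1024)
count_parameters(cfg)
#> $layers
#>  sage1  sage2
#> 262272    771
#> $total
#> [1] 263043
parameter_reduction_pct(count_parameters(cfg)$total)
#> [1] 59.99  # % fewer parameters than the reference CNN

## train on synthetic proteins with a planted binding signal
fx <- generate_fixture_set(fixture_spec(n_proteins = 40, d = 64,
                                        length_range = c(60, 90), seed = 1))
inputs <- prepare_inputs(fx$coord_sets, fx$embeddings, fx$labels, threshold = 17)
fit <- train_fold(inputs[1:32], inputs[33:40],
                  model_config("sageconv", input_dim = 64),
                  train_config(max_epochs = 30, patience = 30, seed = 42))
probs <- predict_proteins(fit$model, inputs[33:40])
evaluate_predictions(probs, fx$labels[33:40])
#> metric_set over 8 proteins
#>   metal    F1 0.970 +/- 0.059 | MCC 0.968 +/- 0.062 | prec 1.000 | rec 0.944 (n=3)
#>   nucleic  F1 0.864 +/- 0.123 | MCC 0.859 +/- 0.126 | prec 0.801 | rec 0.950 (n=5)
#>   small    F1 0.888 +/- 0.054 | MCC 0.886 +/- 0.055 | prec 0.944 | rec 0.860 (n=6)
#>   binary   F1 0.904 +/- 0.058 | MCC 0.892 +/- 0.066 | prec 0.905 | rec 0.915 (n=8)
```

Each line is a per-protein mean ± symmetric 95 % CI of the
confusion-derived metric for one ligand class (and the any-class binary
reduction) on the eight held-out proteins: the model recovers the planted
pockets almost perfectly.

A command-line pipeline (`exec/resibind`) exposes the same steps as
subcommands — `simulate`, `featurize`, `build-graphs`, `train`, `predict`,
`evaluate`, `sweep-thresholds`, `count-params` — with defaults matching the
final configuration (SAGEConv, 17 Å, no DSSP, threshold 0.5).

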