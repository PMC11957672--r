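---
title: "Methods: binding-residue prediction on residue contact graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-residue prediction on residue contact graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resibind)
```

## The problem and the modeling idea

Most proteins act by binding non-protein ligands, and knowing *which
residues* form the binding site is the actionable annotation: it localizes
function, guides mutagenesis and supports ligand design. Experimental
binding annotation lags far behind sequencing, so per-residue predictors
trained on curated complexes are the practical route. Protein language
model (pLM) embeddings are strong per-residue features for this task;
predicted 3D structures are now available for essentially any sequence.
`resibind` combines the two in a deliberately minimal way: the structure is
reduced to a **residue contact graph** — nodes are residues, edges connect
C$\alpha$ pairs within a distance cutoff — and small graph neural networks
propagate embedding information along that graph to output, per residue,
three independent probabilities of binding a metal ion, a nucleic acid, or
a small molecule.

The central assumptions are:

* per-residue pLM embeddings already encode most of the relevant
  biochemistry, so the networks can stay small (about 263k parameters at
  the default width, roughly 60 % fewer than a comparable two-layer
  sequence CNN);
* structure is informative mainly through *proximity*, not through exact
  atomic geometry — hence a thresholded distance graph rather than
  coordinates, which also buys rotation/translation invariance for free and
  makes the model robust to moderate coordinate error in predicted
  structures;
* the three ligand classes are not mutually exclusive (a residue can
  contact a metal ion inside a nucleotide pocket), so the output is
  multi-label with per-class sigmoids, not a softmax.

## Graph construction

From the $L\times3$ C$\alpha$ coordinates we compute the full Euclidean
distance map and connect residues at distance $d \le T$. The cutoff $T$ is
in Ångström; the default is **17 Å**, the setting that works well across
ligand classes, and **4 Å** is the degenerate baseline in which only
consecutive residues (3.8 Å apart) remain connected — the graph encoding of
the plain sequence. The comparison is inclusive ($\le$) so that an ideal
backbone distance written at PDB precision still survives a 4 Å cutoff.

Edges are weighted $w = \max(1 - d/T,\ 10^{-6})$: the simplest monotone map
of distance onto $(0, 1]$, giving spatially close pairs strong influence
during message passing. The $10^{-6}$ floor keeps an edge exactly at the
cutoff active instead of silently dropping it. Isolated nodes are legal
(they occur at very small $T$); their neighbor aggregate is defined as the
zero vector. Edge sets are nested in $T$ by construction, which the
threshold-sweep tooling (`sweep_edge_counts`, the `sweep-thresholds`
subcommand) relies on.

## DSSP features

DSSP output is normalized into a fixed 20-column per-residue vector:
relative position ($i/L$, 1 column), secondary-structure one-hot over the
eight DSSP classes in the fixed order H, B, E, G, I, T, S, `-` (8), $\phi$
and $\psi$ (2), relative solvent accessibility (1), and the four backbone
H-bond (relative index, energy) pairs (8). Choices worth recording:

* **Angles.** $\phi,\psi \in [-180°, 180°]$ are mapped by
  $(\text{angle}+180)/360$ — the unique affine map of that range onto
  $[0,1]$. DSSP's 360.0 sentinel for undefined terminal dihedrals becomes
  0 after normalization: deterministic and in range.
* **H-bond fields** are min–max normalized *within each protein*; a
  constant column maps to all zeros. This makes the encoding invariant to
  per-protein constant shifts and positive rescalings of those fields, so
  the (unknowable) sign convention of the relative indices is immaterial.
* **RSA.** Classic DSSP files print absolute accessible surface; the parser
  divides by the Sander/Tien per-residue maximum (the convention of the
  common Python DSSP wrapper) and caps at 1.
* The column order within the 20 is a package convention, frozen in the
  docs and tests.

## Architectures

All four architectures share hidden width 128, dropout 0.7, and a 3-unit
sigmoid output; inference never applies dropout and is bit-deterministic.

* `sageconv` (default): GraphSAGE($d\to128$), leaky-ReLU, dropout,
  GraphSAGE($128\to3$). The GraphSAGE layer is
  $h_i' = W_{self}h_i + W_{nbr}\bar h_{N(i)} + b$ with $\bar h_{N(i)}$ the
  edge-weighted neighbor mean.
* `gcnconv`: two GCN layers with symmetric degree normalization over the
  weighted adjacency plus unit self-loops.
* `sageconvmlp`: one GraphSAGE layer, then a two-layer fully connected head
  ($\to 32 \to 3$); DSSP features, when used, are concatenated to the
  GraphSAGE output (input 148 to the first FC layer). We wire the head
  self-consistently — the second FC layer takes exactly the 32 features the
  first one produces.
* `sageconvgatmlp`: a GraphSAGE branch ($d\to128$) in parallel with a
  second GraphSAGE ($d$ or the 20 DSSP features $\to128$) feeding two
  single-head GATv2 layers that halve the width ($128\to64\to32$); the
  concatenated 160 features pass through an FC head ($160\to32\to3$).
  GATv2 attention uses the customary LeakyReLU slope 0.2 and one head with
  bias — attention hyper-parameters beyond layer count and widths are
  package conventions.

For the two plain graph architectures, DSSP features enter at the input
(e.g. $1024 \to 1044$ with embeddings of width 1024). The second graph
layer maps directly to the 3 classes — no extra linear head — which is what
makes the parameter count as small as advertised: closed-form counts per
layer (GraphSAGE $2\cdot in\cdot out + out$; GCN/FC $in\cdot out + out$;
GATv2 $2\cdot in\cdot out + 2\cdot out$) are verified in the tests against
enumeration of the instantiated weight arrays. The reference point for the
~60 % reduction is a two-layer 1-D sequence CNN (kernel width 5, channels
$1024\to128\to3$, with biases): 657,411 parameters versus 263,043.

GCN normalization includes standard unit self-loops; whether to do so is a
convention and is documented as such. Undirected edges are treated as two
directed edges of equal weight during message passing.

## Training

The loss is mean binary cross-entropy over residues and classes with the
positive term of class $c$ multiplied by its class weight (defaults 8.9
metal, 7.7 nucleic, 4.4 small). The weights counter the strong class
imbalance (roughly 90 % of residues bind nothing): missing a rare binding
residue costs several times more than a false alarm, which deliberately
shifts the operating point toward recall at the fixed 0.5 call threshold.

Optimization details are package design choices, all exposed in
`train_config()`:

* **Adam**, learning rate $3\times10^{-3}$, one protein graph per step
  (protein graphs are small and lengths vary, so per-protein steps are
  simpler than padding/batching; full-batch accumulation was tried and
  converges to the degenerate no-call solution on imbalanced data, so the
  noisy per-protein regime is kept deliberately).
* **Sparsifying L1** (`l1 = 0.1`): after each Adam step, weight matrices
  are soft-thresholded by `learning_rate * l1`. pLM embeddings are wide
  (768–2560 columns) and many of their dimensions carry nothing about
  binding; with only hundreds of training proteins, wide input layers
  otherwise memorize those dimensions and generalization collapses. The
  proximal L1 zeroes uninformative input weights — built-in feature
  selection — and on planted-signal data moves held-out binary F1 from the
  0.2–0.65 range up to the level of an oracle probe that knows the
  informative dimensions (~0.85). Biases and attention vectors are not
  penalized. Decoupled L2 (`weight_decay`) is available as a milder
  alternative, off by default.
* **Early stopping** on validation binary F1 (micro-averaged at threshold
  0.5), patience 20, maximum 200 epochs; the best-validation checkpoint is
  returned.
* **Determinism**: a single seed fixes initialization, epoch shuffling and
  dropout masks; two runs with the same seed reproduce identical weights.

Cross-training follows a 5-fold protocol: fold $k$ trains on the other four
folds and validates on fold $k$, so every development protein is validated
exactly once; the final predictor is the arithmetic mean of the five fold
models' probabilities (a single-fold mode exists as well). The class-weight
scheme applies the weight inside each class's binary cross-entropy — the
multi-label reading consistent with per-class 0.5 thresholds.

## Prediction semantics

`call_binding` applies the inclusive per-class threshold ($p_C \ge 0.5$);
several classes may fire for one residue, and a residue is non-binding only
when all three probabilities stay below threshold. The binary task is the
logical OR of the class calls — consistent with that non-binding
definition. Lowering the threshold can only add calls (monotonicity), which
underlies the PR/ROC sweeps. The per-residue **reliability** score is the
maximum class probability; per-class probabilities are also emitted so
class-specific reliability analyses remain possible.

## Evaluation conventions

Confusion-derived metrics (MCC, precision, recall, accuracy, F1) are
computed per ligand class and for the binary reduction. Conventions:

* degenerate denominators return 0 (MCC with a zero marginal, precision
  with no predicted positives, recall with no observed positives), keeping
  every metric total;
* accuracy uses the standard form $(TP+TN)/(TP+TN+FP+FN)$;
* aggregate performance is reported as the mean over per-protein values
  with a symmetric 95 % CI, $1.96\,\mathrm{SD}/\sqrt{n}$ (normal
  approximation). A protein with neither observed nor predicted positives
  for a class carries no information about that class's precision, recall,
  F1 or MCC; such undefined values are **excluded** from the aggregation
  (and counted), because zero-filling them would bias means downward for
  proteins that simply lack a ligand class. Zero-filling is available via
  `exclude_undefined = FALSE`. Accuracy is always defined and never
  excluded. A single defined value gets half-width 0 with a flag.
* ROC/PR curves are traced by walking thresholds from high to low (both
  FPR and TPR are monotone in the threshold), and areas are trapezoidal
  along that path; the reliability table reports, for each score cutoff,
  the coverage of observed binding residues and the precision above the
  cutoff. The Pearson correlation between per-residue pLDDT and predicted
  binding probability is reported as `NA` with a warning when either side
  is constant.

## Synthetic data: what it does and does not emulate

The fixture generator exists so that every pipeline stage — file formats,
graph construction, training, evaluation — runs and is testable with zero
downloads. Its defaults are fixed once and define the package's reference
experiments:

* **Geometry**: self-avoiding random walks with consecutive C$\alpha$
  spacing exactly 3.8 Å and non-adjacent separation $\ge$ 4.5 Å. This
  reproduces the two spacing facts the graph builder depends on (a 4 Å
  graph is exactly the backbone; non-adjacent contacts appear only at
  larger cutoffs) but is *not* folded protein geometry: no secondary
  structure, no compact core, no realistic contact-order statistics.
* **Annotations**: 2 pocket centers per protein, each labeling all residues
  within 7 Å with a ligand class drawn as (0.3, 0.3, 0.4) over (metal,
  nucleic, small). The 7 Å radius was calibrated once so that total binding
  prevalence lands near 10 %, mirroring the ~90 % non-binding imbalance of
  real binding data, and is frozen. Pockets may overlap, producing
  multi-label residues.
* **Embeddings**: unit Gaussian noise plus $s$ times a fixed orthogonal
  unit direction per class for labeled residues; the default width is
  $d = 1024$, matching the pLM used by the default configuration, and the
  default signal is $s = 3$ — strong enough to be learnable, weak enough
  that single-residue features alone do not saturate the task (neighbor
  aggregation over a pocket demonstrably helps). $s = 0$ is the null
  model: embeddings independent of labels.
* **DSSP records**: field-wise realistic draws (persistent
  secondary-structure runs, grid-aligned dihedrals with undefined termini,
  bounded H-bond energies), *not* a geometric recomputation from the
  coordinates.

Passing the planted-signal experiments therefore shows that the pipeline
can recover a localized, linearly-embedded class signal under realistic
class imbalance and graph structure — it does not certify performance on
real proteins, where the embedding signal is distributed across dimensions
and structure/feature correlations are richer.

## Numerical and reproducibility choices

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the loss.
* Checkpoints store weights as text at `%.17g`, which round-trips IEEE
  doubles exactly; config travels in a JSON sidecar; load-after-save is
  bit-identical.
* Embedding TSVs are written at full precision for exact round-trips;
  prediction TSVs carry 6 decimals (round-trip to $5\times10^{-7}$).
* All randomness flows from explicit integer seeds; derived seeds stay
  below $2^{31}$.
* Graph construction is verified against a brute-force $O(L^2)$
  re-enumeration (edge sets identical, weights to $10^{-12}$ relative —
  the two routes differ only in floating-point summation order); the metric
  formulas are verified exactly against direct evaluation on all ~14,600
  confusion tables with entries $\le 10$.

The reference experiment sizes used by the test-suite and the acceptance
script are the package's chosen desk scale: 100 training / 30 held-out
proteins of length 80–120 at $d = 1024$ for the planted-signal experiment
(about 1–2 minutes on one CPU), smaller sets for unit tests.

## Known limitations

* Single-chain monomers only; multi-chain files are rejected rather than
  concatenated.
* The DSSP parser consumes classic text output (tolerant of the common
  header variants); it does not run DSSP.
* Embeddings are consumed pre-computed; no pLM inference is provided.
* No probability calibration (Platt/isotonic) is applied; reliability
  analyses use the raw sigmoid outputs.
* The GATv2 implementation is single-head; edge features beyond the scalar
  distance weight are not supported.
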