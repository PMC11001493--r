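---
title: "Multi-threshold thermostability classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-threshold thermostability classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopred)
```

## The problem and the model

Proteins from organisms that grow at high temperature must stay folded at
that temperature, so an organism's optimal growth temperature (OGT) gives a
usable lower bound on the thermal stability of its proteome. thermopred
exploits this proxy to train supervised thermostability predictors without
any per-protein melting-temperature measurements:

1. **Representation.** A protein is represented by the mean of its
   per-residue protein-language-model embedding — a vector of length $D$
   (1024 for ProtT5-class encoders; a dataset-level parameter here).
2. **Labels.** For an ascending threshold grid
   $T \in \{40, 45, 50, 55, 60, 65\}$ °C (the extended grid adds
   70, 75, 80), a protein from an organism with growth temperature $t$ gets
   the binary label $y_T = \mathbf{1}[t \ge T]$: "stable at $T$ and above".
   We include the boundary ($t = T$ is class 1), consistent with the
   lower-bound semantics of the OGT proxy. The labels are monotone
   non-increasing along the grid by construction, which later makes
   *consistency* of independent per-threshold predictions a meaningful
   diagnostic.
3. **Classifier.** One binary classifier per threshold: a multilayer
   perceptron $D \to 256 \to 128 \to 1$ with rectified-linear hidden
   activations and a logistic output, trained with mini-batch Adam
   (learning rate $10^{-4}$, weight decay $10^{-4}$, batch size 24).
   Because the label prevalence varies strongly with the threshold, batches
   are drawn with replacement under inverse-class-frequency weights, giving
   each batch an expected 1:1 class balance.
4. **Model selection.** After every epoch the classifier is evaluated on
   the whole validation set and the snapshot with the highest Matthews
   correlation coefficient (MCC) is kept; ties go to the earliest epoch.
   MCC is the primary metric throughout because it is robust to class
   imbalance. The validation set is always evaluated unweighted, even
   though training batches are resampled: computing a metric under a
   resampling sampler is ill-defined, so the sampler is confined to the
   gradient steps.
5. **Ensembles.** Each threshold gets five members differing only in
   training seed; at inference their probabilities are averaged.

## Cluster-disjoint splitting

Homologous sequences are near-duplicates for a mean-embedding classifier,
so a random split would leak training information into the test set. The
package therefore splits at the level of sequence-identity clusters
(e.g. a CD-HIT clustering at 30% identity, parsed from `.clstr` files):
cluster ids are shuffled with the split seed, and each whole cluster is
assigned to the subset (train / validation / test) with the largest
remaining deficit relative to its target share of the *sequence* count.
Filling by sequence count rather than cluster count is the deliberate
choice, since target fractions describe example counts, and published
corpus splits are reported in sequences. Default fractions are
0.70/0.15/0.15. With many clusters the realized fractions converge to the
targets; with a single dominating cluster the split degenerates to one
subset, which is reported with a warning rather than silently broken up,
because cluster atomicity is the invariant that prevents leakage.

When no external clustering is available, `greedy_cluster()` provides a
self-contained stand-in: sequences are sorted by descending length and each
joins the first cluster whose representative shares at least the identity
threshold of 5-mer containment identity (shared distinct 5-mers over the
smaller set). This is not a replacement for a proper identity clusterer on
real proteomes; it exists so the pipeline is exercisable end to end and is
validated against planted family structure in the tests.

## Multi-threshold consistency: left/right labels and clashes

The per-threshold classifiers are trained independently, so their binary
calls over the ascending grid need not be monotone. The package condenses
an ordered call vector into two temperature-range labels over the tiling
$(-\infty, T_1), [T_1, T_2), \dots, [T_n, \infty)$, rendered `"<40"`,
`"[40,45)"`, …, `"65+"`:

* the **left-hand label** scans from the lowest threshold and names the
  range of the last positive call in the *leading* run of 1s (stopping at
  the first 0);
* the **right-hand label** names the range of the highest positive call
  anywhere;
* a **clash** is flagged when the two differ.

The left-hand rule is interpreted as "last 1 of the leading run" rather
than "last 1 anywhere": under the latter reading the two labels could never
differ, which would contradict the existence of clashes — the scan-based
reading is the only internally consistent one. Exactly the monotone
non-increasing call vectors ($n + 1$ of the $2^n$ possible) are clash-free,
and for those both labels name the highest temperature range at which the
protein is still predicted stable; the tests verify this exhaustively for
all $n \le 9$. The decision cutoff for binarizing probabilities defaults to
0.5 (boundary inclusive); it is exposed as a parameter since it is a
convention, not a fitted quantity.

## Metric panel

All metrics are computed from first principles and checked against
independent brute-force oracles in the test suite: confusion counts, MCC
(with the standard MCC = 0 convention when a confusion-matrix margin is
zero — needed in early epochs when a model predicts one class), accuracy,
precision, recall, specificity, F1, ROC AUC and PR AUC. Two conventions
are worth stating because alternatives exist:

* **ROC AUC** uses the rank (Mann–Whitney) statistic with ties counted one
  half — exact under ties, no curve interpolation.
* **PR AUC** uses average-precision style step summation
  $\sum_i (R_i - R_{i-1}) P_i$ over descending distinct score cut-points,
  not trapezoidal interpolation (the two differ; precision is not linear
  between operating points).

`pca2()` provides the two-component PCA used as embedding quality control
(mean-centred, unscaled), with explained-variance fractions.

## The synthetic-data generator

Every stage of the pipeline must run and be testable offline, so the
package ships a generator of OGT-annotated proteomes with controllable
class signal. Organism growth temperatures are drawn either uniformly on
0–100 °C (emulating a broad-coverage corpus) or from an equal-weight
mesophile/thermophile mixture uniform on 20–40 °C and 60–80 °C (emulating
a bimodal corpus); a fixed list can also be supplied. Sequences are random
strings over the 20 standard residues: sequence content is deliberately
decoupled from the embedding signal so that classifier behaviour is tested
in isolation from embedder behaviour.

Mean embeddings follow a single-direction linear signal model:

$$x_i = \mu + \beta\,\frac{t_i - 50}{50}\,\sqrt{D}\,u + \varepsilon_i,
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma^2),$$

with $\mu$ a fixed seeded base vector and $u$ a fixed seeded unit
direction. Since a unit vector's entries are $O(1/\sqrt D)$, the
$\sqrt D$ factor makes $\beta$ the *per-coordinate* effect size at the OGT
extremes relative to the per-coordinate noise sd $\sigma$ — the scaling a
practitioner would call an effect size, and the one under which the
package's recovery experiments are well-posed: at $\beta = 3$, $\sigma = 1$
the Bayes error of each threshold classifier is ~1–2%, so a correct
implementation should recover held-out MCC well above 0.9, while at
$\beta = 0$ there is no signal at all and MCC should sit at chance.
A linear signal through one direction is also the simplest model under
which all per-threshold classifiers should be mutually consistent, making
the held-out clash rate a meaningful test statistic (near zero when
training works).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real pLM embeddings are anisotropic with heavy
cluster structure; biological OGT labels are noisy proxies (a mesophile's
proteome contains thermostable proteins); the stability signal in real
embeddings is not a single linear direction; and homology structure
couples sequences to embeddings, whereas the planted families here only
couple sequences. Results on the generator validate the machinery, not
biological performance.

`make_cluster_structure()` plants homolog families (a founder plus
point-mutated copies at a configurable per-position rate, family size
including the founder) with a known ground-truth cluster table, used to
validate both the greedy clusterer and split integrity.

## Numerical and design choices

* **Loss**: binary cross-entropy — the standard pairing with a logistic
  output. Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  loss only.
* **Initialization**: seeded uniform fan-in,
  $U(-1/\sqrt{\text{fan\_in}}, 1/\sqrt{\text{fan\_in}})$ for weights and
  biases; the scheme is recorded in each checkpoint's metadata.
* **Optimizer**: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$) with L2 weight decay folded into the gradient
  (the coupled convention of classic Adam, not decoupled AdamW).
* **Epoch definition**: $\lceil N/24 \rceil$ weighted-with-replacement
  batches, $N$ the training-set size; 30 epochs by default with no early
  stopping beyond the max-MCC snapshot.
* **Ensemble members** differ only by training seed, derived
  deterministically from the base seed and the threshold.
* **Determinism**: every random step (simulation, splitting, sampling,
  initialization) runs under an explicitly derived seed, and training is
  bit-reproducible under single-threaded BLAS; provenance records contain
  no timestamps so identical runs produce identical files.
* **Segment pooling** uses stride 1 and no partial edge windows: "each
  k-residue segment gets a prediction" implies dense coverage, and a
  partial window would average a different number of residues than the
  model was asked about.
* **Per-residue / per-segment prediction** feeds residue-level vectors to
  models trained on sequence means; the output header flags these modes as
  exploratory since train and inference representations differ.
* **Checkpoints** are directories of text arrays (17 significant digits —
  exact for IEEE doubles) plus a JSON descriptor with an explicit format
  version; loading validates every array shape against the descriptor.

## Problem sizes used in the checks

The packaged experiments run at desk scale, chosen so the full suite
completes in minutes while leaving comfortable statistical margins: the
end-to-end recovery experiment uses 3000 organisms (one protein each,
uniform OGT, $D = 128$, $\beta = 3$, $\sigma = 1$) with a 70/15/15 split
and all six default ensembles of five members; the imbalance experiment
trains on 900:100 examples at $\beta = 2$ over three seeds; the
reproducibility check runs the whole five-command pipeline twice at 150
organisms and compares every output file byte for byte.

## Known limitations

* The OGT proxy itself: labels are organism-level, not protein-level; the
  package measures recovery of the proxy, which is the ceiling of what
  this supervision can teach.
* `greedy_cluster()` is a containment heuristic, not an aligner; at low
  identity thresholds on real data it will over-merge repetitive sequences.
* No probability calibration: ensemble averages are treated as scores, and
  clashes are reported, not resolved.
* The real-encoder adapter (`plm_embed()`) is a contract slot; no
  pretrained network ships with the package, and nothing else depends on
  one.
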