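---
title: "Methods: language-model gene embeddings for single-cell analysis"
author: "scelmo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: language-model gene embeddings for single-cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scelmo)
```

## The model

scelmo turns a normalized single-cell expression matrix $X_{n \times m}$
($n$ cells, $m$ genes) and a table of per-gene embedding vectors
$E_{m \times t}$ — typically the embedding of a language-model-generated
functional description of each gene — into per-cell vectors in the same
$t$-dimensional space:

$$ e_i \;=\; \mathrm{AVG}(X_i)\, E \;(+\; s_{c_i}), $$

where the averaging operator is either the *arithmetic average* (`aa`),
$\mathrm{AVG}_{aa}(X_i) = X_i / m$, or the *weighted average* (`wa`),
$\mathrm{AVG}_{wa}(X_i) = X_i / \sum_j X_{ij}$, and $s_{c}$ is an optional
embedding of the cell's state label $c$. The underlying assumption is that
the embedding geometry of gene descriptions reflects functional
similarity, so an expression-weighted combination of gene vectors places
transcriptionally similar cells near each other. Under `wa` each cell's
weights sum to one, which makes the embedding invariant to per-cell
rescaling of expression — the reason `wa` is the default for clustering
and batch-effect correction, where library-size artefacts are the enemy.
`aa` preserves the overall expression magnitude and is the convention when
the embeddings feed downstream perturbation models.

Everything that consumes these vectors is *zero-shot*: clustering,
integration scoring, and kNN label transfer involve matrix operations and
similarity search only, no training.

## The contrastive adaptor

When reference and query data come from different sources, zero-shot kNN
transfer degrades. The adaptor is a deliberately small MLP
$T : \mathbb{R}^t \to \mathbb{R}^{d}$ (ReLU hidden layers, default widths
256 and 128; the last hidden layer is the latent space) trained with the
joint objective

$$ L_\text{total} = L_\text{classifier} + \lambda\, L_\text{contrastive},
   \qquad \lambda = 100, $$

where $L_\text{classifier}$ is mean multiclass cross-entropy on the label
head and $L_\text{contrastive}$ is a supervised contrastive loss on the
L2-normalized latent vectors: for anchor $a$ with same-label positives
$P(a)$,

$$ -\frac{1}{|P(a)|} \sum_{p \in P(a)} \log
   \frac{\exp(\cos(z_a, z_p)/\tau)}{\sum_{b \neq a} \exp(\cos(z_a, z_b)/\tau)},
   \qquad \tau = 0.1, $$

averaged over anchors that have at least one positive. The contrastive
form and temperature are our concretization — the joint-objective design
prescribes a contrastive term without writing one out — and both are
configurable (`adaptor_config()`), as is the label column it uses
(`contrastive_labels`, defaulting to the classification labels; pass the
condition column instead when the latent space should separate disease
states). The large default $\lambda$ makes label-aware clustering of the
latent space the dominant term, which is what the downstream kNN
annotation and the deletion screen consume.

Training uses Adam (learning rate $10^{-3}$), minibatches of 256, early
stopping on validation accuracy with patience 10, and returns the weights
of the epoch with the best validation accuracy (earliest on ties). All
randomness — initialization and batch order — derives from
`config$seed`, so two runs with one seed are bitwise identical. Anchors
without positives are excluded from the contrastive term; a batch with no
positives at all contributes 0 with a flag. Batches of size one skip the
contrastive term for the same reason.

## The in-silico deletion screen

For a disease/control contrast the screen asks: deleting which gene moves
diseased cells toward the control state? Candidates are the `top_k`
(default 10) genes ranked by a Wilcoxon rank-sum test of disease versus
control expression (ties broken by descending absolute mean difference;
BH-adjusted p-values are reported but ranking uses raw p-values, and the
candidate set is fixed once on the unmodified matrix). For each candidate
$g$:

* `cs_old`: cosine similarity between the mean adaptor-latent embedding
  of disease cells and that of control cells;
* `cs_new`: the same after setting $g$'s expression to zero *in the
  disease cells only* and re-aggregating and re-embedding them through the
  frozen model (under `wa` the remaining weights renormalize, as they
  must);
* $\mathrm{Score}(g) = \texttt{cs\_new} - \texttt{cs\_old}$, and $g$ is
  flagged a therapeutic-target candidate when the score exceeds `1e-4`.

The similarity is mean-vs-mean; a per-cell-averaged variant (each disease
cell against the control mean) is available via
`cs_method = "per_cell"` since the two readings are both defensible. If a
group's mean latent vector is exactly zero, its cosine is defined as 0 and
flagged. Deleting a gene with zero expression in disease cells is a no-op
by construction, so its score is exactly 0.

A practical note on scale: with a latent space of non-negative ReLU
activations, group means tend to be nearly parallel and `cs_old` sits very
close to 1, so scores live at the $10^{-4}$ magnitude the candidate
threshold is calibrated to. In that regime the ranking among
marginal-score genes is sensitive to the adaptor's training seed; the
planted-truth recovery experiments below should be read as "the driver is
recovered in the large majority of runs", not as a deterministic
guarantee.

## The metric suite

All scores are oriented so that higher is better and, except $R^2$, live
in $[0, 1]$.

* **NMI / ARI** (`cluster_scores()`): exact kNN graph (default
  `graph_k = 15`, euclidean), community detection swept over resolutions
  $0.1, 0.2, \ldots, 2.0$; NMI is the maximum agreement of Leiden
  (modularity objective) partitions with the cell-type labels, ARI the
  maximum for Louvain partitions. Seeded and bitwise reproducible.
* **Silhouettes** (`asw_scores()`):
  $\mathrm{ASW}_\text{label} = (\mathrm{sil}+1)/2$ on cell types;
  $\mathrm{ASW}_\text{batch} = 1 - (\mathrm{sil}+1)/2$ on batches, so
  batch separation is penalized. Singleton labels are excluded and
  tallied.
* **LISI** (`lisi_scores()`): the verbal "count until a label repeats"
  sketch does not define a deterministic statistic, so the raw per-cell
  score is the standard inverse Simpson index of label proportions over
  the `graph_k` nearest neighbours; then
  $\mathrm{iLISI} = (\text{raw}-1)/(B-1)$ and
  $\mathrm{cLISI} = 1 - (\text{raw}-1)/(C-1)$.
* **PCR** (`pcr_score()`): $\sum_i \frac{\mathrm{Var}(PC_i)}{\sum_j
  \mathrm{Var}(PC_j)} R^2(PC_i \sim \text{covariate})$ over
  $G = \min(50, n-1, t)$ components (the count is not standardized
  anywhere we could find; 50 is the common practice). The raw sum grows
  with batch signal, so the reported score is $1 - \text{raw}$ (raw is
  exposed as an attribute) to match the higher-is-better convention of
  the other batch metrics. Zero-variance components contribute 0.
* **Graph connectivity** (`graph_connectivity()`): per cell type, the
  fraction of cells in the largest connected component of the
  type-restricted kNN subgraph, averaged over types; singletons score 1.
* **kBET** (`kbet_score()`): per cell, a Pearson chi-square
  goodness-of-fit of neighbourhood batch counts against global batch
  frequencies; the score is the fraction of cells not rejected at
  `alpha = 0.05`. The original algorithm's subsampling machinery is not
  part of the description we implement.
* **Aggregates** (`aggregate_scores()`): $S_\text{batch}$ is the
  arithmetic mean of $\{\mathrm{ASW}_\text{batch}, \mathrm{PCR},
  \mathrm{GC}, \mathrm{kBET}, \mathrm{iLISI}\}$ and $S_\text{bio}$ of
  $\{\mathrm{ASW}_\text{label}, \mathrm{NMI}, \mathrm{ARI},
  \mathrm{cLISI}\}$, each over the components actually present (absent
  ones are listed, never imputed).
* **Annotation** (`annotation_metrics()`): accuracy plus macro-averaged
  precision/recall/F1 over truth classes (weighted averaging by flag);
  classes never predicted contribute precision 0.
* **Regression** (`regression_metrics()`): per-gene
  $R^2 = 1 - SS_\text{res}/SS_\text{tot}$ (not clamped; a bad predictor
  goes negative), per-gene Pearson correlation averaged over genes, and
  pooled MSE.
* **BLEU** (`bleu_score()`): single-order modified n-gram precision — the
  clipped candidate n-gram matches over total candidate n-grams — with no
  brevity penalty and no geometric mean across orders. Tokenization is
  lowercasing, punctuation stripping, and whitespace splitting, and the
  default order is $n = 2$; the definition in circulation fixes neither,
  so both are parameters. Candidates shorter than $n$ tokens score 0 with
  a flag.

## Embedding tables, providers and the random control

Embedding tables load from TSV (id + floats) or JSON maps; gene matching
everywhere is case-insensitive exact string match, and genes present on
only one side of an expression/table pair are **dropped**, with the
coverage fraction reported — zero-filling missing genes would silently
bias the averages toward zero. A provider contract (`describe`: name to
text; `embed`: text to vector) stands in for any live language model; the
shipped implementations are file-backed and random only, and prompt
templates (exactly one `{}` placeholder) are plain data, editable, never
hard-coded.

`random_embedding_table()` draws i.i.d. standard normal entries — the
"meaningless embedding" control. Under `wa` aggregation it acts as a
random projection of the expression profile, so a fine-tuned adaptor on
top of it can still classify well; comparing informative against random
tables isolates how much the embedding *semantics* contribute beyond the
projection.

`embedding_stability()` summarizes replicate embeddings of the same id
(within-gene pairwise cosines) against distinct ids (cosines of mean
replicate vectors — means, because the replicate jitter is what the
within-gene number already measures). Pairs with a zero vector are
skipped and tallied.

## The synthetic generator

`simulate_dataset()` provides the study conditions for every test:
genes partitioned into modules, each cell type activating its own module
(log-scale shift `module_effect = 2`), additive per-batch per-gene shifts
(`batch_effect = 0.5`), lognormal noise (`noise_sd = 0.3`), and
Poisson-lognormal counts. Gene embeddings are orthonormal module
centroids in $\mathbb{R}^t$ plus Gaussian jitter
(`embedding_noise_sd = 0.25`); state embeddings are the exact per-type
centroids. These defaults produce clearly separable but non-trivial
structure at a few hundred cells — the minimal structure under which the
zero-shot claims can hold at all, chosen once as plausible for a clean
sorted-population experiment.

For the treatment scenario, cells of the first type are split into
matched disease and control halves (other cells are labelled
`background`, so the contrast is never confounded by type composition),
and `n_driver_genes` genes from modules *inactive* in that type are
elevated by `driver_effect = 3` in disease cells only; generation checks
empirically that every driver's disease mean exceeds its control mean.

What the generator does **not** emulate: the anisotropy and norm
distribution of real language-model embeddings, dropout structure and
depth variation of real scRNA-seq, ambient contamination, doublets, or
continuous (trajectory-like) states. Passing tests therefore show the
machinery is faithful to its definitions and recovers planted structure;
they do not certify performance on real tissue atlases.

## Numerical choices and degenerate inputs

* Zero-total cells survive normalization and aggregation as all-zero
  rows with a tally (never NaN); dropping them is an explicit caller
  decision.
* `wa` scale invariance is exact in floating point for power-of-two
  rescalings and holds to ~1e-12 otherwise; `aa` equals `wa` bitwise when
  row sums equal $m$ exactly in double precision.
* kNN ties (equal distances) resolve to the lower row index; vote ties
  resolve by smallest mean distance, then lexicographically — the whole
  transfer is deterministic.
* Cross-entropy uses max-shifted softmax; probabilities are floored at
  1e-300 before logs.
* The contrastive gradient treats zero-norm latent vectors as having
  zero gradient (the normalization is non-differentiable there).
* Model archives and embedding tables serialize numbers at 17
  significant digits, which round-trips doubles exactly.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale, chosen to exercise every code path while keeping a
full run in tens of seconds on one CPU: the annotation scenario at 1,000
cells x 200 genes with $t = 64$ and an adaptor of hidden widths (64, 32);
the integration scenario at 600 cells over 3 batches; the treatment
scenario at 500 cells x 120 genes with one planted driver, screened over
10 generation seeds. Headline numbers from real tissue datasets and
closed-source embedding APIs are out of reach of such fixtures by design;
the package verifies formula fidelity, planted-truth recovery and
reproducibility instead.

## Known limitations

* No HDF5/AnnData container input; expression loads from matrix-market or
  dense TSV plus id tables.
* No live LLM providers ship; the provider contract accepts user
  callables but all shipped tables are file-backed, synthetic, or random.
* The adaptor is CPU-only by design; atlas-scale corpora and transformer
  architectures are out of scope.
* Deletion-screen scores are differences of cosines near 1; their
  ranking among near-threshold genes varies with the adaptor seed (see
  above), so candidate lists should be read across seeds, not from a
  single run.
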