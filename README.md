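# scelmo

Language-model gene embeddings for single-cell analysis: zero-shot cell
embeddings, a lightweight contrastive adaptor for annotation, and an
in-silico gene-deletion screen for therapeutic-target ranking — with the
full scIB-style metric suite and a planted-structure synthetic data
generator, so every stage runs and is testable without any LLM API
access.

## What it does

Modern LLMs can summarize what a gene *does*, and the embedding of that
summary places functionally similar genes near each other. Given a
normalized expression matrix `X` (cells x genes) and a gene-embedding
table `E` (genes x t), scelmo builds per-cell vectors

    e_i = AVG(X_i) E (+ s_c)

with `AVG` either the arithmetic average (`aa`, divide by the gene count
`m`) or the weighted average (`wa`, divide each row by its own sum, the
default for clustering/integration), optionally adding a cell-state
embedding `s_c`. These zero-shot embeddings feed clustering, batch-effect
evaluation and kNN label transfer directly. For harder transfer settings
a small ReLU MLP (*adaptor*) is trained with the joint objective

    L_total = L_classifier + lambda * L_contrastive,   lambda = 100

(cross-entropy head plus a supervised contrastive loss at temperature
0.1 on the latent layer). The deletion screen then ranks the top
differentially expressed genes between a disease and a control group by

    Score(g) = CS_new - CS_old

the change in cosine similarity between the disease and control mean
latent embeddings after zeroing gene `g` in the disease cells only;
`Score(g) > 1e-4` flags `g` as a therapeutic-target candidate.

Audience: computational biologists who want to use LLM-derived gene (or
protein) embeddings as priors for scRNA-seq / proteomic analysis, and
methods developers who need a reproducible, dependency-light reference
implementation of the aggregation, adaptor and screen.

## Worked example

```r
library(scelmo)

## a synthetic dataset with 5 cell types across 2 batches, and gene
## embeddings correlated with the co-expression modules
ds  <- simulate_dataset(preset_config("annotation", seed = 1))
emb <- zero_shot_embeddings(ds$expression, ds$informative_embeddings,
                            mode = "wa")
emb
#> CellEmbeddings: 1000 cells x 64 dims
#> provenance: mode=wa; gene_table=synthetic:seed=1; coverage=1

## zero-shot annotation: kNN label transfer, no training
truth <- ds$expression$cell_type
set.seed(1)
test  <- sort(sample(1000, 200)); train <- setdiff(1:1000, test)
zs <- knn_annotate(emb$vectors[train, ], truth[train],
                   emb$vectors[test, ], k = 10)
annotation_metrics(zs$labels, truth[test])
#> accuracy 1.0000 | precision 1.0000 | recall 1.0000 | f1 1.0000 (macro)

## fine-tune the contrastive adaptor and annotate in its latent space
cfg <- adaptor_config(input_dim = 64, n_classes = 5,
                      hidden_dims = c(64, 32), max_epochs = 40,
                      patience = 8, seed = 1)
fit <- scelmo_adaptor(emb$vectors[train, ], truth[train], config = cfg)
fit
#> scelmo adaptor
#>   architecture: 64 -> 64 -> 32 -> 5 classes (ReLU)
#>   lambda = 100, temperature = 0.1, seed = 1
#>   trained 28 epochs; best epoch 20 (val accuracy 0.605)
ft <- annotate_finetuned(fit, emb$vectors[train, ], truth[train],
                         emb$vectors[test, ], k = 10)
annotation_metrics(ft$labels, truth[test])
#> accuracy 1.0000 | precision 1.0000 | recall 1.0000 | f1 1.0000 (macro)
```

On this clean simulation both routes annotate the held-out cells
perfectly; the adaptor's printed validation number is its *classifier
head* accuracy, which the contrastive-dominated objective (lambda = 100)
leaves well below the latent-space kNN accuracy actually used downstream.

The deletion screen on a dataset with one planted disease driver:

```r
dst <- simulate_dataset(preset_config("treatment", seed = 1))
x   <- log_normalize(dst$expression)
al  <- align_features(x, dst$informative_embeddings)
embt <- aggregate_cells(al$x, al$table, mode = "wa")
cfg2 <- adaptor_config(input_dim = 32, n_classes = 3,
                       hidden_dims = c(64, 32), max_epochs = 30,
                       patience = 6, seed = 1)
fit2 <- scelmo_adaptor(embt, al$x$condition, config = cfg2)
scr  <- screen_targets(fit2, al$x, al$table, "disease", "control",
                       mode = "wa", top_k = 10)
head(as.data.frame(scr), 3)
#>    gene_id cs_old cs_new      score candidate
#> 1 gene_111 0.9998 0.9999  1.073e-04      TRUE
#> 2 gene_116 0.9998 0.9999  2.745e-05     FALSE
#> 3 gene_075 0.9998 0.9998 -2.982e-06     FALSE
dst$truth$driver_gene_ids
#> [1] "gene_111"
```

The planted driver is the top-scoring gene and the only candidate above
the `1e-4` threshold: deleting it moves the diseased cells' mean
embedding toward the control state.

Other entry points: `load_expression()` / `write_expression()` (MTX or
dense TSV), `load_embedding_table()` (TSV/JSON),
`random_embedding_table()` (the meaningless-embedding control),
`add_state_embeddings()`, `evaluate_embeddings()` (NMI, ARI, silhouettes,
LISI, PCR, graph connectivity, kBET, and the `S_batch`/`S_bio`
aggregates), `bleu_score()` and `embedding_stability()` for description
and embedding quality, `save_adaptor()` / `load_adaptor()` for model
archives.

## Vignette

`vignettes/scelmo-methods.Rmd` documents the model, the loss, the screen,
every metric definition and normalization, the synthetic generator's
assumptions, and numerical edge-case policies.
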