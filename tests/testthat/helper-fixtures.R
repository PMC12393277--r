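# Shared builders for small in-code fixtures.

toy_expression <- function(values, layer_tag = NULL, ...) {
  values <- as.matrix(values)
  expression_matrix(values,
                    gene_ids = sprintf("g%d", seq_len(ncol(values))),
                    cell_ids = sprintf("c%d", seq_len(nrow(values))),
                    layer_tag = layer_tag, ...)
}

toy_table <- function(vectors, ids = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(vectors)))
  gene_embedding_table(ids, vectors)
}

# Adaptor whose single hidden layer is the identity map (latent =
# ReLU(input)) and whose classification head is all-zero: a deterministic
# hook for reduction tests.
identity_adaptor <- function(d, n_classes = 2) {
  cfg <- adaptor_config(input_dim = d, n_classes = n_classes,
                        hidden_dims = d, max_epochs = 1)
  weights <- list(
    list(W = diag(d), b = numeric(d)),
    list(W = matrix(0, d, n_classes), b = numeric(n_classes)))
  structure(list(config = cfg, weights = weights,
                 class_labels = sprintf("k%d", seq_len(n_classes)),
                 history = data.frame(), best_epoch = 1L,
                 best_validation_accuracy = NA_real_),
            class = "scelmo_adaptor")
}

# Deterministic 80/20 split of cell indices.
split_cells <- function(n, seed, test_frac = 0.2) {
  set.seed(seed)
  test <- sort(sample(n, round(test_frac * n)))
  list(train = setdiff(seq_len(n), test), test = test)
}

# Zero-shot + fine-tuned accuracies on a simulated dataset; the small
# architecture keeps test runtimes low without changing the objective.
annotation_accuracies <- function(ds, seed, hidden = c(64, 32),
                                  max_epochs = 40, patience = 8) {
  emb <- zero_shot_embeddings(ds$expression, ds$informative_embeddings,
                              mode = "wa")
  truth <- ds$expression$cell_type
  sp <- split_cells(nrow(emb$vectors), seed)
  tr <- emb$vectors[sp$train, , drop = FALSE]
  te <- emb$vectors[sp$test, , drop = FALSE]
  zs <- knn_annotate(tr, truth[sp$train], te, k = 10)
  cfg <- adaptor_config(input_dim = ncol(tr),
                        n_classes = length(unique(truth[sp$train])),
                        hidden_dims = hidden, max_epochs = max_epochs,
                        patience = patience, seed = seed)
  fit <- scelmo_adaptor(tr, truth[sp$train], config = cfg)
  ft <- annotate_finetuned(fit, tr, truth[sp$train], te, k = 10)
  list(zero_shot = mean(zs$labels == truth[sp$test]),
       finetuned = mean(ft$labels == truth[sp$test]),
       fit = fit)
}
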