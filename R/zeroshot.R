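#' Construct a cell embeddings object
#'
#' Cells-by-`t` matrix of per-cell vectors in the embedding space, with a
#' provenance record describing how it was produced.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param vectors numeric matrix, one row per cell.
#' @param provenance list; conventionally holds `mode`, `gene_table`,
#'   `state_table`, `coverage` and (after fine-tuning) `model`.
#' @return an object of class `CellEmbeddings`.
#' @export
cell_embeddings <- function(cell_ids, vectors, provenance = list()) {
  cell_ids <- as.character(cell_ids)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(cell_ids) != nrow(vectors)) {
    stop("cell_ids and vector rows differ in length")
  }
  .stopifnot_finite(vectors, "cell embeddings")
  rownames(vectors) <- cell_ids
  structure(list(cell_ids = cell_ids, vectors = vectors,
                 provenance = provenance),
            class = "CellEmbeddings")
}

#' @export
print.CellEmbeddings <- function(x, ...) {
  cat(sprintf("CellEmbeddings: %d cells x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  if (length(x$provenance)) {
    keep <- !vapply(x$provenance, is.null, logical(1))
    cat("provenance:",
        paste(names(x$provenance)[keep],
              vapply(x$provenance[keep], function(v)
                paste(format(v), collapse = ","), character(1)),
              sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
dim.CellEmbeddings <- function(x) dim(x$vectors)

#' Aggregate gene embeddings into cell embeddings
#'
#' The zero-shot step: each cell's embedding is an expression-weighted
#' combination of the gene embedding matrix `E`. Under `aa` (arithmetic
#' average) the weights are the cell's expression row divided by the number
#' of genes `m`; under `wa` (weighted average) the row is divided by its own
#' sum, so the weights of each cell sum to one and the result is invariant
#' to per-cell rescaling. `wa` is the default: it respects the per-cell
#' scale of log-normalized expression and works better for clustering and
#' batch-effect correction, while `aa` is the convention for driving
#' perturbation models.
#'
#' `x` and `ef` must already be feature-aligned (see [align_features()]):
#' same genes, same order. Cells with an all-zero expression row yield an
#' all-zero embedding; their count is stored in the `n_zero_cells`
#' attribute.
#'
#' @param x an `ExpressionMatrix`; log-normalized input is recommended (a
#'   warning is emitted for raw counts).
#' @param ef a `GeneEmbeddingTable` aligned to `x`.
#' @param mode `"wa"` or `"aa"`.
#' @param coverage optional feature-alignment coverage fraction, recorded in
#'   the provenance.
#' @return a [cell_embeddings()] object.
#' @export
aggregate_cells <- function(x, ef, mode = c("wa", "aa"),
                            coverage = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(ef, "GeneEmbeddingTable"))
  if (length(x$gene_ids) != length(ef$ids) ||
      !all(.fold(x$gene_ids) == .fold(ef$ids))) {
    stop("gene order mismatch: run align_features() first")
  }
  if (ef$dim < 1) stop("embedding table has zero dimension")
  if (x$layer_tag == "counts") {
    warning("aggregating raw counts; log-normalized input is recommended")
  }
  m <- ncol(x$values)
  if (mode == "aa") {
    w <- x$values / m
    n_zero <- sum(rowSums(x$values) == 0)
  } else {
    totals <- rowSums(x$values)
    zero <- totals == 0
    n_zero <- sum(zero)
    w <- x$values / ifelse(zero, 1, totals)
  }
  vec <- w %*% ef$vectors
  out <- cell_embeddings(x$cell_ids, vec,
                         provenance = list(mode = mode,
                                           gene_table = ef$source_tag,
                                           state_table = NULL,
                                           coverage = coverage))
  attr(out, "n_zero_cells") <- n_zero
  out
}

#' Add cell-state embeddings to cell embeddings
#'
#' Optionally enriches aggregated cell embeddings with the embedding of each
#' cell's state label (elementwise addition). Labels absent from the state
#' table contribute a zero vector; their count is stored in the
#' `n_missing_labels` attribute. Because the two terms can have quite
#' different magnitudes, `normalize_terms = TRUE` L2-normalizes each cell
#' vector and each state vector before adding (off by default: raw addition
#' is the reference behaviour).
#'
#' @param cells a `CellEmbeddings` object.
#' @param labels character vector of per-cell state labels.
#' @param ec a [cell_state_embedding_table()] of matching dimension.
#' @param normalize_terms L2-normalize both terms before adding.
#' @return a `CellEmbeddings` object.
#' @export
add_state_embeddings <- function(cells, labels, ec,
                                 normalize_terms = FALSE) {
  stopifnot(inherits(cells, "CellEmbeddings"),
            inherits(ec, "CellStateEmbeddingTable"))
  if (length(labels) != nrow(cells$vectors)) {
    stop("labels length must equal the number of cells")
  }
  if (ec$dim != ncol(cells$vectors)) {
    stop("dimension mismatch: cells have ", ncol(cells$vectors),
         " dims, state table has ", ec$dim)
  }
  pos <- match(.fold(labels), .fold(ec$labels))
  missing <- is.na(pos)
  base <- cells$vectors
  state <- matrix(0, nrow(base), ncol(base))
  state[!missing, ] <- ec$vectors[pos[!missing], , drop = FALSE]
  if (normalize_terms) {
    l2 <- function(m) {
      nrm <- sqrt(rowSums(m^2))
      m / ifelse(nrm == 0, 1, nrm)
    }
    base <- l2(base)
    state <- l2(state)
  }
  prov <- cells$provenance
  prov$state_table <- ec$source_tag
  out <- cell_embeddings(cells$cell_ids, base + state, provenance = prov)
  attr(out, "n_missing_labels") <- sum(missing)
  out
}

#' k-nearest-neighbour label transfer
#'
#' Zero-shot annotation: each test cell takes the majority label among its
#' `k` nearest training cells; no model is trained. Confidence is the vote
#' fraction. Vote ties are broken by the smallest mean distance among the
#' tied labels' neighbours, then lexicographically, so the output is fully
#' deterministic.
#'
#' @param train a `CellEmbeddings` object (or matrix) of reference cells.
#' @param train_labels labels of the reference cells.
#' @param test a `CellEmbeddings` object (or matrix) of query cells.
#' @param k number of neighbours (default 10).
#' @param metric `"euclidean"` (default; raw embeddings, no
#'   pre-normalization) or `"cosine"`.
#' @return a list with `labels` (character) and `confidence` (numeric in
#'   `[0,1]`) for the test cells.
#' @export
knn_annotate <- function(train, train_labels, test, k = 10,
                         metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  tr <- .as_embedding_matrix(train)
  te <- .as_embedding_matrix(test)
  if (ncol(tr) != ncol(te)) stop("train and test dimensions differ")
  if (length(train_labels) != nrow(tr)) {
    stop("train_labels length must equal the number of training cells")
  }
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(tr)) {
    stop("k = ", k, " exceeds the number of training cells (", nrow(tr), ")")
  }
  train_labels <- as.character(train_labels)
  d <- .dist_matrix(te, tr, metric)
  n_test <- nrow(te)
  labels <- character(n_test)
  confidence <- numeric(n_test)
  for (i in seq_len(n_test)) {
    ord <- order(d[i, ])[seq_len(k)]
    nb_lab <- train_labels[ord]
    nb_dist <- d[i, ord]
    votes <- table(nb_lab)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) mean(nb_dist[nb_lab == l]),
                       numeric(1))
      top <- top[mean_d == min(mean_d)]
      top <- sort(top)[1]
    }
    labels[i] <- top
    confidence[i] <- max(votes) / k
  }
  list(labels = labels, confidence = confidence)
}

#' Zero-shot cell embeddings from counts in one call
#'
#' Convenience pipeline: log-normalize raw counts (skipped for already
#' log-normalized input), align features with the embedding table,
#' aggregate, and optionally add cell-state embeddings.
#'
#' @param x an `ExpressionMatrix` (counts or lognorm).
#' @param table a `GeneEmbeddingTable`.
#' @param mode aggregation mode, `"wa"` or `"aa"`.
#' @param target_sum library-size target for [log_normalize()].
#' @param state_table optional [cell_state_embedding_table()].
#' @param state_labels per-cell state labels, required with `state_table`;
#'   defaults to `x$cell_type`.
#' @return a `CellEmbeddings` object.
#' @export
zero_shot_embeddings <- function(x, table, mode = c("wa", "aa"),
                                 target_sum = 1e4, state_table = NULL,
                                 state_labels = NULL) {
  mode <- match.arg(mode)
  if (x$layer_tag == "counts") x <- log_normalize(x, target_sum)
  al <- align_features(x, table)
  emb <- aggregate_cells(al$x, al$table, mode = mode,
                         coverage = al$coverage)
  if (!is.null(state_table)) {
    if (is.null(state_labels)) state_labels <- x$cell_type
    if (is.null(state_labels)) {
      stop("state_labels required when adding state embeddings")
    }
    emb <- add_state_embeddings(emb, state_labels, state_table)
  }
  emb
}
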