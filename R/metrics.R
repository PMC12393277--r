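#' Clustering agreement scores (NMI, ARI) over a resolution sweep
#'
#' Builds an exact kNN graph on the embeddings, sweeps the community-
#' detection resolution over `resolutions`, and reports the maximum
#' agreement with the known cell-type labels: NMI against Leiden
#' (modularity objective) partitions and ARI against Louvain partitions.
#' Deterministic for a fixed `seed`.
#'
#' @param embeddings a `CellEmbeddings` object or numeric matrix.
#' @param cell_types per-cell type labels (at least 2 distinct).
#' @param graph_k neighbours for the kNN graph (default 15).
#' @param seed RNG seed for community detection.
#' @param resolutions resolution grid (default `seq(0.1, 2, by = 0.1)`).
#' @return list with `nmi`, `ari`, and the resolutions attaining them.
#' @export
cluster_scores <- function(embeddings, cell_types, graph_k = 15, seed = 0,
                           resolutions = seq(0.1, 2, by = 0.1)) {
  x <- .as_embedding_matrix(embeddings)
  if (length(unique(cell_types)) < 2) {
    stop("cluster_scores needs at least 2 cell types")
  }
  truth <- as.integer(factor(cell_types))
  g <- .knn_graph(x, k = min(graph_k, nrow(x) - 1))
  .with_seed(seed, {
    nmi_vals <- ari_vals <- numeric(length(resolutions))
    for (i in seq_along(resolutions)) {
      r <- resolutions[i]
      mem_l <- igraph::membership(
        igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = r, n_iterations = 3))
      nmi_vals[i] <- igraph::compare(truth, mem_l, method = "nmi")
      mem_v <- igraph::membership(igraph::cluster_louvain(g, resolution = r))
      ari_vals[i] <- igraph::compare(truth, mem_v, method = "adjusted.rand")
    }
    list(nmi = max(nmi_vals), ari = max(ari_vals),
         nmi_resolution = resolutions[which.max(nmi_vals)],
         ari_resolution = resolutions[which.max(ari_vals)])
  })
}

# Mean silhouette width for one labelling; cells belonging to singleton
# labels are dropped first (tallied via attribute).
.asw_raw <- function(d, labels) {
  labels <- as.character(labels)
  counts <- table(labels)
  singletons <- names(counts)[counts < 2]
  keep <- !(labels %in% singletons)
  if (length(unique(labels[keep])) < 2) {
    stop("silhouette needs at least 2 labels with >= 2 members")
  }
  dm <- as.matrix(d)[keep, keep]
  sil <- cluster::silhouette(as.integer(factor(labels[keep])),
                             dmatrix = dm)
  structure(mean(sil[, "sil_width"]), n_excluded_labels = length(singletons))
}

#' Normalized average silhouette widths
#'
#' `asw_label = (raw + 1) / 2` rewards tight, separated cell-type clusters;
#' `asw_batch = 1 - (raw_batch + 1) / 2` inverts the batch silhouette so
#' that well-mixed batches (raw near 0) score near 0.5 and fully separated
#' batches score near 0. Labels with a single member are excluded and
#' tallied.
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param cell_types per-cell type labels, or `NULL` to skip `asw_label`.
#' @param batches per-cell batch labels, or `NULL` to skip `asw_batch`.
#' @return list with `asw_label` and/or `asw_batch` (absent components are
#'   `NULL`), each carrying an `n_excluded_labels` attribute.
#' @export
asw_scores <- function(embeddings, cell_types = NULL, batches = NULL) {
  x <- .as_embedding_matrix(embeddings)
  d <- stats::dist(x)
  out <- list(asw_label = NULL, asw_batch = NULL)
  if (!is.null(cell_types)) {
    raw <- .asw_raw(d, cell_types)
    out$asw_label <- structure((as.numeric(raw) + 1) / 2,
                               n_excluded_labels =
                                 attr(raw, "n_excluded_labels"))
  }
  if (!is.null(batches)) {
    raw <- .asw_raw(d, batches)
    out$asw_batch <- structure(1 - (as.numeric(raw) + 1) / 2,
                               n_excluded_labels =
                                 attr(raw, "n_excluded_labels"))
  }
  out
}

# Mean inverse Simpson index of label proportions over each cell's
# graph_k nearest neighbours.
.lisi_raw <- function(idx, labels) {
  labels <- as.character(labels)
  mean(apply(idx, 1, function(nb) {
    p <- table(labels[nb]) / length(nb)
    1 / sum(p^2)
  }))
}

#' Local inverse Simpson's index scores
#'
#' Per cell, the inverse Simpson index of label proportions over its
#' `graph_k` nearest neighbours, averaged over cells and normalized to
#' `[0,1]`: `ilisi = (raw - 1) / (B - 1)` rewards batch mixing (1 = every
#' neighbourhood a uniform mix of all `B` batches, 0 = pure neighbourhoods)
#' and `clisi = 1 - (raw - 1) / (C - 1)` rewards cell-type purity.
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param batches per-cell batch labels (`NULL` or fewer than 2 levels
#'   leaves `ilisi` absent).
#' @param cell_types per-cell type labels (same rule for `clisi`).
#' @param graph_k neighbourhood size (default 15).
#' @return list with `ilisi` and/or `clisi`; absent components are `NULL`.
#' @export
lisi_scores <- function(embeddings, batches = NULL, cell_types = NULL,
                        graph_k = 15) {
  x <- .as_embedding_matrix(embeddings)
  idx <- .knn_index(x, k = min(graph_k, nrow(x) - 1))
  out <- list(ilisi = NULL, clisi = NULL)
  if (!is.null(batches) && length(unique(batches)) >= 2) {
    b <- length(unique(batches))
    out$ilisi <- (.lisi_raw(idx, batches) - 1) / (b - 1)
  }
  if (!is.null(cell_types) && length(unique(cell_types)) >= 2) {
    cc <- length(unique(cell_types))
    out$clisi <- 1 - (.lisi_raw(idx, cell_types) - 1) / (cc - 1)
  }
  out
}

#' Principal-component regression score
#'
#' Measures how much embedding variance a covariate (typically batch)
#' explains: over the first `n_pcs` principal components, the sum of each
#' component's variance share times the R-squared of regressing it on the
#' covariate. The raw sum (`pcr_raw` attribute, high = strong covariate
#' signal) is returned as `1 - pcr_raw` so that, like every other
#' batch-removal metric here, higher means better mixing.
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param covariate per-cell covariate with at least 2 levels.
#' @param n_pcs number of principal components (default
#'   `min(50, n - 1, t)`).
#' @return score in `[0,1]` with attribute `pcr_raw`.
#' @export
pcr_score <- function(embeddings, covariate, n_pcs = NULL) {
  x <- .as_embedding_matrix(embeddings)
  if (length(unique(covariate)) < 2) {
    stop("covariate is constant; PCR undefined")
  }
  if (length(covariate) != nrow(x)) {
    stop("covariate length must equal the number of cells")
  }
  g <- min(if (is.null(n_pcs)) 50 else n_pcs, nrow(x) - 1, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev[seq_len(g)]^2
  cov_f <- factor(covariate)
  r2 <- vapply(seq_len(g), function(i) {
    if (vars[i] <= max(vars) * 1e-12) return(0)  # degenerate component
    summary(stats::lm(pc$x[, i] ~ cov_f))$r.squared
  }, numeric(1))
  raw <- sum(vars / sum(vars) * r2)
  structure(1 - raw, pcr_raw = raw)
}

#' Graph connectivity
#'
#' For each cell type, the fraction of its cells lying in the largest
#' connected component of the kNN subgraph restricted to that type,
#' averaged over types. A well-integrated embedding keeps each cell type
#' connected across batches (score near 1); types split into distant
#' islands score lower. Singleton types contribute 1.
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param cell_types per-cell type labels.
#' @param graph_k neighbours per cell within each type subgraph (default
#'   15, clamped per type).
#' @return score in `[0,1]`.
#' @export
graph_connectivity <- function(embeddings, cell_types, graph_k = 15) {
  x <- .as_embedding_matrix(embeddings)
  types <- unique(cell_types)
  frac <- vapply(types, function(tp) {
    ix <- which(cell_types == tp)
    if (length(ix) < 2) return(1)
    g <- .knn_graph(x[ix, , drop = FALSE],
                    k = min(graph_k, length(ix) - 1))
    comp <- igraph::components(g)
    max(comp$csize) / length(ix)
  }, numeric(1))
  mean(frac)
}

#' kBET-style batch mixing score
#'
#' Per cell, a Pearson chi-square goodness-of-fit test of the batch
#' composition of its `graph_k` nearest neighbours against the global batch
#' frequencies; the score is the fraction of cells whose local composition
#' is *not* rejected at level `alpha`. 1 means every neighbourhood looks
#' like the global mixture.
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param batches per-cell batch labels (at least 2 levels).
#' @param graph_k neighbourhood size (default 15).
#' @param alpha rejection level (default 0.05).
#' @return acceptance rate in `[0,1]`.
#' @export
kbet_score <- function(embeddings, batches, graph_k = 15, alpha = 0.05) {
  x <- .as_embedding_matrix(embeddings)
  batches <- as.character(batches)
  levels <- sort(unique(batches))
  if (length(levels) < 2) stop("kBET needs at least 2 batches")
  k <- min(graph_k, nrow(x) - 1)
  idx <- .knn_index(x, k = k)
  p_global <- as.numeric(table(factor(batches, levels))) / length(batches)
  df <- length(levels) - 1
  pvals <- apply(idx, 1, function(nb) {
    obs <- as.numeric(table(factor(batches[nb], levels)))
    expct <- p_global * k
    stat <- sum((obs - expct)^2 / expct)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  })
  mean(pvals >= alpha)
}

#' Aggregate batch-removal and biology-conservation scores
#'
#' `s_batch` is the arithmetic mean of the batch-removal components
#' (`asw_batch`, `pcr`, `gc`, `kbet`, `ilisi`); `s_bio` of the
#' biology-conservation components (`asw_label`, `nmi`, `ari`, `clisi`).
#' Absent (`NULL`/`NA`) components are excluded from the mean and listed.
#'
#' @param parts named list of available component scores (any subset of the
#'   nine names above).
#' @return an object of class `MetricReport`: the components plus
#'   `s_batch`, `s_bio`, and `missing`, a list naming excluded components
#'   per aggregate.
#' @export
aggregate_scores <- function(parts) {
  batch_parts <- c("asw_batch", "pcr", "gc", "kbet", "ilisi")
  bio_parts <- c("asw_label", "nmi", "ari", "clisi")
  pick <- function(names) {
    v <- lapply(names, function(nm) parts[[nm]])
    names(v) <- names
    present <- !vapply(v, function(z) is.null(z) || all(is.na(z)),
                       logical(1))
    list(values = vapply(v[present], function(z) as.numeric(z)[1],
                         numeric(1)),
         missing = names[!present])
  }
  b <- pick(batch_parts)
  s <- pick(bio_parts)
  out <- parts[intersect(names(parts), c(batch_parts, bio_parts))]
  out$s_batch <- if (length(b$values)) mean(b$values) else NA_real_
  out$s_bio <- if (length(s$values)) mean(s$values) else NA_real_
  out$missing <- list(batch = b$missing, bio = s$missing)
  structure(out, class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("Integration metric report\n")
  nums <- x[vapply(x, is.numeric, logical(1))]
  for (nm in names(nums)) {
    cat(sprintf("  %-10s %.4f\n", nm, as.numeric(nums[[nm]])[1]))
  }
  if (length(x$missing$batch)) {
    cat("  s_batch excludes:", paste(x$missing$batch, collapse = ", "), "\n")
  }
  if (length(x$missing$bio)) {
    cat("  s_bio excludes:", paste(x$missing$bio, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full metric suite for an embedding
#'
#' Convenience wrapper running every applicable metric (clustering
#' agreement, silhouettes, LISI, PCR, graph connectivity, kBET) for the
#' metadata provided and aggregating with [aggregate_scores()].
#'
#' @param embeddings a `CellEmbeddings` object or matrix.
#' @param cell_types optional per-cell type labels.
#' @param batches optional per-cell batch labels.
#' @param graph_k neighbourhood size shared by the graph-based metrics.
#' @param seed RNG seed for community detection.
#' @return a `MetricReport`.
#' @export
evaluate_embeddings <- function(embeddings, cell_types = NULL,
                                batches = NULL, graph_k = 15, seed = 0) {
  parts <- list()
  if (!is.null(cell_types) && length(unique(cell_types)) >= 2) {
    cl <- cluster_scores(embeddings, cell_types, graph_k = graph_k,
                         seed = seed)
    parts$nmi <- cl$nmi
    parts$ari <- cl$ari
    parts$gc <- graph_connectivity(embeddings, cell_types,
                                   graph_k = graph_k)
  }
  asw <- asw_scores(embeddings, cell_types = cell_types, batches = batches)
  parts$asw_label <- asw$asw_label
  parts$asw_batch <- asw$asw_batch
  lisi <- lisi_scores(embeddings, batches = batches,
                      cell_types = cell_types, graph_k = graph_k)
  parts$ilisi <- lisi$ilisi
  parts$clisi <- lisi$clisi
  if (!is.null(batches) && length(unique(batches)) >= 2) {
    parts$pcr <- as.numeric(pcr_score(embeddings, batches))
    parts$kbet <- kbet_score(embeddings, batches, graph_k = graph_k)
  }
  aggregate_scores(parts)
}

#' Annotation quality metrics
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the truth
#' classes. Classes never predicted contribute precision 0 (and classes
#' absent from the truth are ignored).
#'
#' @param pred predicted labels.
#' @param truth ground-truth labels of the same length.
#' @param averaging `"macro"` (default) or `"weighted"` (by truth class
#'   frequency).
#' @return an object of class `AnnotationReport`: `accuracy`, `precision`,
#'   `recall`, `f1`, `averaging`, and a `per_class` data frame.
#' @export
annotation_metrics <- function(pred, truth,
                               averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length")
  }
  classes <- sort(unique(truth))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = cl, n = tp + fn, precision = precision,
               recall = recall, f1 = f1, stringsAsFactors = FALSE)
  }))
  w <- if (averaging == "macro") rep(1, nrow(per)) else per$n
  w <- w / sum(w)
  structure(list(accuracy = mean(pred == truth),
                 precision = sum(w * per$precision),
                 recall = sum(w * per$recall),
                 f1 = sum(w * per$f1),
                 averaging = averaging, per_class = per),
            class = "AnnotationReport")
}

#' @export
print.AnnotationReport <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$averaging))
  invisible(x)
}

#' Regression quality metrics
#'
#' For observed values `y` and predictions `f` (vectors, or matrices with
#' one column per gene): the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot` (averaged over genes for matrices; negative
#' values are not clamped), the Pearson correlation averaged over genes,
#' and the pooled mean squared error. Genes with a constant observed or
#' predicted vector are skipped for PCC and R2 and tallied.
#'
#' @param y observed values.
#' @param f predicted values, same shape.
#' @return an object of class `RegressionReport`: `r2`, `pcc`, `mse`, and
#'   `n_skipped`.
#' @export
regression_metrics <- function(y, f) {
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (is.vector(f)) f <- matrix(f, ncol = 1)
  if (!all(dim(y) == dim(f))) stop("y and f must have identical shape")
  m <- ncol(y)
  r2s <- pccs <- rep(NA_real_, m)
  skipped <- 0L
  for (j in seq_len(m)) {
    yy <- y[, j]
    ff <- f[, j]
    ss_tot <- sum((yy - mean(yy))^2)
    if (ss_tot > 0) r2s[j] <- 1 - sum((yy - ff)^2) / ss_tot
    if (stats::sd(yy) > 0 && stats::sd(ff) > 0) {
      pccs[j] <- stats::cor(yy, ff)
    } else {
      skipped <- skipped + 1L
    }
  }
  structure(list(r2 = mean(r2s, na.rm = TRUE),
                 pcc = mean(pccs, na.rm = TRUE),
                 mse = mean((y - f)^2),
                 n_skipped = skipped),
            class = "RegressionReport")
}

#' @export
print.RegressionReport <- function(x, ...) {
  cat(sprintf("r2 %.4f | pcc %.4f | mse %.6g (%d gene(s) skipped)\n",
              x$r2, x$pcc, x$mse, x$n_skipped))
  invisible(x)
}
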