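#' Rank differentially expressed genes between two conditions
#'
#' Candidate pool for the deletion screen: per gene, a two-sample Wilcoxon
#' rank-sum comparison of disease versus control cells. Genes are ranked by
#' ascending p-value, ties broken by descending absolute mean difference.
#' Benjamini-Hochberg adjusted p-values are reported alongside but the
#' ranking uses the raw p-values.
#'
#' @param x an `ExpressionMatrix`.
#' @param disease_label,control_label condition labels to compare; each must
#'   be present with at least 2 cells.
#' @param condition per-cell condition labels; defaults to `x$condition`.
#' @param top_k number of top-ranked genes to return (default 10; clamped to
#'   the number of genes with a warning).
#' @return a data frame with columns `gene_id`, `p_value`, `p_adjusted`,
#'   `mean_diff` (disease minus control), restricted to the `top_k`
#'   top-ranked genes in rank order; attribute `n_genes_tested` carries the
#'   total number of genes tested.
#' @export
rank_degs <- function(x, disease_label, control_label,
                      condition = NULL, top_k = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(condition)) condition <- x$condition
  if (is.null(condition)) stop("no condition labels available")
  if (length(condition) != nrow(x$values)) {
    stop("condition length must equal the number of cells")
  }
  dz <- condition == disease_label
  ct <- condition == control_label
  if (sum(dz) < 2) stop("condition label '", disease_label,
                        "' has fewer than 2 cells")
  if (sum(ct) < 2) stop("condition label '", control_label,
                        "' has fewer than 2 cells")
  m <- ncol(x$values)
  pvals <- numeric(m)
  diffs <- numeric(m)
  for (j in seq_len(m)) {
    a <- x$values[dz, j]
    b <- x$values[ct, j]
    diffs[j] <- mean(a) - mean(b)
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
      pvals[j] <- 1  # identical constant on both sides
    } else {
      pvals[j] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
  }
  padj <- stats::p.adjust(pvals, method = "BH")
  ord <- order(pvals, -abs(diffs))
  if (top_k > m) {
    warning("top_k = ", top_k, " exceeds the ", m,
            " genes available; returning all genes")
    top_k <- m
  }
  sel <- ord[seq_len(top_k)]
  out <- data.frame(gene_id = x$gene_ids[sel], p_value = pvals[sel],
                    p_adjusted = padj[sel], mean_diff = diffs[sel],
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_tested") <- m
  out
}

# Mean latent vector of a group of cells: aggregate expression rows into
# zero-shot embeddings, push through the frozen adaptor, average.
.group_latent_mean <- function(model, values, gene_ids, cell_ids, ef, mode,
                               layer_tag) {
  xm <- expression_matrix(values, gene_ids, cell_ids, layer_tag = layer_tag)
  emb <- suppressWarnings(aggregate_cells(xm, ef, mode = mode))
  latent <- predict(model, emb, type = "latent")
  colMeans(latent)
}

#' Deletion score of a single gene
#'
#' Computes the cosine similarity between the mean latent embedding of
#' disease cells and that of control cells before (`cs_old`) and after
#' (`cs_new`) in-silico deletion of one gene: the gene's expression is set
#' to zero in the disease cells only, the cell embeddings are re-aggregated
#' and re-embedded through the frozen model, and the control side is left
#' untouched. A positive difference `cs_new - cs_old` means deleting the
#' gene moves diseased cells toward the control state.
#'
#' If a group's mean latent vector is exactly zero, its cosine similarity is
#' defined as 0 and flagged via the `zero_mean_latent` attribute.
#'
#' @param model a fitted [scelmo_adaptor()] trained on this embedding space.
#' @param x an `ExpressionMatrix`, feature-aligned with `ef`.
#' @param ef the aligned `GeneEmbeddingTable`.
#' @param gene gene identifier to delete (case-insensitive).
#' @param disease_label,control_label condition labels.
#' @param mode aggregation mode, `"wa"` or `"aa"`.
#' @param condition per-cell condition labels; defaults to `x$condition`.
#' @param cs_method `"mean"` compares the two group mean vectors;
#'   `"per_cell"` averages, over disease cells, the cosine of each cell's
#'   latent vector against the control mean.
#' @return named numeric vector `c(cs_old =, cs_new =)`.
#' @export
deletion_score <- function(model, x, ef, gene, disease_label,
                           control_label, mode = c("wa", "aa"),
                           condition = NULL,
                           cs_method = c("mean", "per_cell")) {
  mode <- match.arg(mode)
  cs_method <- match.arg(cs_method)
  stopifnot(inherits(model, "scelmo_adaptor"),
            inherits(x, "ExpressionMatrix"),
            inherits(ef, "GeneEmbeddingTable"))
  if (is.null(condition)) condition <- x$condition
  if (is.null(condition)) stop("no condition labels available")
  gi <- match(.fold(gene), .fold(x$gene_ids))
  if (is.na(gi)) stop("gene '", gene, "' not present in the matrix")
  dz <- which(condition == disease_label)
  ct <- which(condition == control_label)
  if (length(dz) == 0) stop("no cells with label '", disease_label, "'")
  if (length(ct) == 0) stop("no cells with label '", control_label, "'")

  ctrl_latent <- .control_latent(model, x, ef, mode, ct)
  dis_vals <- x$values[dz, , drop = FALSE]
  old <- .disease_cs(model, dis_vals, x, ef, mode, dz, ctrl_latent,
                     cs_method)
  dis_vals[, gi] <- 0
  new <- .disease_cs(model, dis_vals, x, ef, mode, dz, ctrl_latent,
                     cs_method)
  out <- c(cs_old = old$cs, cs_new = new$cs)
  attr(out, "zero_mean_latent") <- old$zero || new$zero
  out
}

.control_latent <- function(model, x, ef, mode, ct) {
  xm <- expression_matrix(x$values[ct, , drop = FALSE], x$gene_ids,
                          x$cell_ids[ct], layer_tag = x$layer_tag)
  emb <- suppressWarnings(aggregate_cells(xm, ef, mode = mode))
  predict(model, emb, type = "latent")
}

.disease_cs <- function(model, dis_vals, x, ef, mode, dz, ctrl_latent,
                        cs_method) {
  xm <- expression_matrix(dis_vals, x$gene_ids, x$cell_ids[dz],
                          layer_tag = x$layer_tag)
  emb <- suppressWarnings(aggregate_cells(xm, ef, mode = mode))
  latent <- predict(model, emb, type = "latent")
  ctrl_mean <- colMeans(ctrl_latent)
  if (cs_method == "mean") {
    cs <- .cosine(colMeans(latent), ctrl_mean)
  } else {
    per <- apply(latent, 1, .cosine, b = ctrl_mean)
    cs <- mean(ifelse(is.na(per), 0, per))
  }
  zero <- is.na(cs)
  list(cs = if (zero) 0 else cs, zero = zero)
}

#' In-silico deletion screen over top differentially expressed genes
#'
#' The full therapeutic-target screen: rank genes by differential expression
#' between disease and control cells ([rank_degs()], candidate set fixed
#' once on the unmodified matrix), then score each candidate by
#' [deletion_score()]. Genes whose deletion shifts the diseased mean
#' embedding toward the control state by more than `threshold` are flagged
#' as therapeutic-target candidates. Control-cell expression is never
#' modified.
#'
#' @inheritParams deletion_score
#' @param top_k number of top DEGs to screen (default 10).
#' @param threshold candidate threshold on the score (default `1e-4`).
#' @return a `DeletionScreenReport`: a data frame with columns `gene_id`,
#'   `cs_old`, `cs_new`, `score` (`cs_new - cs_old`), `candidate`, sorted by
#'   descending score, with attributes `threshold`, `disease_label`,
#'   `control_label`, `n_candidates_tested` and `deg_table`.
#' @export
screen_targets <- function(model, x, ef, disease_label, control_label,
                           mode = c("wa", "aa"), top_k = 10,
                           threshold = 1e-4, condition = NULL,
                           cs_method = c("mean", "per_cell")) {
  mode <- match.arg(mode)
  cs_method <- match.arg(cs_method)
  if (is.null(condition)) condition <- x$condition
  degs <- rank_degs(x, disease_label, control_label,
                    condition = condition, top_k = top_k)
  dz <- which(condition == disease_label)
  ct <- which(condition == control_label)
  ctrl_latent <- .control_latent(model, x, ef, mode, ct)
  base_vals <- x$values[dz, , drop = FALSE]
  old <- .disease_cs(model, base_vals, x, ef, mode, dz, ctrl_latent,
                     cs_method)
  rows <- lapply(degs$gene_id, function(g) {
    gi <- match(.fold(g), .fold(x$gene_ids))
    vals <- base_vals
    vals[, gi] <- 0
    new <- .disease_cs(model, vals, x, ef, mode, dz, ctrl_latent,
                       cs_method)
    data.frame(gene_id = g, cs_old = old$cs, cs_new = new$cs,
               score = new$cs - old$cs, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$candidate <- rep$score > threshold
  rep <- rep[order(-rep$score), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "threshold") <- threshold
  attr(rep, "disease_label") <- disease_label
  attr(rep, "control_label") <- control_label
  attr(rep, "n_candidates_tested") <- nrow(rep)
  attr(rep, "deg_table") <- degs
  class(rep) <- c("DeletionScreenReport", "data.frame")
  rep
}

#' @export
print.DeletionScreenReport <- function(x, ...) {
  cat(sprintf("Deletion screen: %s vs %s; %d candidate gene(s) above %g\n",
              attr(x, "disease_label"), attr(x, "control_label"),
              sum(x$candidate), attr(x, "threshold")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a deletion screen report
#'
#' TSV of the per-gene scores plus a JSON summary (labels, threshold,
#' number of candidates).
#'
#' @param report a `DeletionScreenReport`.
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "DeletionScreenReport"))
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(disease_label = attr(report, "disease_label"),
           control_label = attr(report, "control_label"),
           threshold = attr(report, "threshold"),
           n_candidates_tested = attr(report, "n_candidates_tested"),
           n_candidates_flagged = sum(report$candidate),
           top_gene = report$gene_id[1]),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
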