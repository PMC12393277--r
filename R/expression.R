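#' Construct a validated expression matrix
#'
#' The shared substrate for every other step: a cells-by-genes matrix of
#' finite non-negative values together with per-cell metadata. Values may be
#' raw counts (`layer_tag = "counts"`) or the log1p of library-size scaled
#' counts (`layer_tag = "lognorm"`).
#'
#' @param values numeric matrix (or Matrix sparse matrix), cells in rows,
#'   genes in columns. Coerced to a dense base matrix internally.
#' @param gene_ids character vector of gene identifiers, unique after
#'   case-folding.
#' @param cell_ids character vector of unique cell identifiers.
#' @param cell_type,batch,condition optional per-cell categorical metadata,
#'   each of length `n_cells`.
#' @param layer_tag `"counts"` or `"lognorm"`. If `NULL`, inferred:
#'   integer-valued matrices are tagged `"counts"`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_type`, `batch`, `condition`,
#'   `layer_tag`.
#' @examples
#' x <- expression_matrix(matrix(0:5, 3, 2), c("g1", "g2"),
#'                        c("c1", "c2", "c3"))
#' x$layer_tag
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              cell_type = NULL, batch = NULL,
                              condition = NULL, layer_tag = NULL) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  .stopifnot_finite(values, "expression matrix")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at (row %d, col %d)",
                 neg[1, 1], neg[1, 2]))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (any(!nzchar(gene_ids)) || any(!nzchar(cell_ids))) {
    stop("identifiers must be non-empty strings")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("gene axis mismatch: ", length(gene_ids), " gene ids for ",
         ncol(values), " matrix columns")
  }
  if (length(cell_ids) != nrow(values)) {
    stop("cell axis mismatch: ", length(cell_ids), " cell ids for ",
         nrow(values), " matrix rows")
  }
  dup <- duplicated(.fold(gene_ids))
  if (any(dup)) {
    stop("duplicate gene ids after case-folding: ",
         paste(unique(gene_ids[dup]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  for (nm in c("cell_type", "batch", "condition")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != nrow(values)) {
      stop(nm, " metadata has length ", length(v), ", expected ",
           nrow(values))
    }
  }
  if (is.null(layer_tag)) {
    layer_tag <- if (all(values == floor(values))) "counts" else "lognorm"
  }
  layer_tag <- match.arg(layer_tag, c("counts", "lognorm"))
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_type = if (is.null(cell_type)) NULL else as.character(cell_type),
         batch = if (is.null(batch)) NULL else as.character(batch),
         condition = if (is.null(condition)) NULL else as.character(condition),
         layer_tag = layer_tag),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$layer_tag))
  meta <- c(cell_type = !is.null(x$cell_type), batch = !is.null(x$batch),
            condition = !is.null(x$condition))
  cat("metadata:", if (any(meta)) paste(names(meta)[meta], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

.read_id_table <- function(path, id_col) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- id_col %in% fields
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  if (!has_header) names(tab)[1] <- id_col
  tab
}

#' Load an expression matrix from delimited files
#'
#' Reads either a matrix-market (`.mtx`) sparse triplet file or a dense
#' tab-separated numeric table, plus a gene table and a cell table. The gene
#' table's first column (header `gene_id`, header optional) holds gene
#' identifiers; the cell table holds `cell_id` and optionally `cell_type`,
#' `batch`, `condition` columns. A matrix-market file may be stored either
#' cells-by-genes or genes-by-cells; the orientation is resolved against the
#' lengths of the two id tables.
#'
#' @param matrix_source path to the matrix file.
#' @param genes_source path to the gene table.
#' @param cells_source path to the cell table.
#' @param layer_tag optional explicit layer tag; inferred when `NULL`.
#' @return an [expression_matrix()] object, row/column order preserved from
#'   the source files.
#' @export
load_expression <- function(matrix_source, genes_source, cells_source,
                            layer_tag = NULL) {
  genes <- .read_id_table(genes_source, "gene_id")
  cells <- .read_id_table(cells_source, "cell_id")
  gene_ids <- genes$gene_id
  cell_ids <- cells$cell_id
  first <- readLines(matrix_source, n = 1)
  if (startsWith(first, "%%MatrixMarket")) {
    m <- as.matrix(Matrix::readMM(matrix_source))
    if (nrow(m) == length(cell_ids) && ncol(m) == length(gene_ids)) {
      # stored cells x genes
    } else if (nrow(m) == length(gene_ids) && ncol(m) == length(cell_ids)) {
      m <- t(m)
    } else {
      stop(sprintf(paste0("matrix dimensions %dx%d match neither the cell ",
                          "axis (%d) nor the gene axis (%d)"),
                   nrow(m), ncol(m), length(cell_ids), length(gene_ids)))
    }
  } else {
    m <- as.matrix(utils::read.table(matrix_source, sep = "\t",
                                     header = FALSE, quote = "",
                                     comment.char = ""))
    dimnames(m) <- NULL
    if (nrow(m) != length(cell_ids)) {
      stop("cell axis mismatch: dense matrix has ", nrow(m),
           " rows but the cell table lists ", length(cell_ids), " cells")
    }
    if (ncol(m) != length(gene_ids)) {
      stop("gene axis mismatch: dense matrix has ", ncol(m),
           " columns but the gene table lists ", length(gene_ids), " genes")
    }
  }
  expression_matrix(m, gene_ids, cell_ids,
                    cell_type = cells$cell_type, batch = cells$batch,
                    condition = cells$condition, layer_tag = layer_tag)
}

#' Write an expression matrix to delimited files
#'
#' Inverse of [load_expression()]. Writes `matrix.mtx` (sparse) or
#' `matrix.tsv` (dense, full 17-digit precision), `genes.tsv` and
#' `cells.tsv` under `dir`.
#'
#' @param x an `ExpressionMatrix`.
#' @param dir output directory, created if missing.
#' @param format `"mtx"` (cells-by-genes triplets) or `"dense"`.
#' @return invisibly, the paths written (named character vector).
#' @export
write_expression <- function(x, dir, format = c("mtx", "dense")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "mtx") {
    mpath <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                "generalMatrix"), mpath)
  } else {
    mpath <- file.path(dir, "matrix.tsv")
    txt <- apply(x$values, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    })
    writeLines(txt, mpath)
  }
  gpath <- file.path(dir, "genes.tsv")
  writeLines(c("gene_id", x$gene_ids), gpath)
  cpath <- file.path(dir, "cells.tsv")
  meta <- data.frame(cell_id = x$cell_ids, stringsAsFactors = FALSE)
  if (!is.null(x$cell_type)) meta$cell_type <- x$cell_type
  if (!is.null(x$batch)) meta$batch <- x$batch
  if (!is.null(x$condition)) meta$condition <- x$condition
  utils::write.table(meta, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mpath, genes = gpath, cells = cpath))
}

#' Library-size normalize and log-transform counts
#'
#' Scales every cell so its total equals `target_sum`, then applies
#' `log1p`, the usual scRNA-seq preprocessing convention. Cells whose total
#' count is zero are left all-zero; their number is reported via a warning
#' and recorded in the `n_zero_cells` attribute.
#'
#' @param x an `ExpressionMatrix` with `layer_tag = "counts"`.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return an `ExpressionMatrix` with `layer_tag = "lognorm"`.
#' @export
log_normalize <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer_tag != "counts") {
    stop("log_normalize expects counts; input is already log-normalized")
  }
  if (!is.numeric(target_sum) || target_sum <= 0) {
    stop("target_sum must be a positive real")
  }
  totals <- rowSums(x$values)
  zero <- totals == 0
  scale <- ifelse(zero, 0, target_sum / totals)
  vals <- log1p(x$values * scale)
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts left all-zero")
  }
  out <- expression_matrix(vals, x$gene_ids, x$cell_ids,
                           cell_type = x$cell_type, batch = x$batch,
                           condition = x$condition, layer_tag = "lognorm")
  attr(out, "n_zero_cells") <- sum(zero)
  out
}

#' Restrict an expression matrix and an embedding table to shared genes
#'
#' Genes are matched case-insensitively; genes present on only one side are
#' dropped (not zero-filled), because padding the embedding matrix with
#' zeros would silently distort the expression-weighted averages downstream.
#' The output keeps the gene order of `x`.
#'
#' @param x an `ExpressionMatrix`.
#' @param table a [gene_embedding_table()].
#' @return a list with elements `x`, `table` (both restricted to the
#'   intersection, identical order) and `coverage`, the fraction of `x`'s
#'   genes that were matched.
#' @export
align_features <- function(x, table) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(table, "GeneEmbeddingTable"))
  pos <- match(.fold(x$gene_ids), .fold(table$ids))
  keep <- which(!is.na(pos))
  if (length(keep) == 0) {
    stop("no genes shared between the expression matrix and the embedding table")
  }
  coverage <- length(keep) / length(x$gene_ids)
  x2 <- expression_matrix(x$values[, keep, drop = FALSE],
                          x$gene_ids[keep], x$cell_ids,
                          cell_type = x$cell_type, batch = x$batch,
                          condition = x$condition, layer_tag = x$layer_tag)
  t2 <- gene_embedding_table(x$gene_ids[keep],
                             table$vectors[pos[keep], , drop = FALSE],
                             source_tag = table$source_tag)
  list(x = x2, table = t2, coverage = coverage)
}
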