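#' Synthetic dataset configuration
#'
#' Parameters of the planted-structure generator. Genes are partitioned
#' into co-expression modules; each cell type activates its own module
#' (log-scale mean shift `module_effect`); batches add per-gene shifts of
#' scale `batch_effect`; counts are Poisson-lognormal around the resulting
#' mean with lognormal noise `noise_sd`. When `n_driver_genes > 0`, one
#' cell type is split into matched disease and control halves and the
#' driver genes gain `driver_effect` on the log scale in the disease cells
#' only. Informative gene embeddings are module centroids (orthonormal
#' directions in `R^t`) plus Gaussian jitter `embedding_noise_sd`, so that
#' expression-weighted aggregation has signal to exploit; state embeddings
#' are the exact per-type centroids.
#'
#' @param n_cells,n_genes,n_cell_types,n_batches,n_modules dataset shape;
#'   `n_modules` defaults to `n_cell_types` and must be at least as large.
#' @param t embedding dimension (must satisfy `t >= n_modules`).
#' @param module_effect log-scale mean shift of a cell type's active module
#'   (default 2).
#' @param batch_effect scale (sd) of the additive per-batch, per-gene
#'   log-scale shift (default 0.5).
#' @param noise_sd lognormal noise sd (default 0.3).
#' @param n_driver_genes number of planted disease driver genes (default
#'   0).
#' @param driver_effect log-scale elevation of driver genes in disease
#'   cells (default 3).
#' @param embedding_noise_sd jitter sd of gene embeddings around their
#'   module centroid (default 0.25).
#' @param seed integer; generation is fully determined by the seed.
#' @return an object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_cells = 500, n_genes = 200,
                             n_cell_types = 4, n_batches = 2,
                             n_modules = n_cell_types, t = 32,
                             module_effect = 2, batch_effect = 0.5,
                             noise_sd = 0.3, n_driver_genes = 0,
                             driver_effect = 3, embedding_noise_sd = 0.25,
                             seed = 1) {
  stopifnot(n_cells >= 2, n_genes >= 2, n_cell_types >= 1, n_batches >= 1,
            t >= 1, module_effect > 0, batch_effect >= 0, noise_sd > 0,
            n_driver_genes >= 0, driver_effect > 0,
            embedding_noise_sd > 0)
  if (n_modules < 1) stop("infeasible config: n_modules must be >= 1")
  if (n_modules < n_cell_types) {
    stop("infeasible config: need n_modules >= n_cell_types so every ",
         "cell type can activate a distinct module")
  }
  if (t < n_modules) {
    stop("infeasible config: need t >= n_modules for orthonormal module ",
         "centroids")
  }
  if (n_modules > n_genes) stop("infeasible config: more modules than genes")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 n_batches = as.integer(n_batches),
                 n_modules = as.integer(n_modules), t = as.integer(t),
                 module_effect = module_effect,
                 batch_effect = batch_effect, noise_sd = noise_sd,
                 n_driver_genes = as.integer(n_driver_genes),
                 driver_effect = driver_effect,
                 embedding_noise_sd = embedding_noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Preset synthetic configurations
#'
#' Ready-made study conditions for the four standard scenarios:
#' `"clustering"` (single batch, 4 well-separated types),
#' `"batch"` (3 types across 3 batches with strong batch shifts),
#' `"annotation"` (1,000 cells, 5 types, 200 genes, t = 64, 2 batches),
#' and `"treatment"` (2 types, one planted driver gene with matched
#' disease/control halves within one type).
#'
#' @param preset one of `"clustering"`, `"batch"`, `"annotation"`,
#'   `"treatment"`.
#' @param seed integer seed.
#' @param ... overrides forwarded to [synthetic_config()].
#' @return a `SyntheticConfig`.
#' @export
preset_config <- function(preset = c("clustering", "batch", "annotation",
                                     "treatment"), seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clustering = list(n_cells = 600, n_genes = 150, n_cell_types = 4,
                      n_batches = 1, t = 32),
    batch = list(n_cells = 600, n_genes = 150, n_cell_types = 3,
                 n_batches = 3, t = 32, batch_effect = 1),
    annotation = list(n_cells = 1000, n_genes = 200, n_cell_types = 5,
                      n_batches = 2, t = 64),
    treatment = list(n_cells = 500, n_genes = 120, n_cell_types = 2,
                     n_batches = 1, t = 32, n_driver_genes = 1))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(synthetic_config, args)
}

#' Simulate a single-cell dataset with planted structure
#'
#' Generates counts, metadata, and matched gene/state embedding tables per
#' the model described in [synthetic_config()]. When drivers are planted,
#' cells of the first cell type are split into `"disease"` and `"control"`
#' halves (other cells are labelled `"background"`), drivers are drawn from
#' modules not active in that type so that their expression is near
#' baseline in control cells, and the generated dataset is checked
#' empirically: every driver must have a higher disease than control mean.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `SyntheticDataset`: a list with
#'   `expression` (counts `ExpressionMatrix` with `cell_type`, `batch`,
#'   `condition` metadata), `truth` (list: `gene_module`,
#'   `driver_gene_ids`, `module_of_type`), `informative_embeddings`
#'   (`GeneEmbeddingTable`), `state_embeddings`
#'   (`CellStateEmbeddingTable`), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  .with_seed(cfg$seed, {
    n <- cfg$n_cells
    m <- cfg$n_genes
    gene_ids <- sprintf("gene_%0*d", nchar(m), seq_len(m))
    cell_ids <- sprintf("cell_%0*d", nchar(n), seq_len(n))
    type_names <- sprintf("type_%d", seq_len(cfg$n_cell_types))
    batch_names <- sprintf("batch_%d", seq_len(cfg$n_batches))

    gene_module <- sort(rep(seq_len(cfg$n_modules), length.out = m))
    cell_type <- sample(rep(type_names, length.out = n))
    batch <- sample(rep(batch_names, length.out = n))
    module_of_type <- seq_len(cfg$n_cell_types)

    condition <- rep("background", n)
    driver_ids <- character(0)
    if (cfg$n_driver_genes > 0) {
      t1 <- which(cell_type == type_names[1])
      dz <- sample(t1, floor(length(t1) / 2))
      condition[t1] <- "control"
      condition[dz] <- "disease"
      pool <- if (cfg$n_modules > 1) which(gene_module != module_of_type[1])
              else seq_len(m)
      drivers <- sample(pool, cfg$n_driver_genes)
      driver_ids <- gene_ids[drivers]
    }

    log_mu <- matrix(0, n, m)
    for (j in seq_len(cfg$n_cell_types)) {
      rows <- cell_type == type_names[j]
      cols <- gene_module == module_of_type[j]
      log_mu[rows, cols] <- log_mu[rows, cols] + cfg$module_effect
    }
    batch_shift <- matrix(stats::rnorm(cfg$n_batches * m,
                                       sd = cfg$batch_effect),
                          cfg$n_batches, m)
    log_mu <- log_mu + batch_shift[match(batch, batch_names), ]
    if (cfg$n_driver_genes > 0) {
      log_mu[condition == "disease", drivers] <-
        log_mu[condition == "disease", drivers] + cfg$driver_effect
    }
    log_mu <- log_mu + matrix(stats::rnorm(n * m, sd = cfg$noise_sd), n, m)
    counts <- matrix(stats::rpois(n * m, exp(log_mu)), n, m)

    centroids <- qr.Q(qr(matrix(stats::rnorm(cfg$t * cfg$n_modules),
                                cfg$t, cfg$n_modules)))
    gene_vec <- t(centroids[, gene_module, drop = FALSE]) +
      matrix(stats::rnorm(m * cfg$t, sd = cfg$embedding_noise_sd),
             m, cfg$t)
    state_vec <- t(centroids[, module_of_type, drop = FALSE])

    if (length(driver_ids) > 0) {
      dz_rows <- condition == "disease"
      ct_rows <- condition == "control"
      ratio_ok <- vapply(drivers, function(g) {
        mean(counts[dz_rows, g]) > mean(counts[ct_rows, g])
      }, logical(1))
      if (!all(ratio_ok)) {
        warning("planted driver(s) not elevated in disease cells: ",
                paste(driver_ids[!ratio_ok], collapse = ", "))
      }
    }

    expr <- expression_matrix(counts, gene_ids, cell_ids,
                              cell_type = cell_type, batch = batch,
                              condition = condition, layer_tag = "counts")
    structure(
      list(expression = expr,
           truth = list(gene_module = stats::setNames(gene_module,
                                                      gene_ids),
                        driver_gene_ids = driver_ids,
                        module_of_type = stats::setNames(module_of_type,
                                                         type_names)),
           informative_embeddings =
             gene_embedding_table(gene_ids, gene_vec,
                                  source_tag =
                                    sprintf("synthetic:seed=%d", cfg$seed)),
           state_embeddings =
             cell_state_embedding_table(type_names, state_vec,
                                        source_tag =
                                          sprintf("synthetic:seed=%d",
                                                  cfg$seed)),
           config = cfg),
      class = "SyntheticDataset")
  })
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("SyntheticDataset: %d cells x %d genes, %d types, ",
                     "%d batch(es), t = %d, seed = %d\n"),
              cfg$n_cells, cfg$n_genes, cfg$n_cell_types, cfg$n_batches,
              cfg$t, cfg$seed))
  if (length(x$truth$driver_gene_ids)) {
    cat("planted driver(s):",
        paste(x$truth$driver_gene_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate replicate embeddings of stored vectors
#'
#' Emulates repeated embedding calls for the same feature: each replicate
#' is the stored vector plus Gaussian jitter. Used to exercise
#' [embedding_stability()] without a live provider.
#'
#' @param table a `GeneEmbeddingTable`.
#' @param r replicates per id (at least 2).
#' @param jitter_sd Gaussian jitter sd.
#' @param seed integer seed; output is reproducible.
#' @return named list: id -> `r x t` matrix of replicates.
#' @export
simulate_embedding_replicates <- function(table, r, jitter_sd, seed) {
  stopifnot(inherits(table, "GeneEmbeddingTable"))
  if (r < 2) stop("need r >= 2 replicates")
  .with_seed(seed, {
    out <- lapply(seq_along(table$ids), function(i) {
      base <- matrix(table$vectors[i, ], r, table$dim, byrow = TRUE)
      base + matrix(stats::rnorm(r * table$dim, sd = jitter_sd),
                    r, table$dim)
    })
    stats::setNames(out, table$ids)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Writes the expression matrix (matrix-market + TSV metadata via
#' [write_expression()]), the informative gene embedding table, the state
#' embedding table, and a JSON truth record (module assignments, drivers).
#'
#' @param dataset a `SyntheticDataset`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expression, dir, format = "mtx")
  write_embedding_table(dataset$informative_embeddings,
                        file.path(dir, "gene_embeddings.tsv"))
  write_embedding_table(dataset$state_embeddings,
                        file.path(dir, "state_embeddings.tsv"))
  jsonlite::write_json(
    list(gene_module = as.list(dataset$truth$gene_module),
         driver_gene_ids = dataset$truth$driver_gene_ids,
         module_of_type = as.list(dataset$truth$module_of_type),
         config = unclass(dataset$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
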