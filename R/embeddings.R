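#' Construct a gene embedding table
#'
#' A map from gene identifiers to fixed-length real vectors -- the
#' language-model-derived prior that the whole pipeline consumes. Rows of
#' `vectors` correspond to `ids`.
#'
#' @param ids character vector, unique after case-folding.
#' @param vectors numeric matrix, one row per id, `t` columns.
#' @param source_tag provenance string, e.g. `"file"` or `"random:seed=0"`.
#' @return an object of class `GeneEmbeddingTable` with elements `ids`,
#'   `vectors`, `dim`, `source_tag`.
#' @export
gene_embedding_table <- function(ids, vectors, source_tag = "memory") {
  ids <- as.character(ids)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(ids) != nrow(vectors)) {
    stop("ids and vector rows differ in length")
  }
  if (any(!nzchar(ids))) stop("empty id")
  dup <- duplicated(.fold(ids))
  if (any(dup)) {
    stop("duplicate ids after case-folding: ",
         paste(unique(ids[dup]), collapse = ", "))
  }
  if (ncol(vectors) < 1) stop("embedding dimension must be at least 1")
  .stopifnot_finite(vectors, "embedding table")
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors, dim = ncol(vectors),
                 source_tag = source_tag),
            class = "GeneEmbeddingTable")
}

#' @export
print.GeneEmbeddingTable <- function(x, ...) {
  cat(sprintf("GeneEmbeddingTable: %d ids x %d dims [%s]\n",
              length(x$ids), x$dim, x$source_tag))
  invisible(x)
}

#' Construct a cell-state embedding table
#'
#' Same shape as [gene_embedding_table()] but keyed by cell-type/state
#' labels; added on top of aggregated cell embeddings via
#' [add_state_embeddings()].
#'
#' @param labels character vector of state labels, unique after
#'   case-folding.
#' @param vectors numeric matrix, one row per label.
#' @param source_tag provenance string.
#' @return an object of class `CellStateEmbeddingTable`.
#' @export
cell_state_embedding_table <- function(labels, vectors,
                                       source_tag = "memory") {
  tab <- gene_embedding_table(labels, vectors, source_tag)
  structure(list(labels = tab$ids, vectors = tab$vectors, dim = tab$dim,
                 source_tag = source_tag),
            class = "CellStateEmbeddingTable")
}

#' Load an embedding table from TSV or JSON
#'
#' TSV dialect: one record per line, identifier followed by `t`
#' tab-separated floats, no header. JSON dialect: an object mapping ids to
#' arrays of floats. All records must share one vector length.
#'
#' @param source path; files ending in `.json` are parsed as JSON.
#' @return a `GeneEmbeddingTable` with `source_tag = "file"`.
#' @export
load_embedding_table <- function(source) {
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    lst <- jsonlite::fromJSON(source, simplifyVector = TRUE,
                              simplifyMatrix = FALSE)
    if (!is.list(lst) || is.null(names(lst))) {
      stop("JSON embedding table must be an object of id -> vector")
    }
    lens <- vapply(lst, length, integer(1))
    if (length(unique(lens)) > 1) {
      bad <- names(lst)[which(lens != lens[1])[1]]
      stop("ragged embedding table: id '", bad, "' has length ",
           lens[bad], " but '", names(lst)[1], "' has length ", lens[1])
    }
    vec <- do.call(rbind, lapply(lst, as.numeric))
    tab <- gene_embedding_table(names(lst), vec, source_tag = "file")
    return(tab)
  }
  lines <- readLines(source)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- vapply(parts, length, integer(1))
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    stop("ragged embedding table: id '", parts[[bad]][1], "' has ",
         lens[bad] - 1, " values but '", parts[[1]][1], "' has ",
         lens[1] - 1)
  }
  ids <- vapply(parts, `[`, character(1), 1)
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1))),
                nrow = length(ids), ncol = lens[1] - 1, byrow = TRUE)
  gene_embedding_table(ids, vec, source_tag = "file")
}

#' Write an embedding table to TSV or JSON
#'
#' @param table a `GeneEmbeddingTable` or `CellStateEmbeddingTable`.
#' @param path output path.
#' @param format `"tsv"` (id + floats per line) or `"json"` (id -> array
#'   object).
#' @return invisibly, `path`.
#' @export
write_embedding_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  ids <- if (inherits(table, "CellStateEmbeddingTable")) table$labels
         else table$ids
  if (format == "json") {
    lst <- stats::setNames(lapply(seq_along(ids), function(i) {
      table$vectors[i, ]
    }), ids)
    jsonlite::write_json(lst, path, digits = I(17), auto_unbox = FALSE)
  } else {
    txt <- vapply(seq_along(ids), function(i) {
      paste(c(ids[i], sprintf("%.17g", table$vectors[i, ])),
            collapse = "\t")
    }, character(1))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Generate a random-control embedding table
#'
#' I.i.d. standard-normal entries: the "meaningless embedding" control used
#' to test whether downstream gains depend on the semantic content of the
#' vectors or merely on a random projection of expression.
#'
#' @param ids character vector of identifiers.
#' @param t embedding dimension (positive integer).
#' @param seed integer; the table is bitwise reproducible per
#'   `(ids, t, seed)`.
#' @return a `GeneEmbeddingTable` with `source_tag = "random:seed=<seed>"`.
#' @export
random_embedding_table <- function(ids, t, seed) {
  if (!is.numeric(t) || t < 1) stop("embedding dimension t must be >= 1")
  t <- as.integer(t)
  vec <- .with_seed(seed, matrix(stats::rnorm(length(ids) * t),
                                 nrow = length(ids), ncol = t))
  gene_embedding_table(ids, vec,
                       source_tag = sprintf("random:seed=%d",
                                            as.integer(seed)))
}

#' Define a prompt template
#'
#' A template carries exactly one `{}` placeholder into which the feature or
#' state name is substituted before being sent to a description provider.
#'
#' @param template_text string with a single `{}` placeholder.
#' @param kind `"gene"`, `"protein"` or `"cell_type"`.
#' @return an object of class `PromptTemplate`.
#' @export
prompt_template <- function(template_text,
                            kind = c("gene", "protein", "cell_type")) {
  kind <- match.arg(kind)
  n_ph <- length(gregexpr("{}", template_text, fixed = TRUE)[[1]])
  if (!grepl("{}", template_text, fixed = TRUE) || n_ph != 1) {
    stop("template must contain exactly one {} placeholder")
  }
  structure(list(template_text = template_text, kind = kind),
            class = "PromptTemplate")
}

#' Default prompt templates
#'
#' Editable defaults for the three feature kinds; nothing downstream is tied
#' to this wording.
#'
#' @return named list of [prompt_template()] objects.
#' @export
default_prompt_templates <- function() {
  list(
    gene = prompt_template(
      "Summarize the molecular function and biological role of the gene {}.",
      "gene"),
    protein = prompt_template(
      "Summarize the molecular function and biological role of the protein {}.",
      "protein"),
    cell_type = prompt_template(
      "Describe the characteristic functions and marker genes of the cell type {}.",
      "cell_type"))
}

#' Substitute a feature name into a prompt template
#'
#' @param name non-empty feature or state name.
#' @param template a [prompt_template()].
#' @return the prompt string, deterministic in its inputs.
#' @export
build_prompt <- function(name, template) {
  stopifnot(inherits(template, "PromptTemplate"))
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("name must be a non-empty string")
  }
  sub("{}", name, template$template_text, fixed = TRUE)
}

#' Define an embedding provider
#'
#' The contract standing in for a live language model: `describe` maps a
#' feature name to text, `embed` maps text to a length-`dim` numeric vector.
#' Both are treated as opaque and possibly nondeterministic. Only
#' file-backed ([file_embedding_provider()]) and random providers ship;
#' users may plug in their own callables (e.g. wrapping an HTTP client).
#'
#' @param describe function(name) -> text.
#' @param embed function(text) -> numeric vector of length `dim`.
#' @param dim embedding dimension.
#' @return an object of class `EmbeddingProviderContract`.
#' @export
embedding_provider <- function(describe, embed, dim) {
  stopifnot(is.function(describe), is.function(embed), dim >= 1)
  structure(list(describe = describe, embed = embed, dim = as.integer(dim)),
            class = "EmbeddingProviderContract")
}

#' File-backed embedding provider
#'
#' Looks vectors up in a stored table; `describe` is the identity on the
#' name (no free text is available offline).
#'
#' @param table a `GeneEmbeddingTable`.
#' @return an `EmbeddingProviderContract`.
#' @export
file_embedding_provider <- function(table) {
  stopifnot(inherits(table, "GeneEmbeddingTable"))
  embedding_provider(
    describe = function(name) name,
    embed = function(text) {
      i <- match(.fold(text), .fold(table$ids))
      if (is.na(i)) stop("id '", text, "' not present in the backing table")
      table$vectors[i, ]
    },
    dim = table$dim)
}

#' Build an embedding table through a provider
#'
#' Runs `describe` then `embed` for each name, optionally through a prompt
#' template, and collects the vectors into a table.
#'
#' @param provider an [embedding_provider()].
#' @param names character vector of feature names.
#' @param template optional [prompt_template()] applied to each name before
#'   `describe`.
#' @return a `GeneEmbeddingTable` with `source_tag = "provider"`.
#' @export
embed_names <- function(provider, names, template = NULL) {
  stopifnot(inherits(provider, "EmbeddingProviderContract"))
  vec <- t(vapply(names, function(nm) {
    q <- if (is.null(template)) nm else build_prompt(nm, template)
    v <- provider$embed(provider$describe(q))
    if (length(v) != provider$dim || any(!is.finite(v))) {
      stop("provider returned an invalid vector for '", nm, "'")
    }
    v
  }, numeric(provider$dim)))
  gene_embedding_table(names, vec, source_tag = "provider")
}

#' Replicate-stability statistics for embeddings
#'
#' Quantifies how stable repeated embeddings of the same feature are,
#' against how similar embeddings of different features are: pairwise
#' cosine similarity over all same-id replicate pairs (`within_gene`) and
#' over all pairs of distinct ids' mean replicate vectors (`between_gene`).
#' A well-behaved provider shows within-gene similarity near 1 and clearly
#' lower between-gene similarity. Pairs involving a zero vector are skipped
#' and tallied.
#'
#' @param replicates named list: id -> matrix of `r x t` replicate
#'   embeddings. At least one id must have `r >= 2`.
#' @return an object of class `StabilityReport`: lists `within_gene` and
#'   `between_gene`, each with `mean`, `min`, `max`, `n_pairs`, plus
#'   `n_skipped`.
#' @export
embedding_stability <- function(replicates) {
  if (!is.list(replicates) || is.null(names(replicates))) {
    stop("replicates must be a named list of matrices")
  }
  mats <- lapply(replicates, function(m) {
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    m
  })
  if (!any(vapply(mats, nrow, integer(1)) >= 2)) {
    stop("at least one id needs >= 2 replicates")
  }
  skipped <- 0L
  within <- numeric(0)
  for (m in mats) {
    r <- nrow(m)
    if (r < 2) next
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        cs <- .cosine(m[i, ], m[j, ])
        if (is.na(cs)) skipped <- skipped + 1L else within <- c(within, cs)
      }
    }
  }
  means <- do.call(rbind, lapply(mats, colMeans))
  between <- numeric(0)
  n_ids <- nrow(means)
  if (n_ids >= 2) {
    for (i in seq_len(n_ids - 1)) {
      for (j in seq(i + 1, n_ids)) {
        cs <- .cosine(means[i, ], means[j, ])
        if (is.na(cs)) skipped <- skipped + 1L else between <- c(between, cs)
      }
    }
  }
  summ <- function(v) {
    if (length(v) == 0) {
      list(mean = NA_real_, min = NA_real_, max = NA_real_, n_pairs = 0L)
    } else {
      list(mean = mean(v), min = min(v), max = max(v),
           n_pairs = length(v))
    }
  }
  structure(list(within_gene = summ(within), between_gene = summ(between),
                 n_skipped = skipped),
            class = "StabilityReport")
}

.tokenize <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  if (n == 1) return(tokens)
  apply(stats::embed(seq_along(tokens), n)[, n:1, drop = FALSE], 1,
        function(ix) paste(tokens[ix], collapse = " "))
}

#' Single-order BLEU (modified n-gram precision)
#'
#' Modified n-gram precision at a single order `n`: over the distinct
#' n-grams of the candidate, the clipped match count against the reference
#' divided by the total candidate n-gram count. No brevity penalty and no
#' geometric mean across orders. Tokenization is lowercasing, punctuation
#' stripping, whitespace splitting.
#'
#' @param candidate generated description.
#' @param reference ground-truth description.
#' @param n n-gram order (default 2).
#' @return an object of class `DescriptionEvalReport`: `bleu` in `[0,1]`,
#'   `n`, and `short_candidate` (TRUE when the candidate has fewer than `n`
#'   tokens, in which case `bleu` is defined as 0).
#' @export
bleu_score <- function(candidate, reference, n = 2) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cand <- .ngrams(.tokenize(candidate), n)
  ref <- .ngrams(.tokenize(reference), n)
  if (length(cand) == 0) {
    return(structure(list(bleu = 0, n = n, short_candidate = TRUE),
                     class = "DescriptionEvalReport"))
  }
  c_counts <- table(cand)
  r_counts <- table(ref)
  clipped <- vapply(names(c_counts), function(s) {
    min(c_counts[[s]], if (s %in% names(r_counts)) r_counts[[s]] else 0L)
  }, numeric(1))
  structure(list(bleu = sum(clipped) / sum(c_counts), n = n,
                 short_candidate = FALSE),
            class = "DescriptionEvalReport")
}
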