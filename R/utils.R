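# Internal helpers shared across modules.

# Case-folded identifier matching: all gene/label lookups go through this so
# "Tp53" and "TP53" collide at load time instead of silently diverging later.
.fold <- function(x) tolower(trimws(as.character(x)))

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Cosine similarity; NA when either vector has zero norm so callers can apply
# their documented zero-vector convention explicitly.
.cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Dense pairwise distance matrix (rows of x vs rows of y).
.dist_matrix <- function(x, y = NULL, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.null(y)) y <- x
  if (metric == "euclidean") {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0  # numerical underflow guard
    sqrt(d2)
  } else {
    nx <- sqrt(rowSums(x^2))
    ny <- sqrt(rowSums(y^2))
    nx[nx == 0] <- 1
    ny[ny == 0] <- 1
    1 - tcrossprod(x / nx, y / ny)
  }
}

# Exact k-nearest-neighbour indices into `train` for each row of `query`
# (query = NULL means self-kNN with self excluded). Ties resolve to the
# lower row index, which keeps every downstream graph deterministic.
.knn_index <- function(train, query = NULL, k, metric = "euclidean") {
  self_query <- is.null(query)
  d <- .dist_matrix(if (self_query) train else query, train, metric)
  n_q <- nrow(d)
  if (k > ncol(d) - as.integer(self_query)) {
    stop("k = ", k, " exceeds the number of available neighbours")
  }
  idx <- matrix(0L, n_q, k)
  for (i in seq_len(n_q)) {
    di <- d[i, ]
    if (self_query) di[i] <- Inf
    idx[i, ] <- order(di)[seq_len(k)]
  }
  idx
}

# Undirected simple kNN graph over the rows of x.
.knn_graph <- function(x, k) {
  idx <- .knn_index(x, k = k)
  n <- nrow(x)
  edges <- cbind(rep(seq_len(n), times = k), as.vector(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

# Extract a plain numeric matrix from a CellEmbeddings object or matrix.
.as_embedding_matrix <- function(x) {
  if (inherits(x, "CellEmbeddings")) return(x$vectors)
  if (is.matrix(x)) return(x)
  if (inherits(x, "Matrix")) return(as.matrix(x))
  stop("expected a CellEmbeddings object or a numeric matrix")
}

.stopifnot_finite <- function(m, what) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s contains a non-finite value at (row %d, col %d)",
                 what, bad[1, 1], bad[1, 2]))
  }
  invisible(TRUE)
}
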