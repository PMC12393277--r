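# Naive per-cell, per-gene aggregation oracle used across this file.
aggregate_oracle <- function(vals, emb, mode) {
  n <- nrow(vals)
  m <- ncol(vals)
  out <- matrix(0, n, ncol(emb))
  for (i in seq_len(n)) {
    denom <- if (mode == "aa") m else sum(vals[i, ])
    if (denom == 0) next
    for (j in seq_len(m)) {
      out[i, ] <- out[i, ] + (vals[i, j] / denom) * emb[j, ]
    }
  }
  out
}

test_that("aa and wa weights follow the printed averaging formulas", {
  set.seed(2)
  emb <- matrix(rnorm(9), 3, 3)
  x <- toy_expression(matrix(c(2, 0, 2), 1, 3), layer_tag = "lognorm")
  tab <- toy_table(emb)
  aa <- aggregate_cells(x, tab, mode = "aa")
  expect_equal(unname(aa$vectors[1, ]),
               as.numeric((c(2, 0, 2) / 3) %*% emb))
  wa <- aggregate_cells(x, tab, mode = "wa")
  expect_equal(unname(wa$vectors[1, ]),
               as.numeric(c(0.5, 0, 0.5) %*% emb))

  ident <- toy_table(diag(3))
  x2 <- toy_expression(matrix(c(1, 2, 3), 1, 3), layer_tag = "lognorm")
  expect_equal(unname(aggregate_cells(x2, ident, "wa")$vectors[1, ]),
               c(1, 2, 3) / 6)
})

test_that("aggregation matches the double-loop oracle on random instances", {
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(2:50, 1)
    m <- sample(2:50, 1)
    t <- sample(2:8, 1)
    vals <- matrix(rexp(n * m), n, m) * rbinom(n * m, 1, 0.6)
    x <- toy_expression(vals, layer_tag = "lognorm")
    tab <- toy_table(matrix(rnorm(m * t), m, t))
    for (mode in c("aa", "wa")) {
      got <- aggregate_cells(x, tab, mode = mode)$vectors
      want <- aggregate_oracle(vals, tab$vectors, mode)
      expect_lt(max(abs(got - want)) / max(abs(want), 1e-12), 1e-10)
    }
  }
})

test_that("wa is scale-invariant while aa scales linearly", {
  set.seed(41)
  vals <- matrix(rexp(60), 5, 12)
  x <- toy_expression(vals, layer_tag = "lognorm")
  tab <- toy_table(matrix(rnorm(12 * 6), 12, 6))
  base_wa <- aggregate_cells(x, tab, "wa")$vectors
  base_aa <- aggregate_cells(x, tab, "aa")$vectors
  for (c0 in c(2, 0.5, 8)) {  # powers of two: scaling is float-exact
    scaled <- toy_expression(c0 * vals, layer_tag = "lognorm")
    expect_identical(aggregate_cells(scaled, tab, "wa")$vectors, base_wa)
    expect_equal(aggregate_cells(scaled, tab, "aa")$vectors, c0 * base_aa,
                 tolerance = 1e-12)
  }
  scaled <- toy_expression(pi * vals, layer_tag = "lognorm")
  expect_equal(aggregate_cells(scaled, tab, "wa")$vectors, base_wa,
               tolerance = 1e-12)
})

test_that("aa equals wa exactly when every row sums to the gene count", {
  set.seed(42)
  m <- 8
  # integer rows summing exactly to m keep both denominators float-identical
  vals <- t(rmultinom(4, size = m, prob = rep(1, m)))
  x <- toy_expression(vals, layer_tag = "lognorm")
  tab <- toy_table(matrix(rnorm(m * 3), m, 3))
  expect_identical(aggregate_cells(x, tab, "aa")$vectors,
                   aggregate_cells(x, tab, "wa")$vectors)
})

test_that("zero-expression cells embed to zero and are tallied", {
  x <- toy_expression(rbind(c(0, 0, 0), c(1, 1, 0)), layer_tag = "lognorm")
  tab <- toy_table(matrix(rnorm(9), 3, 3))
  for (mode in c("aa", "wa")) {
    out <- aggregate_cells(x, tab, mode)
    expect_equal(unname(out$vectors[1, ]), c(0, 0, 0))
    expect_identical(attr(out, "n_zero_cells"), 1L)
  }
})

test_that("aggregation guards order, counts input and provenance", {
  x <- toy_expression(matrix(1, 1, 2), layer_tag = "lognorm")
  tab <- toy_table(matrix(1:4, 2, 2), ids = c("g2", "g1"))
  expect_error(aggregate_cells(x, tab), "gene order mismatch")
  counts <- toy_expression(matrix(1:2, 1, 2))
  ok_tab <- toy_table(matrix(1:4, 2, 2))
  expect_warning(aggregate_cells(counts, ok_tab), "counts")
  out <- aggregate_cells(x, ok_tab, "wa", coverage = 0.8)
  expect_identical(out$provenance$mode, "wa")
  expect_equal(out$provenance$coverage, 0.8)
})

test_that("state embeddings add per-label vectors with zero fallback", {
  cells <- cell_embeddings(c("c1", "c2"), rbind(c(1, 1), c(2, 2)))
  ec0 <- cell_state_embedding_table(c("a", "b"), matrix(0, 2, 2))
  expect_equal(add_state_embeddings(cells, c("a", "b"), ec0)$vectors,
               cells$vectors)
  ec <- cell_state_embedding_table("a", matrix(c(2, 3), 1, 2))
  out <- add_state_embeddings(cells, c("a", "zz"), ec)
  expect_equal(unname(out$vectors[1, ]), c(3, 4))
  expect_equal(unname(out$vectors[2, ]), c(2, 2))
  expect_identical(attr(out, "n_missing_labels"), 1L)
  bad <- cell_state_embedding_table("a", matrix(1, 1, 3))
  expect_error(add_state_embeddings(cells, c("a", "a"), bad),
               "dimension mismatch")
})

test_that("kNN transfer votes, reports confidence and breaks ties", {
  set.seed(50)
  tr <- matrix(rnorm(20), 10, 2)
  lab <- rep(c("x", "y"), 5)
  hit <- knn_annotate(tr, lab, tr[3, , drop = FALSE], k = 1)
  expect_identical(hit$labels, lab[3])
  expect_equal(hit$confidence, 1)

  left <- cbind(rnorm(50, -10), rnorm(50))
  right <- cbind(rnorm(50, 10), rnorm(50))
  trn <- rbind(left, right)
  labs <- rep(c("L", "R"), each = 50)
  got <- knn_annotate(trn, labs, matrix(c(9.5, 0), 1, 2), k = 10)
  expect_identical(got$labels, "R")

  # balanced 2-class with k = n_train: global tie; the symmetric geometry
  # also ties mean distance, so the lexicographic rule decides
  sym <- rbind(c(-1, 0), c(1, 0))
  tie <- knn_annotate(sym, c("b", "a"), matrix(0, 1, 2), k = 2)
  expect_identical(tie$labels, "a")
  expect_equal(tie$confidence, 0.5)

  expect_error(knn_annotate(sym, c("b", "a"), matrix(0, 1, 2), k = 3),
               "exceeds")
})

test_that("kNN agrees with an exhaustive-distance oracle", {
  set.seed(51)
  tr <- matrix(rnorm(60), 30, 2)
  labs <- sample(c("p", "q", "r"), 30, replace = TRUE)
  te <- matrix(rnorm(10), 5, 2)
  got <- knn_annotate(tr, labs, te, k = 7)
  for (i in 1:5) {
    d <- sqrt(colSums((t(tr) - te[i, ])^2))
    nb <- labs[order(d)[1:7]]
    votes <- sort(table(nb), decreasing = TRUE)
    if (sum(votes == max(votes)) == 1) {
      expect_identical(got$labels[i], names(votes)[1])
      expect_equal(got$confidence[i], max(votes) / 7)
    }
  }
})

test_that("zero_shot_embeddings composes the full zero-shot path", {
  ds <- simulate_dataset(synthetic_config(n_cells = 60, n_genes = 40,
                                          n_cell_types = 2, n_batches = 1,
                                          t = 8, seed = 4))
  emb <- zero_shot_embeddings(ds$expression, ds$informative_embeddings,
                              mode = "wa",
                              state_table = ds$state_embeddings)
  expect_s3_class(emb, "CellEmbeddings")
  expect_equal(dim(emb$vectors), c(60L, 8L))
  expect_identical(emb$provenance$mode, "wa")
  expect_false(is.null(emb$provenance$state_table))
})
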