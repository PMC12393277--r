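# Points on a circle with a periodic batch pattern: every cell's k nearest
# neighbours are its k/2 flanks on each side, so neighbourhood label
# proportions are known exactly.
circle_cells <- function(n, pattern) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  list(x = cbind(cos(theta), sin(theta)) * 100,
       labels = rep(pattern, length.out = n))
}

two_blobs <- function(n_per = 100, gap = 50, d = 4, sd = 1, seed = 80) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, sd = sd), n_per),
             matrix(rnorm(n_per * d, mean = gap, sd = sd), n_per))
  list(x = x, labels = rep(c("t1", "t2"), each = n_per))
}

test_that("well-separated blobs are recovered perfectly by the sweep", {
  bl <- two_blobs()
  cs <- cluster_scores(bl$x, bl$labels, seed = 1)
  expect_equal(cs$nmi, 1)
  expect_equal(cs$ari, 1)
  expect_error(cluster_scores(bl$x, rep("one", 200)), "at least 2")
})

test_that("cluster scores are deterministic and near zero under null labels", {
  bl <- two_blobs(n_per = 60)
  a <- cluster_scores(bl$x, bl$labels, seed = 5)
  b <- cluster_scores(bl$x, bl$labels, seed = 5)
  expect_identical(a, b)
  set.seed(81)
  perm <- sample(bl$labels)
  cs <- cluster_scores(bl$x, perm, seed = 5)
  expect_lt(abs(cs$ari), 0.1)
})

test_that("ARI route agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(82)
  for (i in 1:20) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(igraph::compare(a, b, method = "adjusted.rand"),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("silhouette scores land on the documented normalizations", {
  bl <- two_blobs(gap = 100, sd = 0.5)
  asw <- asw_scores(bl$x, cell_types = bl$labels)
  expect_gt(as.numeric(asw$asw_label), 0.99)
  # batches alternating inside each tight cluster: raw batch sil ~ 0
  batches <- rep(c("b1", "b2"), 100)
  mixed <- asw_scores(bl$x, batches = batches)
  expect_equal(as.numeric(mixed$asw_batch), 0.5, tolerance = 0.1)
  # batch == cluster: strong separation, asw_batch near 0
  sep <- asw_scores(bl$x, batches = bl$labels)
  expect_lt(as.numeric(sep$asw_batch), 0.05)
  # singleton labels excluded and tallied
  lab3 <- bl$labels
  lab3[1] <- "solo"
  tallied <- asw_scores(bl$x, cell_types = lab3)
  expect_identical(attr(tallied$asw_label, "n_excluded_labels"), 1L)
})

test_that("LISI endpoints and the 3:1 mixture match hand computation", {
  pure <- two_blobs(n_per = 60, gap = 1000)
  l <- lisi_scores(pure$x, batches = pure$labels,
                   cell_types = pure$labels, graph_k = 10)
  expect_equal(l$ilisi, 0)
  expect_equal(l$clisi, 1)

  even <- circle_cells(64, c("A", "B"))
  le <- lisi_scores(even$x, batches = even$labels, graph_k = 16)
  expect_equal(le$ilisi, 1, tolerance = 1e-12)

  three_one <- circle_cells(64, c("A", "A", "A", "B"))
  lt <- lisi_scores(three_one$x, batches = three_one$labels, graph_k = 16)
  expect_equal(lt$ilisi, 1 / (0.75^2 + 0.25^2) - 1, tolerance = 1e-12)

  expect_null(lisi_scores(pure$x, batches = rep("b", 120))$ilisi)
})

test_that("PCR is rotation-invariant and hits both extremes", {
  set.seed(83)
  x <- matrix(rnorm(300), 100, 3)
  cov <- sample(c("a", "b"), 100, replace = TRUE)
  s1 <- pcr_score(x, cov)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  s2 <- pcr_score(x %*% q, cov)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-8)
  expect_gt(as.numeric(s1), 0.9)  # independent covariate: raw near 0

  ind <- cbind(rep(c(0, 10), each = 50), 0)
  # exact-fit warning from lm is expected in this constructed worst case
  worst <- suppressWarnings(pcr_score(ind, rep(c("a", "b"), each = 50)))
  expect_lt(as.numeric(worst), 1e-8)
  expect_equal(attr(worst, "pcr_raw"), 1, tolerance = 1e-8)
  expect_error(pcr_score(x, rep("a", 100)), "constant")
})

test_that("graph connectivity scores islands and singletons as documented", {
  bl <- two_blobs(gap = 100)
  expect_equal(graph_connectivity(bl$x, bl$labels), 1)
  # one type split into two distant equal halves, small k: that type = 0.5
  set.seed(84)
  split_type <- rbind(matrix(rnorm(20), 10, 2),
                      matrix(rnorm(20, mean = 500), 10, 2))
  whole_type <- matrix(rnorm(40, mean = 100), 20, 2)
  x <- rbind(split_type, whole_type)
  types <- rep(c("split", "whole"), each = 20)
  expect_equal(graph_connectivity(x, types, graph_k = 5), (0.5 + 1) / 2)
  # singleton type contributes 1
  x1 <- rbind(x, c(0, 0))
  expect_equal(graph_connectivity(x1, c(types, "solo"), graph_k = 5),
               (0.5 + 1 + 1) / 3)
})

test_that("kBET accepts global-like neighbourhoods and rejects separation", {
  even <- circle_cells(64, c("A", "B"))
  expect_equal(kbet_score(even$x, even$labels, graph_k = 16), 1)
  sep <- two_blobs(gap = 1000)
  expect_lt(kbet_score(sep$x, sep$labels, graph_k = 10), 0.05)
  expect_equal(kbet_score(sep$x, sep$labels, graph_k = 10, alpha = 0), 1)
  expect_error(kbet_score(even$x, rep("A", 64)), "at least 2")
})

test_that("aggregates are exact means over present components", {
  all_one <- aggregate_scores(list(asw_batch = 1, pcr = 1, gc = 1,
                                   kbet = 1, ilisi = 1))
  expect_equal(all_one$s_batch, 1)
  spread <- aggregate_scores(list(asw_batch = 0.2, pcr = 0.4, gc = 0.6,
                                  kbet = 0.8, ilisi = 1.0))
  expect_equal(spread$s_batch, 0.6)
  partial <- aggregate_scores(list(asw_batch = 0.2, pcr = 0.4, gc = 0.6,
                                   kbet = 0.8,
                                   asw_label = 0.5, nmi = 0.7, ari = 0.3,
                                   clisi = 0.9))
  expect_equal(partial$s_batch, 0.5)
  expect_identical(partial$missing$batch, "ilisi")
  expect_equal(partial$s_bio, 0.6)
  empty <- aggregate_scores(list(nmi = 0.5))
  expect_true(is.na(empty$s_batch))
})

test_that("the full evaluation wrapper fills every applicable slot", {
  bl <- two_blobs(n_per = 60)
  batches <- rep(c("b1", "b2"), 60)
  rep1 <- evaluate_embeddings(bl$x, cell_types = bl$labels,
                              batches = batches, seed = 2)
  for (nm in c("nmi", "ari", "gc", "asw_label", "asw_batch", "ilisi",
               "clisi", "pcr", "kbet", "s_batch", "s_bio")) {
    expect_false(is.null(rep1[[nm]]), label = nm)
  }
  expect_equal(rep1$s_bio,
               mean(c(rep1$asw_label, rep1$nmi, rep1$ari, rep1$clisi)))
})

test_that("annotation metrics reproduce the hand confusion-matrix case", {
  expect_equal(annotation_metrics(c("a", "b"), c("a", "b"))$f1, 1)
  r <- annotation_metrics(pred = rep("pos", 4),
                          truth = c("pos", "pos", "pos", "neg"))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$precision, (0.75 + 0) / 2)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, (2 * 0.75 / 1.75 + 0) / 2)
  none <- annotation_metrics(c("x", "x"), c("y", "z"))
  expect_equal(none$f1, 0)
  expect_error(annotation_metrics("a", c("a", "b")), "equal length")
  w <- annotation_metrics(rep("pos", 4), c("pos", "pos", "pos", "neg"),
                          averaging = "weighted")
  expect_equal(w$precision, 0.75 * 0.75)
})

test_that("regression metrics follow the printed formulas", {
  y <- c(1, 5, 2, 4)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$mse, 0)
  const <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(const$r2, 0)
  expect_equal(const$n_skipped, 1L)
  hand <- regression_metrics(c(1, 2, 3), c(2, 4, 6))
  expect_equal(hand$pcc, 1)
  expect_equal(hand$mse, 14 / 3)
  expect_equal(hand$r2, -6)
  m <- regression_metrics(cbind(c(1, 2, 3), c(1, 2, 3)),
                          cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(m$r2, mean(c(1, 1 - 8 / 2)))
  expect_error(regression_metrics(1:3, 1:4), "identical shape")
})

test_that("normalized metrics stay in [0,1] on random instances", {
  set.seed(85)
  for (i in 1:100) {
    n <- sample(20:40, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    types <- sample(c("t1", "t2", "t3"), n, replace = TRUE)
    batches <- sample(c("b1", "b2"), n, replace = TRUE)
    if (min(table(types)) < 2 || min(table(batches)) < 2) next
    vals <- c(
      unlist(lisi_scores(x, batches = batches, cell_types = types,
                         graph_k = 5)),
      as.numeric(asw_scores(x, cell_types = types,
                            batches = batches)$asw_label),
      as.numeric(pcr_score(x, batches)),
      kbet_score(x, batches, graph_k = 5),
      graph_connectivity(x, types, graph_k = 5),
      unlist(annotation_metrics(sample(types), types)[
        c("accuracy", "precision", "recall", "f1")]))
    expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
  }
})
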