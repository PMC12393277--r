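test_that("classifier loss matches closed forms", {
  expect_equal(classifier_loss(matrix(0, 4, 5), rep(1, 4)), log(5))
  big <- matrix(-50, 3, 3)
  big[cbind(1:3, 1:3)] <- 50
  expect_lt(classifier_loss(big, 1:3), 1e-10)
  # hand softmax: two cells, logits [[1,0],[0,1]], true classes on the 1s
  expect_equal(classifier_loss(rbind(c(1, 0), c(0, 1)), c(1, 2)),
               -log(exp(1) / (exp(1) + 1)))
  expect_error(classifier_loss(matrix(0, 2, 2), c(1, 3)), "class set")
  expect_equal(classifier_loss(matrix(0, 2, 2), c("a", "b"),
                               class_levels = c("a", "b")), log(2))
})

test_that("contrastive loss matches hand-evaluated cases", {
  # three identical vectors, one label: every anchor term reduces to log 2
  z <- matrix(1, 3, 4)
  expect_equal(as.numeric(contrastive_loss(z, rep("a", 3))), log(2))
  # orthogonal tight clusters at vanishing temperature: loss -> 0
  z2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  lab2 <- c("a", "a", "b", "b")
  expect_lt(as.numeric(contrastive_loss(z2, lab2, temperature = 0.01)),
            1e-10)
  # every label unique: defined as 0 with a flag
  u <- contrastive_loss(matrix(rnorm(6), 3, 2), c("a", "b", "c"))
  expect_equal(as.numeric(u), 0)
  expect_true(attr(u, "no_positives"))
})

test_that("contrastive gradient matches finite differences", {
  set.seed(60)
  z <- matrix(rnorm(5 * 3), 5, 3)
  labels <- c("a", "a", "b", "b", "b")
  tau <- 0.1
  got <- scelmo:::.supcon(z, labels, tau, want_grad = TRUE)
  eps <- 1e-6
  for (idx in sample(15, 6)) {
    zp <- z; zp[idx] <- zp[idx] + eps
    zm <- z; zm[idx] <- zm[idx] - eps
    fd <- (scelmo:::.supcon(zp, labels, tau)$loss -
             scelmo:::.supcon(zm, labels, tau)$loss) / (2 * eps)
    expect_equal(got$grad[idx], fd, tolerance = 1e-5)
  }
})

make_blobs <- function(n_per, centers, sd, seed) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(sprintf("c%d", seq_len(nrow(centers))),
                           each = n_per))
}

test_that("training separates linearly separable blobs perfectly", {
  centers <- rbind(rep(5, 16), rep(-5, 16))
  blobs <- make_blobs(200, centers, sd = 1, seed = 61)
  # separability oracle: nearest-centroid classification is already perfect
  cent <- rbind(colMeans(blobs$x[1:200, ]), colMeans(blobs$x[201:400, ]))
  d <- scelmo:::.dist_matrix(blobs$x, cent)
  expect_equal(mean(max.col(-d) == rep(1:2, each = 200)), 1)

  cfg <- adaptor_config(input_dim = 16, n_classes = 2,
                        hidden_dims = c(32, 16), max_epochs = 30,
                        patience = 5, seed = 7)
  fit <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  expect_equal(fit$best_validation_accuracy, 1.0)
  expect_s3_class(fit, "scelmo_adaptor")
})

test_that("history decomposes as total = classifier + lambda * contrastive", {
  blobs <- make_blobs(60, rbind(c(3, 3, 3, 3), c(-3, -3, -3, -3)),
                      sd = 1, seed = 62)
  cfg <- adaptor_config(input_dim = 4, n_classes = 2, hidden_dims = c(8),
                        max_epochs = 8, seed = 3)
  fit <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  h <- fit$history
  lam <- cfg$lambda_contrastive
  expect_true(all(abs(h$total_loss -
                        (h$classifier_loss + lam * h$contrastive_loss)) /
                    pmax(abs(h$total_loss), 1e-12) < 1e-6))
  # lambda = 0: the total must equal the classifier term alone
  cfg0 <- adaptor_config(input_dim = 4, n_classes = 2, hidden_dims = c(8),
                         lambda_contrastive = 0, max_epochs = 5, seed = 3)
  fit0 <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg0)
  expect_equal(fit0$history$total_loss, fit0$history$classifier_loss)
})

test_that("training is bitwise reproducible under a fixed seed", {
  blobs <- make_blobs(50, rbind(c(2, 2, 0), c(-2, -2, 0)), sd = 1,
                      seed = 63)
  cfg <- adaptor_config(input_dim = 3, n_classes = 2, hidden_dims = c(8, 4),
                        max_epochs = 6, seed = 11)
  f1 <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  f2 <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("degenerate label sets are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(scelmo_adaptor(x, rep("only", 10)), "single class")
  expect_error(scelmo_adaptor(x, rep(c("a", "b"), 5),
                              val = x, val_labels = rep("zz", 10)),
               "outside the training label set")
})

test_that("the latent space is the last hidden ReLU layer", {
  hook <- identity_adaptor(3)
  x <- rbind(c(1, -2, 3), c(0.5, 0, -1))
  expect_equal(predict(hook, x, type = "latent"), pmax(x, 0))
  expect_identical(predict(hook, x, type = "latent"),
                   predict(hook, x, type = "latent"))
  blobs <- make_blobs(30, rbind(c(2, 2), c(-2, -2)), sd = 0.5, seed = 64)
  cfg <- adaptor_config(input_dim = 2, n_classes = 2, hidden_dims = c(16, 5),
                        max_epochs = 3, seed = 2)
  fit <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  expect_equal(ncol(predict(fit, blobs$x, type = "latent")), 5L)
  expect_error(predict(fit, matrix(0, 1, 3)), "dims")
})

test_that("identity-hook fine-tuned annotation reduces to zero-shot kNN", {
  set.seed(65)
  tr <- matrix(abs(rnorm(40)), 20, 2)  # non-negative: ReLU is identity
  te <- matrix(abs(rnorm(10)), 5, 2)
  labs <- rep(c("a", "b"), 10)
  hook <- identity_adaptor(2)
  expect_identical(annotate_finetuned(hook, tr, labs, te, k = 5),
                   knn_annotate(tr, labs, te, k = 5))
  expect_error(annotate_finetuned(hook, tr, labs, te, k = 21), "exceeds")
})

test_that("separated latent clusters annotate held-out cells perfectly", {
  # constructed clusters: the identity hook leaves the (non-negative)
  # separation intact, so latent-space kNN must be error-free
  blobs <- make_blobs(100, rbind(rep(10, 4), rep(1, 4)), sd = 0.5,
                      seed = 66)
  sp <- split_cells(200, seed = 1)
  hook <- identity_adaptor(4)
  out <- annotate_finetuned(hook, blobs$x[sp$train, ],
                            blobs$labels[sp$train],
                            blobs$x[sp$test, ], k = 10)
  expect_equal(mean(out$labels == blobs$labels[sp$test]), 1)

  # a trained adaptor on the same geometry stays near-perfect
  cfg <- adaptor_config(input_dim = 4, n_classes = 2, hidden_dims = c(16, 8),
                        max_epochs = 30, patience = 8, seed = 5)
  fit <- scelmo_adaptor(blobs$x[sp$train, ], blobs$labels[sp$train],
                        config = cfg)
  trained <- annotate_finetuned(fit, blobs$x[sp$train, ],
                                blobs$labels[sp$train],
                                blobs$x[sp$test, ], k = 10)
  expect_gte(mean(trained$labels == blobs$labels[sp$test]), 0.95)
})

test_that("a saved adaptor reloads to identical predictions", {
  blobs <- make_blobs(40, rbind(c(2, 0, 0), c(-2, 0, 0)), sd = 0.5,
                      seed = 67)
  cfg <- adaptor_config(input_dim = 3, n_classes = 2, hidden_dims = c(6),
                        max_epochs = 4, seed = 9)
  fit <- scelmo_adaptor(blobs$x, blobs$labels, config = cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_adaptor(fit, path)
  back <- load_adaptor(path)
  expect_identical(back$class_labels, fit$class_labels)
  expect_equal(back$weights, fit$weights, tolerance = 1e-15)
  expect_identical(predict(back, blobs$x, type = "class"),
                   predict(fit, blobs$x, type = "class"))
  expect_equal(predict(back, blobs$x, type = "latent"),
               predict(fit, blobs$x, type = "latent"), tolerance = 1e-12)
})

test_that("random embeddings still beat chance after fine-tuning", {
  ds <- simulate_dataset(preset_config("clustering", seed = 19))
  rnd <- random_embedding_table(ds$expression$gene_ids, t = 32, seed = 0)
  emb <- zero_shot_embeddings(ds$expression, rnd, mode = "wa")
  truth <- ds$expression$cell_type
  sp <- split_cells(nrow(emb$vectors), seed = 19)
  cfg <- adaptor_config(input_dim = 32, n_classes = 4,
                        hidden_dims = c(64, 32), max_epochs = 40,
                        patience = 8, seed = 19)
  fit <- scelmo_adaptor(emb$vectors[sp$train, ], truth[sp$train],
                        config = cfg)
  out <- annotate_finetuned(fit, emb$vectors[sp$train, ], truth[sp$train],
                            emb$vectors[sp$test, ], k = 10)
  acc <- mean(out$labels == truth[sp$test])
  chance <- max(table(truth[sp$test])) / length(sp$test)
  expect_gte(acc, chance + 0.3)
})
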