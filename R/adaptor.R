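#' Adaptor configuration
#'
#' Hyper-parameters of the lightweight adaptor network: a small multilayer
#' perceptron with ReLU activations trained under a joint objective
#' `L_total = L_classifier + lambda * L_contrastive`, with `lambda = 100` by
#' default so the label-aware clustering term dominates. The last hidden
#' layer is the latent space used for annotation and the deletion screen.
#'
#' @param input_dim dimension `t` of the input cell embeddings.
#' @param n_classes number of target classes.
#' @param hidden_dims integer vector of hidden-layer widths (default
#'   `c(256, 128)`); the last entry is the latent dimension.
#' @param lambda_contrastive weight of the contrastive term (default 100).
#' @param temperature softmax temperature of the contrastive loss (default
#'   0.1).
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs maximum training epochs (default 100).
#' @param patience early-stopping patience on validation accuracy (default
#'   10).
#' @param batch_size minibatch size (default 256).
#' @param seed integer RNG seed; training is fully reproducible given the
#'   seed.
#' @param balanced reweight the classification loss by inverse class
#'   frequency (default FALSE).
#' @return an object of class `adaptor_config`.
#' @export
adaptor_config <- function(input_dim, n_classes,
                           hidden_dims = c(256L, 128L),
                           lambda_contrastive = 100,
                           temperature = 0.1,
                           learning_rate = 1e-3,
                           max_epochs = 100L,
                           patience = 10L,
                           batch_size = 256L,
                           seed = 1L,
                           balanced = FALSE) {
  stopifnot(input_dim >= 1, n_classes >= 2, length(hidden_dims) >= 1,
            all(hidden_dims >= 1), lambda_contrastive >= 0,
            temperature > 0, learning_rate > 0, max_epochs >= 1,
            patience >= 1, batch_size >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden_dims = as.integer(hidden_dims),
                 lambda_contrastive = lambda_contrastive,
                 temperature = temperature,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 balanced = isTRUE(balanced)),
            class = "adaptor_config")
}

# ---- losses -----------------------------------------------------------------

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Multiclass cross-entropy classification loss
#'
#' Mean negative log softmax probability of the true class.
#'
#' @param logits numeric matrix, cells by classes.
#' @param labels class memberships: integer indices in `1..n_classes`, or
#'   values of `class_levels`.
#' @param class_levels optional character vector naming the logit columns.
#' @param weights optional per-class weights (same order as columns).
#' @return non-negative scalar loss.
#' @export
classifier_loss <- function(logits, labels, class_levels = NULL,
                            weights = NULL) {
  if (!is.matrix(logits)) stop("logits must be a matrix")
  y <- .label_index(labels, ncol(logits), class_levels)
  p <- .softmax(logits)
  ll <- -log(pmax(p[cbind(seq_len(nrow(logits)), y)], 1e-300))
  if (is.null(weights)) mean(ll) else {
    w <- weights[y]
    sum(w * ll) / sum(w)
  }
}

.label_index <- function(labels, n_classes, class_levels = NULL) {
  if (is.numeric(labels) && is.null(class_levels)) {
    y <- as.integer(labels)
    if (any(y < 1 | y > n_classes)) {
      stop("label outside the class set 1..", n_classes)
    }
    return(y)
  }
  if (is.null(class_levels)) stop("class_levels required for named labels")
  y <- match(as.character(labels), class_levels)
  if (anyNA(y)) {
    stop("label outside the class set: ",
         paste(unique(labels[is.na(y)]), collapse = ", "))
  }
  y
}

# Supervised contrastive loss on L2-normalized latent vectors, with its
# gradient wrt the un-normalized latent matrix. For each anchor with at
# least one same-label positive:
#   -(1/|P(a)|) sum_p log( exp(cos(z_a,z_p)/tau) /
#                          sum_{b != a} exp(cos(z_a,z_b)/tau) )
# averaged over such anchors. Anchors without positives are excluded; if no
# anchor has a positive the loss is 0 (flagged).
.supcon <- function(z, labels, tau, want_grad = FALSE) {
  n <- nrow(z)
  d <- ncol(z)
  zero_out <- list(loss = 0, grad = matrix(0, n, d), no_positives = TRUE)
  if (n < 2) return(zero_out)
  labels <- as.character(labels)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  anchors <- npos > 0
  if (!any(anchors)) return(zero_out)
  r <- sqrt(rowSums(z^2))
  rsafe <- ifelse(r == 0, 1, r)
  u <- z / rsafe
  s <- tcrossprod(u)
  ex <- exp(s / tau)
  diag(ex) <- 0
  denom <- rowSums(ex)
  mean_pos_sim <- rowSums(s * same) / pmax(npos, 1)
  per_anchor <- log(denom) - mean_pos_sim / tau
  n_anchor <- sum(anchors)
  loss <- sum(per_anchor[anchors]) / n_anchor
  if (!want_grad) {
    return(list(loss = loss, grad = NULL, no_positives = FALSE))
  }
  q <- ex / denom            # q[a, b] = softmax over b != a
  g <- (q - same / pmax(npos, 1)) / (tau * n_anchor)
  g[!anchors, ] <- 0
  diag(g) <- 0
  gu <- (g + t(g)) %*% u      # dL/du
  # back through u = z / ||z||
  proj <- rowSums(gu * u)
  gz <- (gu - u * proj) / rsafe
  gz[r == 0, ] <- 0
  list(loss = loss, grad = gz, no_positives = FALSE)
}

#' Supervised contrastive loss
#'
#' The label-aware clustering term of the adaptor objective: anchors are
#' pulled toward same-label cells and pushed from all others in cosine
#' similarity, with softmax temperature `temperature`. Latent vectors are
#' L2-normalized internally. Batches in which no anchor has a same-label
#' positive yield 0 with attribute `no_positives = TRUE`.
#'
#' @param latent numeric matrix, cells by latent dims (`n >= 2`).
#' @param labels per-cell labels defining positives.
#' @param temperature positive softmax temperature (default 0.1).
#' @return non-negative scalar loss.
#' @export
contrastive_loss <- function(latent, labels, temperature = 0.1) {
  if (!is.matrix(latent)) stop("latent must be a matrix")
  if (nrow(latent) < 2) stop("contrastive loss needs at least 2 cells")
  if (temperature <= 0) stop("temperature must be positive")
  res <- .supcon(latent, labels, temperature, want_grad = FALSE)
  structure(res$loss, no_positives = res$no_positives)
}

# ---- network ----------------------------------------------------------------

.init_weights <- function(config) {
  dims <- c(config$input_dim, config$hidden_dims, config$n_classes)
  weights <- vector("list", length(dims) - 1)
  for (l in seq_along(weights)) {
    fan_in <- dims[l]
    weights[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1]))
  }
  weights
}

# Forward pass; hidden layers use ReLU, the output layer is linear. The
# latent representation is the post-ReLU activation of the last hidden
# layer.
.adaptor_forward <- function(weights, x) {
  n_hidden <- length(weights) - 1
  pre <- vector("list", n_hidden)
  act <- vector("list", n_hidden)
  h <- x
  for (l in seq_len(n_hidden)) {
    pre[[l]] <- sweep(h %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    act[[l]] <- pmax(pre[[l]], 0)
    h <- act[[l]]
  }
  out <- length(weights)
  logits <- sweep(h %*% weights[[out]]$W, 2, weights[[out]]$b, "+")
  list(pre = pre, act = act, logits = logits)
}

# One joint backward pass: cross-entropy on the logits plus
# lambda * supervised-contrastive on the latent layer.
.adaptor_backward <- function(weights, x, fwd, y, con_labels, config,
                              class_weights = NULL) {
  n <- nrow(x)
  n_hidden <- length(weights) - 1
  latent <- if (n_hidden > 0) fwd$act[[n_hidden]] else x
  p <- .softmax(fwd$logits)
  onehot <- matrix(0, n, ncol(p))
  onehot[cbind(seq_len(n), y)] <- 1
  if (is.null(class_weights)) {
    dlogits <- (p - onehot) / n
    cls <- -sum(log(pmax(p[cbind(seq_len(n), y)], 1e-300))) / n
  } else {
    w <- class_weights[y]
    dlogits <- (p - onehot) * (w / sum(w))
    cls <- sum(w * -log(pmax(p[cbind(seq_len(n), y)], 1e-300))) / sum(w)
  }
  con <- .supcon(latent, con_labels, config$temperature,
                 want_grad = config$lambda_contrastive > 0)
  grads <- vector("list", length(weights))
  out <- length(weights)
  grads[[out]] <- list(W = crossprod(latent, dlogits),
                       b = colSums(dlogits))
  dh <- dlogits %*% t(weights[[out]]$W)
  if (config$lambda_contrastive > 0) {
    dh <- dh + config$lambda_contrastive * con$grad
  }
  for (l in rev(seq_len(n_hidden))) {
    dpre <- dh * (fwd$pre[[l]] > 0)
    h_in <- if (l == 1) x else fwd$act[[l - 1]]
    grads[[l]] <- list(W = crossprod(h_in, dpre), b = colSums(dpre))
    if (l > 1) dh <- dpre %*% t(weights[[l]]$W)
  }
  list(grads = grads, classifier_loss = cls, contrastive_loss = con$loss)
}

#' Fit the contrastive adaptor
#'
#' Trains the adaptor network on zero-shot cell embeddings with the joint
#' objective `L_total = L_classifier + lambda * L_contrastive`, using Adam
#' with minibatches and early stopping on validation accuracy. The returned
#' model carries the weights from the epoch with the best validation
#' accuracy (earliest epoch on ties). Training is fully reproducible given
#' `config$seed`.
#'
#' @param train a `CellEmbeddings` object (or matrix) of training cells.
#' @param train_labels per-cell class labels for the classification head.
#' @param val,val_labels validation cells and labels used for model
#'   selection; the validation label set must be a subset of the training
#'   one. Defaults to the training data when omitted.
#' @param config an [adaptor_config()]; defaults are derived from the data
#'   when `NULL`.
#' @param contrastive_labels optional label vector for the contrastive term
#'   (e.g. condition rather than cell type); defaults to `train_labels`.
#' @param verbose print per-epoch progress.
#' @return an object of class `scelmo_adaptor` with elements `config`,
#'   `weights`, `class_labels`, `history` (per-epoch `total_loss`,
#'   `classifier_loss`, `contrastive_loss`, `validation_accuracy`) and
#'   `best_epoch`. Methods: [predict.scelmo_adaptor()],
#'   [print.scelmo_adaptor()], [summary.scelmo_adaptor()],
#'   [plot.scelmo_adaptor()], [coef.scelmo_adaptor()].
#' @export
scelmo_adaptor <- function(train, train_labels, val = NULL,
                           val_labels = NULL, config = NULL,
                           contrastive_labels = NULL, verbose = FALSE) {
  x <- .as_embedding_matrix(train)
  train_labels <- as.character(train_labels)
  if (length(train_labels) != nrow(x)) {
    stop("train_labels length must equal the number of training cells")
  }
  class_labels <- sort(unique(train_labels))
  if (length(class_labels) < 2) {
    stop("training labels contain a single class; ",
         "both loss terms are degenerate")
  }
  if (is.null(val)) {
    val <- x
    val_labels <- train_labels
  }
  xv <- .as_embedding_matrix(val)
  val_labels <- as.character(val_labels)
  if (length(val_labels) != nrow(xv)) {
    stop("val_labels length must equal the number of validation cells")
  }
  if (!all(val_labels %in% class_labels)) {
    stop("validation labels outside the training label set: ",
         paste(setdiff(unique(val_labels), class_labels), collapse = ", "))
  }
  if (is.null(config)) {
    config <- adaptor_config(input_dim = ncol(x),
                             n_classes = length(class_labels))
  }
  if (config$input_dim != ncol(x)) {
    stop("config$input_dim (", config$input_dim,
         ") does not match the data (", ncol(x), ")")
  }
  if (config$n_classes != length(class_labels)) {
    stop("config$n_classes (", config$n_classes, ") does not match the ",
         length(class_labels), " observed classes")
  }
  if (is.null(contrastive_labels)) contrastive_labels <- train_labels
  contrastive_labels <- as.character(contrastive_labels)
  if (length(contrastive_labels) != nrow(x)) {
    stop("contrastive_labels length must equal the number of training cells")
  }
  y <- match(train_labels, class_labels)
  yv <- match(val_labels, class_labels)
  class_weights <- if (config$balanced) {
    freq <- tabulate(y, nbins = config$n_classes)
    length(y) / (config$n_classes * pmax(freq, 1))
  } else NULL

  .with_seed(config$seed, {
    weights <- .init_weights(config)
    adam_m <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
    adam_v <- adam_m
    adam_t <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(x)
    history <- data.frame(epoch = integer(0), total_loss = numeric(0),
                          classifier_loss = numeric(0),
                          contrastive_loss = numeric(0),
                          validation_accuracy = numeric(0))
    best_acc <- -Inf
    best_epoch <- NA_integer_
    best_weights <- weights
    stale <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      cls_sum <- 0; con_sum <- 0; n_seen <- 0
      for (s in starts) {
        ix <- perm[s:min(s + config$batch_size - 1, n)]
        fwd <- .adaptor_forward(weights, x[ix, , drop = FALSE])
        bwd <- .adaptor_backward(weights, x[ix, , drop = FALSE], fwd,
                                 y[ix], contrastive_labels[ix], config,
                                 class_weights)
        adam_t <- adam_t + 1
        for (l in seq_along(weights)) {
          for (p in c("W", "b")) {
            g <- bwd$grads[[l]][[p]]
            adam_m[[l]][[p]] <- b1 * adam_m[[l]][[p]] + (1 - b1) * g
            adam_v[[l]][[p]] <- b2 * adam_v[[l]][[p]] + (1 - b2) * g^2
            mhat <- adam_m[[l]][[p]] / (1 - b1^adam_t)
            vhat <- adam_v[[l]][[p]] / (1 - b2^adam_t)
            weights[[l]][[p]] <- weights[[l]][[p]] -
              config$learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
        nb <- length(ix)
        cls_sum <- cls_sum + nb * bwd$classifier_loss
        con_sum <- con_sum + nb * bwd$contrastive_loss
        n_seen <- n_seen + nb
      }
      cls_epoch <- cls_sum / n_seen
      con_epoch <- con_sum / n_seen
      total_epoch <- cls_epoch + config$lambda_contrastive * con_epoch
      val_fwd <- .adaptor_forward(weights, xv)
      val_acc <- mean(max.col(val_fwd$logits, ties.method = "first") == yv)
      history <- rbind(history,
                       data.frame(epoch = epoch, total_loss = total_epoch,
                                  classifier_loss = cls_epoch,
                                  contrastive_loss = con_epoch,
                                  validation_accuracy = val_acc))
      if (verbose) {
        message(sprintf("epoch %3d  total %.4f  cls %.4f  con %.4f  val %.4f",
                        epoch, total_epoch, cls_epoch, con_epoch, val_acc))
      }
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_epoch <- epoch
        best_weights <- weights
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    structure(list(config = config, weights = best_weights,
                   class_labels = class_labels, history = history,
                   best_epoch = best_epoch,
                   best_validation_accuracy = best_acc),
              class = "scelmo_adaptor")
  })
}

#' Predict from a fitted adaptor
#'
#' @param object a fitted [scelmo_adaptor()].
#' @param newdata a `CellEmbeddings` object or numeric matrix with
#'   `config$input_dim` columns.
#' @param type `"class"` (predicted labels), `"prob"` (softmax
#'   probabilities), `"logits"`, or `"latent"` (last-hidden-layer
#'   activations).
#' @param ... unused.
#' @return depends on `type`; deterministic given fixed weights.
#' @export
predict.scelmo_adaptor <- function(object, newdata,
                                   type = c("class", "prob", "logits",
                                            "latent"), ...) {
  type <- match.arg(type)
  x <- .as_embedding_matrix(newdata)
  if (ncol(x) != object$config$input_dim) {
    stop("newdata has ", ncol(x), " dims; model expects ",
         object$config$input_dim)
  }
  fwd <- .adaptor_forward(object$weights, x)
  switch(type,
         logits = fwd$logits,
         prob = .softmax(fwd$logits),
         class = object$class_labels[max.col(fwd$logits,
                                             ties.method = "first")],
         latent = {
           n_hidden <- length(object$weights) - 1
           if (n_hidden > 0) fwd$act[[n_hidden]] else x
         })
}

#' @export
print.scelmo_adaptor <- function(x, ...) {
  cat("scelmo adaptor\n")
  cat(sprintf("  architecture: %d -> %s -> %d classes (ReLU)\n",
              x$config$input_dim,
              paste(x$config$hidden_dims, collapse = " -> "),
              x$config$n_classes))
  cat(sprintf("  lambda = %g, temperature = %g, seed = %d\n",
              x$config$lambda_contrastive, x$config$temperature,
              x$config$seed))
  cat(sprintf("  trained %d epochs; best epoch %d (val accuracy %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_validation_accuracy))
  invisible(x)
}

#' @export
summary.scelmo_adaptor <- function(object, ...) {
  print(object)
  cat("\nclasses:", paste(object$class_labels, collapse = ", "), "\n")
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.scelmo_adaptor <- function(object, ...) object$weights

#' @export
plot.scelmo_adaptor <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$total_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$validation_accuracy, type = "l",
                 xlab = "epoch", ylab = "accuracy",
                 main = "validation accuracy", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Embed cells through a fitted adaptor
#'
#' Maps cell embeddings to the adaptor's latent space (post-ReLU activations
#' of the last hidden layer), extending the provenance with the model
#' identity.
#'
#' @param model a fitted [scelmo_adaptor()].
#' @param cells a `CellEmbeddings` object.
#' @return a `CellEmbeddings` object of latent vectors.
#' @export
embed_cells_finetuned <- function(model, cells) {
  stopifnot(inherits(model, "scelmo_adaptor"),
            inherits(cells, "CellEmbeddings"))
  latent <- predict(model, cells, type = "latent")
  prov <- cells$provenance
  prov$model <- sprintf("adaptor(seed=%d,best_epoch=%d)",
                        model$config$seed, model$best_epoch)
  cell_embeddings(cells$cell_ids, latent, provenance = prov)
}

#' kNN annotation in the adaptor's latent space
#'
#' Maps both reference and query cells through the fitted adaptor and runs
#' [knn_annotate()] in the latent space.
#'
#' @inheritParams knn_annotate
#' @param model a fitted [scelmo_adaptor()].
#' @return as [knn_annotate()].
#' @export
annotate_finetuned <- function(model, train, train_labels, test, k = 10,
                               metric = c("euclidean", "cosine")) {
  stopifnot(inherits(model, "scelmo_adaptor"))
  ztr <- predict(model, train, type = "latent")
  zte <- predict(model, test, type = "latent")
  knn_annotate(ztr, train_labels, zte, k = k, metric = match.arg(metric))
}

#' Save / load a fitted adaptor
#'
#' The model is serialized to a single JSON archive (config, class labels,
#' weight arrays at full precision) and can be reloaded across sessions.
#'
#' @param model a fitted [scelmo_adaptor()].
#' @param path output path (`.json`).
#' @return `save_adaptor` invisibly returns `path`; `load_adaptor` returns
#'   the reconstructed `scelmo_adaptor`.
#' @export
save_adaptor <- function(model, path) {
  stopifnot(inherits(model, "scelmo_adaptor"))
  payload <- list(
    config = unclass(model$config),
    class_labels = model$class_labels,
    best_epoch = model$best_epoch,
    best_validation_accuracy = model$best_validation_accuracy,
    history = model$history,
    weights = lapply(model$weights, function(w) {
      list(W = list(dim = dim(w$W), data = as.vector(w$W)), b = w$b)
    }))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_adaptor
#' @export
load_adaptor <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg_fields <- p$config[names(p$config) %in% names(formals(adaptor_config))]
  cfg_fields <- lapply(cfg_fields, unlist)
  cfg <- do.call(adaptor_config, cfg_fields)
  weights <- lapply(p$weights, function(w) {
    dims <- unlist(w$W$dim)
    list(W = matrix(unlist(w$W$data), dims[1], dims[2]),
         b = as.numeric(unlist(w$b)))
  })
  hist_cols <- c("epoch", "total_loss", "classifier_loss",
                 "contrastive_loss", "validation_accuracy")
  history <- as.data.frame(lapply(stats::setNames(hist_cols, hist_cols),
                                  function(cn) {
    vapply(p$history, function(row) as.numeric(row[[cn]]), numeric(1))
  }))
  structure(list(config = cfg, weights = weights,
                 class_labels = as.character(unlist(p$class_labels)),
                 history = history,
                 best_epoch = as.integer(p$best_epoch),
                 best_validation_accuracy =
                   as.numeric(p$best_validation_accuracy)),
            class = "scelmo_adaptor")
}
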