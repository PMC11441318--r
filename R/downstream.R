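#' Per-protein embeddings by global average pooling
#'
#' Runs the student encoder over each (clean) token sequence and averages the
#' per-position hidden states, yielding one fixed-length vector per protein.
#'
#' @param model An `mtdp_model` (or bare `student_params`).
#' @param tokens A tibble from [tokenize_sequences()], produced with the
#'   model's vocabulary.
#' @param vocab The vocabulary the tokens were produced with (checked against
#'   the model's recorded vocabulary when `model` is an `mtdp_model`).
#' @return A tibble with an `id` column and `e1 ... ed` embedding columns.
#' @export
embed_sequences <- function(model, tokens, vocab = aa_vocabulary()) {
  params <- if (inherits(model, "mtdp_model")) {
    if (!identical(model$vocab_hash, vocab_hash(vocab))) {
      stop("vocabulary mismatch between model and tokens", call. = FALSE)
    }
    model$params
  } else {
    model
  }
  scfg <- attr(params, "config")
  if (anyDuplicated(tokens$id)) stop("duplicate sequence ids", call. = FALSE)
  mat <- t(vapply(tokens$tokens, function(tk) {
    colMeans(encode_sequence(params, tk, scfg)$hidden)
  }, numeric(scfg$hidden_dim)))
  colnames(mat) <- paste0("e", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(id = tokens$id), tibble::as_tibble(mat))
}

embedding_matrix <- function(embeddings) {
  m <- as.matrix(embeddings[setdiff(names(embeddings), "id")])
  rownames(m) <- embeddings$id
  m
}

#' Write embeddings as a tab-separated matrix
#'
#' @param embeddings A tibble from [embed_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  utils::write.table(embeddings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated label file
#'
#' Format: `id<TAB>label`, no header. For multi-label tasks the label field
#' holds comma-separated label indices (possibly empty).
#'
#' @param path Label file path.
#' @param task_kind One of `"binary"`, `"multiclass"`, `"multilabel"`,
#'   `"regression"`.
#' @return A tibble with columns `id` and `label` (list column for
#'   multilabel, numeric for regression, integer otherwise).
#' @export
read_labels <- function(path, task_kind = c("binary", "multiclass",
                                            "multilabel", "regression")) {
  task_kind <- match.arg(task_kind)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "label"),
                          colClasses = c("character", "character"))
  label <- switch(task_kind,
    regression = as.numeric(df$label),
    multilabel = lapply(strsplit(df$label, ","),
                        function(x) as.integer(x[nzchar(x)])),
    as.integer(df$label))
  tibble::tibble(id = df$id, label = label)
}

# ---- MLP head ---------------------------------------------------------------

task_targets <- function(labels, task_kind, n_labels = NULL) {
  switch(task_kind,
    binary = ,
    multiclass = {
      cls <- sort(unique(labels))
      if (length(cls) < 2L) {
        stop("classification requires at least 2 classes in the training set",
             call. = FALSE)
      }
      y <- match(labels, cls)
      list(y = y, classes = cls, n_out = length(cls))
    },
    multilabel = {
      nl <- n_labels %||% max(c(0L, unlist(labels))) + 1L
      Y <- matrix(0, length(labels), nl)
      for (i in seq_along(labels)) Y[i, labels[[i]] + 1L] <- 1
      list(Y = Y, n_out = nl)
    },
    regression = list(y = as.numeric(labels), n_out = 1L))
}

#' Fit a two-layer perceptron head on embeddings
#'
#' The standard fine-tuning head: a two-layer feed-forward network (one ReLU
#' hidden layer, default width 256) trained full-batch with AdamW until the
#' training loss plateaus or `max_epochs` is reached. Loss functions follow
#' the task family: softmax cross-entropy for binary/multiclass,
#' per-label binary cross-entropy for multilabel, mean squared error for
#' regression. The student encoder stays frozen; only the head is trained.
#'
#' @param embeddings Tibble from [embed_sequences()] (column `id` +
#'   embedding columns).
#' @param labels Tibble with columns `id`, `label` ([read_labels()] format).
#' @param task_kind `"binary"`, `"multiclass"`, `"multilabel"` or
#'   `"regression"`.
#' @param hidden Hidden width (default 256).
#' @param lr AdamW learning rate (default 1e-2; full-batch).
#' @param max_epochs Maximum training epochs (default 500).
#' @param tol Relative training-loss improvement below which the plateau
#'   counter advances (default 1e-5).
#' @param patience Plateau epochs before early stop (default 25).
#' @param weight_decay AdamW weight decay (default 0).
#' @param n_labels Multilabel only: total number of labels (inferred from the
#'   training set when `NULL`).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp_head`.
#' @export
fit_head <- function(embeddings, labels, task_kind = c("binary", "multiclass",
                                                       "multilabel", "regression"),
                     hidden = 256L, lr = 1e-2, max_epochs = 500L, tol = 1e-5,
                     patience = 25L, weight_decay = 0, n_labels = NULL,
                     seed = 1L) {
  task_kind <- match.arg(task_kind)
  labels <- labels[match(embeddings$id, labels$id), ]
  if (anyNA(labels$id)) stop("labels missing for some embedded ids", call. = FALSE)
  X <- embedding_matrix(embeddings)
  # standardize features on the training set (guards against the widely
  # different per-dimension scales of pooled hidden states)
  mu <- colMeans(X)
  sigma <- pmax(apply(X, 2L, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2L, mu), 2L, sigma, `/`)
  tg <- task_targets(labels$label, task_kind, n_labels)
  d <- ncol(X); h <- as.integer(hidden); o <- tg$n_out

  set.seed(seed)
  p <- list(W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
            b1 = rep(0, h),
            W2 = matrix(stats::rnorm(h * o, sd = sqrt(2 / h)), h, o),
            b2 = rep(0, o))
  pvec <- flatten_params(p)
  opt <- adamw_init(length(pvec))
  n <- nrow(X)

  head_forward <- function(p) {
    A <- sweep(X %*% p$W1, 2L, p$b1, `+`)
    Z <- A * (A > 0)
    list(A = A, Z = Z, out = sweep(Z %*% p$W2, 2L, p$b2, `+`))
  }
  loss_and_grad <- function(p) {
    fw <- head_forward(p)
    out <- fw$out
    if (task_kind %in% c("binary", "multiclass")) {
      P <- softmax_rows(out)
      loss <- -mean(log(P[cbind(seq_len(n), tg$y)]))
      dout <- P / n
      dout[cbind(seq_len(n), tg$y)] <- dout[cbind(seq_len(n), tg$y)] - 1 / n
    } else if (task_kind == "multilabel") {
      P <- stats::plogis(out)
      eps <- 1e-12
      loss <- -mean(tg$Y * log(P + eps) + (1 - tg$Y) * log(1 - P + eps))
      dout <- (P - tg$Y) / length(tg$Y)
    } else {
      resid <- out[, 1L] - tg$y
      loss <- mean(resid^2)
      dout <- matrix(2 * resid / n, n, 1L)
    }
    dZ <- dout %*% t(p$W2)
    dA <- dZ * (fw$A > 0)
    g <- list(W1 = crossprod(X, dA), b1 = colSums(dA),
              W2 = crossprod(fw$Z, dout), b2 = colSums(dout))
    list(loss = loss, g = g)
  }

  hist <- numeric(0)
  best <- Inf; stall <- 0L
  for (ep in seq_len(max_epochs)) {
    lg <- loss_and_grad(p)
    hist <- c(hist, lg$loss)
    if (lg$loss < best * (1 - tol)) { best <- lg$loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    res <- adamw_step(pvec, flatten_params(lg$g), opt, lr, weight_decay)
    pvec <- res$pvec; opt <- res$opt
    p <- unflatten_params(pvec, p)
  }

  structure(
    list(params = p, task_kind = task_kind, hidden = h,
         classes = tg$classes, n_labels = if (task_kind == "multilabel") o,
         feature_names = colnames(X), center = mu, scale = sigma,
         epochs = length(hist),
         train_loss = hist[length(hist)], loss_history = hist),
    class = "mlp_head"
  )
}

#' @export
print.mlp_head <- function(x, ...) {
  cat("<mlp_head>", x$task_kind, "task, hidden", x$hidden, "\n")
  cat(sprintf("  trained %d epochs, final train loss %.5f\n",
              x$epochs, x$train_loss))
  invisible(x)
}

#' Predict with a fitted head
#'
#' @param object An `mlp_head`.
#' @param embeddings Tibble from [embed_sequences()].
#' @param ... Unused.
#' @return A tibble with `id` and task-appropriate prediction columns
#'   (`pred` class / value; `labels` list column for multilabel).
#' @export
predict.mlp_head <- function(object, embeddings, ...) {
  X <- embedding_matrix(embeddings)[, object$feature_names, drop = FALSE]
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  p <- object$params
  A <- sweep(X %*% p$W1, 2L, p$b1, `+`)
  out <- sweep((A * (A > 0)) %*% p$W2, 2L, p$b2, `+`)
  switch(object$task_kind,
    binary = ,
    multiclass = tibble::tibble(
      id = embeddings$id,
      pred = object$classes[max.col(out, ties.method = "first")]),
    multilabel = tibble::tibble(
      id = embeddings$id,
      labels = lapply(seq_len(nrow(out)), function(i) which(out[i, ] > 0) - 1L)),
    regression = tibble::tibble(id = embeddings$id, pred = out[, 1L]))
}

# ---- metrics & cross-validation --------------------------------------------

#' Evaluate a fitted head on labeled embeddings
#'
#' Default metrics per task family: accuracy (binary/multiclass),
#' micro-averaged F1 (multilabel), Spearman correlation (regression).
#'
#' @param head An `mlp_head`.
#' @param embeddings Tibble from [embed_sequences()].
#' @param labels Tibble with `id`, `label`.
#' @return A one-row tibble with `metric` and `value`.
#' @export
evaluate_head <- function(head, embeddings, labels) {
  labels <- labels[match(embeddings$id, labels$id), ]
  pred <- predict(head, embeddings)
  switch(head$task_kind,
    binary = ,
    multiclass = tibble::tibble(
      metric = "accuracy", value = mean(pred$pred == labels$label)),
    multilabel = {
      nl <- head$n_labels
      truth <- matrix(FALSE, nrow(labels), nl)
      for (i in seq_len(nrow(labels))) truth[i, labels$label[[i]] + 1L] <- TRUE
      phat <- matrix(FALSE, nrow(labels), nl)
      for (i in seq_len(nrow(labels))) phat[i, pred$labels[[i]] + 1L] <- TRUE
      tp <- sum(truth & phat)
      prec <- if (sum(phat) > 0) tp / sum(phat) else 0
      rec <- if (sum(truth) > 0) tp / sum(truth) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      tibble::tibble(metric = "micro_f1", value = f1)
    },
    regression = tibble::tibble(
      metric = "spearman",
      value = stats::cor(pred$pred, labels$label, method = "spearman")))
}

#' k-fold cross-validation of the embed-and-fine-tune pipeline
#'
#' Shuffles the ids with a fixed seed, partitions them into `k` folds whose
#' sizes differ by at most one, and for each fold trains a fresh head on the
#' other `k - 1` folds and evaluates it on the held-out fold. The default
#' `k = 10` matches standard benchmarking practice. The partition is asserted
#' on every run: no held-out id ever appears in its fold's training set.
#'
#' @param embeddings Tibble from [embed_sequences()].
#' @param labels Tibble with `id`, `label`.
#' @param task_kind Task family (see [fit_head()]).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle and head initializations.
#' @param ... Passed to [fit_head()] (e.g. `hidden`, `max_epochs`).
#' @return An object of class `cv_result`: tibble of per-fold metric values
#'   plus a `fold_assignment` attribute.
#' @export
cross_validate <- function(embeddings, labels, task_kind, k = 10L, seed = 1L, ...) {
  n <- nrow(embeddings)
  if (n < k) stop("need at least k = ", k, " samples; got ", n, call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    stopifnot(length(intersect(embeddings$id[train_idx],
                               embeddings$id[test_idx])) == 0L)
    nl <- if (task_kind == "multilabel") {
      max(c(0L, unlist(labels$label))) + 1L
    }
    head <- fit_head(embeddings[train_idx, ], labels, task_kind,
                     n_labels = nl, seed = seed + f, ...)
    ev <- evaluate_head(head, embeddings[test_idx, ], labels)
    rows[[f]] <- tibble::tibble(fold = f, metric = ev$metric, value = ev$value,
                                n_test = length(test_idx))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fold_assignment") <- tibble::tibble(id = embeddings$id, fold = fold)
  attr(out, "task_kind") <- task_kind
  class(out) <- c("cv_result", class(out))
  out
}
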