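test_that("global average pooling equals the mean of hidden states (zero-layer oracle)", {
  # with zero layers the hidden states are exactly the embedding rows, so the
  # pooled embedding has a closed form
  cfg <- student_config(num_layers = 0, hidden_dim = 8, num_heads = 1,
                        feedforward_dim = 4)
  params <- init_student(cfg, seed = 6)
  tk <- tokenize_sequences(random_records(5, seed = 7))
  emb <- embed_sequences(params, tk)
  for (i in 1:5) {
    expected <- colMeans(params$emb[tk$tokens[[i]], , drop = FALSE])
    expect_equal(unlist(emb[i, -1], use.names = FALSE), expected)
  }
  # two positions with values 1 and 3 in a dimension pool to 2
  p2 <- params; p2$emb[1, 1] <- 1; p2$emb[2, 1] <- 3
  one <- tibble::tibble(id = "x", tokens = list(c(1L, 2L)),
                        length = 2L, original_length = 2L)
  expect_equal(embed_sequences(p2, one)$e1, 2)
})

test_that("permuting batch order permutes embedding rows identically", {
  params <- init_student(tiny_cfg(), seed = 2)
  tk <- tokenize_sequences(random_records(8, seed = 3))
  emb <- embed_sequences(params, tk)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  emb_p <- embed_sequences(params, tk[perm, ])
  expect_equal(emb_p, emb[perm, ], ignore_attr = TRUE)
})

gaussian_blobs <- function(n = 200, d = 8, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1] <- X[y == 1, 1] + sep
  emb <- tibble::as_tibble(X, .name_repair = ~ paste0("e", seq_len(d)))
  emb <- dplyr::bind_cols(tibble::tibble(id = sprintf("g%03d", 1:n)), emb)
  list(emb = emb, labels = tibble::tibble(id = emb$id, label = y))
}

test_that("the MLP head separates well-separated Gaussian blobs", {
  b <- gaussian_blobs()
  head <- fit_head(b$emb, b$labels, "binary", hidden = 32, seed = 2)
  acc <- evaluate_head(head, b$emb, b$labels)
  expect_equal(acc$metric, "accuracy")
  expect_gte(acc$value, 0.99)
})

test_that("the regression head fits a realizable linear target", {
  set.seed(4)
  d <- 6; n <- 150
  X <- matrix(rnorm(n * d), n, d)
  beta <- rnorm(d)
  y <- drop(X %*% beta)
  emb <- dplyr::bind_cols(tibble::tibble(id = sprintf("r%03d", 1:n)),
                          tibble::as_tibble(X, .name_repair = ~ paste0("e", 1:d)))
  labels <- tibble::tibble(id = emb$id, label = y)
  head <- fit_head(emb, labels, "regression", hidden = 32, max_epochs = 800,
                   seed = 3)
  expect_lte(head$train_loss, 0.01 * stats::var(y))
  ev <- evaluate_head(head, emb, labels)
  expect_equal(ev$metric, "spearman")
  expect_gt(ev$value, 0.99)
})

test_that("the multilabel head recovers labels tied to thresholded coordinates", {
  set.seed(5)
  n <- 200; d <- 6
  X <- matrix(rnorm(n * d), n, d)
  lab <- lapply(seq_len(n), function(i) which(X[i, 1:2] > 0) - 1L)
  emb <- dplyr::bind_cols(tibble::tibble(id = sprintf("m%03d", 1:n)),
                          tibble::as_tibble(X, .name_repair = ~ paste0("e", 1:d)))
  labels <- tibble::tibble(id = emb$id, label = lab)
  head <- fit_head(emb, labels, "multilabel", hidden = 32, n_labels = 2L,
                   seed = 6)
  pred <- predict(head, emb)
  per_label_acc <- vapply(1:2, function(l) {
    truth <- vapply(lab, function(x) (l - 1L) %in% x, TRUE)
    got <- vapply(pred$labels, function(x) (l - 1L) %in% x, TRUE)
    mean(truth == got)
  }, 0)
  expect_true(all(per_label_acc >= 0.95))
  ev <- evaluate_head(head, emb, labels)
  expect_equal(ev$metric, "micro_f1")
  expect_gt(ev$value, 0.9)
})

test_that("degenerate single-class training sets are refused", {
  b <- gaussian_blobs(n = 40)
  b$labels$label <- 0L
  expect_error(fit_head(b$emb, b$labels, "binary"), "at least 2 classes")
})

test_that("our MLP head and nnet agree on a separable problem (independent check)", {
  skip_if_not_installed("nnet")
  b <- gaussian_blobs(n = 120, sep = 5, seed = 9)
  ours <- fit_head(b$emb, b$labels, "binary", hidden = 16, seed = 1)
  acc_ours <- evaluate_head(ours, b$emb, b$labels)$value
  X <- as.matrix(b$emb[, -1])
  nn <- nnet::nnet(X, nnet::class.ind(b$labels$label), size = 16, softmax = TRUE,
                   trace = FALSE, maxit = 200)
  acc_nnet <- mean(max.col(predict(nn, X)) - 1L == b$labels$label)
  expect_gte(acc_ours, 0.99)
  expect_gte(acc_nnet, 0.99)
})

test_that("cross-validation partitions ids into balanced disjoint folds", {
  b <- gaussian_blobs(n = 100)
  cv <- cross_validate(b$emb, b$labels, "binary", k = 10, seed = 3,
                       hidden = 8, max_epochs = 60)
  expect_equal(nrow(cv), 10L)
  expect_equal(unique(cv$n_test), 10L)
  fa <- attr(cv, "fold_assignment")
  expect_setequal(fa$id, b$emb$id)
  expect_equal(as.vector(table(fa$fold)), rep(10L, 10))
  # uneven n: fold sizes differ by at most one
  cv2 <- cross_validate(b$emb[1:97, ], b$labels[1:97, ], "binary", k = 10,
                        seed = 3, hidden = 8, max_epochs = 30)
  sizes <- table(attr(cv2, "fold_assignment")$fold)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(cross_validate(b$emb[1:5, ], b$labels[1:5, ], "binary", k = 10),
               "at least k")
  expect_equal(formals(cross_validate)$k, 10L)
})

test_that("labels independent of embeddings give chance-level accuracy", {
  set.seed(8)
  n <- 500; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  emb <- dplyr::bind_cols(tibble::tibble(id = sprintf("n%03d", 1:n)),
                          tibble::as_tibble(X, .name_repair = ~ paste0("e", 1:d)))
  labels <- tibble::tibble(id = emb$id, label = sample(0:1, n, replace = TRUE))
  cv <- cross_validate(emb, labels, "binary", k = 10, seed = 2,
                       hidden = 8, max_epochs = 80)
  expect_lt(abs(mean(cv$value) - 0.5), 0.1)
})

test_that("cv results expose tidy, glance and a box-plot autoplot", {
  b <- gaussian_blobs(n = 60)
  cv <- cross_validate(b$emb, b$labels, "binary", k = 5, seed = 1,
                       hidden = 8, max_epochs = 60)
  td <- tidy(cv)
  expect_equal(names(td), c("fold", "metric", "value", "n_test"))
  g <- glance(cv)
  expect_equal(g$k, 5L)
  expect_true(g$mean >= 0 && g$mean <= 1)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("embeddings and labels survive a round trip through their file formats", {
  params <- init_student(tiny_cfg(), seed = 1)
  tk <- tokenize_sequences(random_records(4, seed = 2))
  emb <- embed_sequences(params, tk)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(emb, f)
  back <- protdistill:::read_embeddings_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(emb), tolerance = 1e-12)

  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t0"), lf)
  expect_equal(read_labels(lf, "binary")$label, c(1L, 0L))
  writeLines(c("a\t0,2", "b\t"), lf)
  ml <- read_labels(lf, "multilabel")
  expect_equal(ml$label[[1]], c(0L, 2L))
  expect_equal(length(ml$label[[2]]), 0L)
})
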