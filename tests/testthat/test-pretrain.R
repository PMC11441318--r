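test_that("the learning-rate schedule warms up linearly then decays to zero", {
  cfg <- pretrain_config(base_lr = 3e-4, warmup_ratio = 0.1)
  total <- 1000L
  expect_equal(lr_schedule(0, total, cfg), 0)
  expect_equal(lr_schedule(ceiling(0.1 * total), total, cfg), 3e-4)
  expect_equal(lr_schedule(total, total, cfg), 0)

  lrs <- vapply(0:total, lr_schedule, 0, total_steps = total, config = cfg)
  warm <- ceiling(0.1 * total)
  expect_true(all(diff(lrs[1:(warm + 1)]) >= 0))
  expect_true(all(diff(lrs[(warm + 1):(total + 1)]) <= 0))
  expect_equal(max(lrs), 3e-4)
})

make_tiny_run <- function(n = 20, epochs = 2, seed = 5, teacher_q = 0.9,
                          batch_size = 10) {
  tk <- tokenize_sequences(random_records(n, len_range = c(15L, 25L), seed = 8))
  store <- build_test_store(
    tk, list(noisy = list(kind = "noisy_oracle", params = list(q = teacher_q))),
    new_store_dir())
  cfg <- pretrain_config(epochs = epochs, batch_size = batch_size,
                         base_lr = 1e-3, seed = seed)
  list(tk = tk, store = store, cfg = cfg)
}

test_that("a tiny pre-training run completes with finite logged losses", {
  r <- make_tiny_run()
  m <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  expect_s3_class(m, "mtdp_model")
  expect_equal(nrow(m$log), 2L * ceiling(20 / 10))
  expect_true(all(is.finite(m$log$l_mlm)))
  expect_true(all(is.finite(m$log$l_distill)))
  expect_true(all(is.finite(m$log$l_total)))
  expect_true(all(diff(m$log$step) == 1L))
  # the combined objective identity holds per step
  expect_equal(m$log$l_total,
               0.2 * m$log$l_mlm + 0.8 * m$log$l_distill, tolerance = 1e-9)
})

test_that("identical configuration and seed reproduce the checkpoint bitwise", {
  r <- make_tiny_run()
  m1 <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  m2 <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
})

test_that("resumed training equals straight-through training on the same seed stream", {
  r <- make_tiny_run(epochs = 4)
  straight <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  half <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg, stop_after_epoch = 2)
  resumed <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg, resume = half)
  expect_identical(resumed$params, straight$params)
  expect_equal(resumed$log, straight$log)
})

test_that("missing teacher records abort before any training", {
  r <- make_tiny_run()
  extra <- tokenize_sequences(random_records(25, len_range = c(15L, 25L),
                                             seed = 8))
  expect_error(pretrain(extra, r$store, tiny_cfg(), r$cfg), "missing")
})

test_that("single-teacher pre-training equals multi-teacher on a one-teacher store", {
  r <- make_tiny_run()
  a <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  b <- single_teacher_pretrain(r$tk, r$store, "noisy", tiny_cfg(), r$cfg)
  expect_identical(a$params, b$params)
  expect_equal(a$log, b$log)
  expect_null(b$choices)
  expect_error(single_teacher_pretrain(r$tk, r$store, "ghost", tiny_cfg(), r$cfg),
               "unknown teacher")
})

test_that("alpha boundaries steer the gradients to a single loss term", {
  r <- make_tiny_run()
  masked <- apply_mask(r$tk[1, ], rate = 0.3, seed = 3)
  scfg <- tiny_cfg()
  params <- init_student(scfg, seed = 2)
  pcfg <- r$cfg
  inst <- function(alpha, q) {
    store <- build_test_store(
      r$tk[1, ], list(noisy = list(kind = "noisy_oracle", params = list(q = q))),
      new_store_dir())
    protdistill:::pretrain_instance(
      params, scfg, masked, 1, store, "noisy",
      loss_config(alpha = alpha), NULL, pcfg, FALSE, FALSE, "noisy")
  }
  # alpha = 1: gradient ignores the teacher entirely
  g1a <- inst(1, 0.6); g1b <- inst(1, 0.95)
  expect_equal(g1a$gvec, g1b$gvec, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g1a$l_distill, g1b$l_distill)))
  # alpha = 0: gradient changes with the teacher
  g0a <- inst(0, 0.6); g0b <- inst(0, 0.95)
  expect_gt(max(abs(g0a$gvec - g0b$gvec)), 1e-9)
})

test_that("masked-LM training reduces the loss on a 50-sequence corpus", {
  # a skewed residue composition gives the masked positions learnable
  # structure (a uniform background would be incompressible)
  spec <- synthetic_spec(n_sequences = 50, length_range = c(15L, 25L),
                         motifs = tibble::tibble(class = 0L, motif = "DKLIVE",
                                                 prob = 1),
                         background_freqs = 0.6^(1:20), seed = 14)
  tk <- tokenize_sequences(generate_corpus(spec)$records)
  store <- build_test_store(tk, list(u = list(kind = "uniform")), new_store_dir())
  # pure MLM (alpha = 1); 200 steps of a 2-layer, hidden-32 student
  cfg <- pretrain_config(epochs = 40, batch_size = 10, base_lr = 1e-3,
                         loss = loss_config(alpha = 1), seed = 9)
  m <- single_teacher_pretrain(tk, store, "u",
                               student_config(num_layers = 2, hidden_dim = 32,
                                              num_heads = 4, feedforward_dim = 64),
                               cfg)
  first <- m$log$l_mlm[1]
  last <- mean(m$log$l_mlm[(nrow(m$log) - 4):nrow(m$log)])
  expect_equal(nrow(m$log), 200L)
  expect_lt(last, 0.7 * first)
})

test_that("checkpoints round-trip and refuse a mismatched vocabulary", {
  r <- make_tiny_run()
  m <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)

  other <- aa_vocabulary()
  other$tokens[1] <- "B"
  expect_error(load_checkpoint(f, other), "vocabulary mismatch")
})

test_that("embedding-space distillation trains and reduces its loss", {
  tk <- tokenize_sequences(random_records(20, len_range = c(12L, 20L), seed = 31))
  store <- build_test_store(
    tk, list(et = list(kind = "oracle", params = list(embed_dim = 8))),
    new_store_dir())
  cfg <- pretrain_config(epochs = 15, batch_size = 10, base_lr = 1e-3,
                         loss = loss_config(alpha = 0.2,
                                            distill_space = "embedding"),
                         seed = 4)
  m <- single_teacher_pretrain(tk, store, "et", tiny_cfg(), cfg)
  expect_true(all(is.finite(m$log$l_distill)))
  expect_lt(mean(tail(m$log$l_distill, 3)), mean(head(m$log$l_distill, 3)))
  expect_true("proj" %in% names(m$params))
})

test_that("tidy, glance and autoplot expose the training history", {
  r <- make_tiny_run()
  m <- pretrain(r$tk, r$store, tiny_cfg(), r$cfg)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("step", "l_mlm", "l_distill", "l_total") %in% names(td)))
  g <- glance(m)
  expect_equal(g$n_parameters, count_parameters(tiny_cfg()))
  expect_equal(g$steps, m$steps_done)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
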