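test_that("corpus generation is a pure function of spec and seed", {
  spec <- synthetic_spec(n_sequences = 40, seed = 9)
  expect_identical(generate_corpus(spec), generate_corpus(spec))
  spec2 <- synthetic_spec(n_sequences = 40, seed = 10)
  expect_false(identical(generate_corpus(spec)$records,
                         generate_corpus(spec2)$records))
})

test_that("insertion probability 1 plants the class motif in every sequence", {
  spec <- synthetic_spec(n_sequences = 60, task_kind = "binary", seed = 2)
  corp <- generate_corpus(spec)
  mt <- spec$motifs
  for (i in seq_len(60)) {
    motif <- mt$motif[mt$class == corp$labels$label[i]]
    expect_true(grepl(motif, corp$records$sequence[i], fixed = TRUE))
  }
})

test_that("the balanced sampler yields exactly equal class counts", {
  spec <- synthetic_spec(n_sequences = 1000, task_kind = "binary", seed = 3)
  corp <- generate_corpus(spec)
  expect_equal(as.vector(table(corp$labels$label)), c(500L, 500L))
})

test_that("impossible specs are rejected", {
  expect_error(
    synthetic_spec(length_range = c(6L, 10L),
                   motifs = tibble::tibble(class = 0:1,
                                           motif = c("ACDEFGH", "MKVLAWS"),
                                           prob = 1)),
    "shorter than the minimum")
  expect_error(
    synthetic_spec(motifs = tibble::tibble(class = 0L, motif = "ACDX", prob = 1)),
    "canonical")
})

test_that("generated corpora round-trip through FASTA unchanged", {
  corp <- generate_corpus(synthetic_spec(n_sequences = 25, seed = 5))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(corp$records, f)
  expect_equal(read_fasta(f), corp$records)
})

test_that("regression corpora carry motif counts with Gaussian noise", {
  spec <- synthetic_spec(n_sequences = 120, task_kind = "regression",
                         length_range = c(60L, 90L), noise_sd = 0.1, seed = 6)
  corp <- generate_corpus(spec)
  motif <- spec$motifs$motif[1]
  planted <- corp$labels$count
  # every planted copy is present as a substring occurrence
  found <- vapply(corp$records$sequence, function(s) {
    length(gregexpr(motif, s, fixed = TRUE)[[1]][gregexpr(motif, s, fixed = TRUE)[[1]] > 0])
  }, 0L)
  expect_true(all(found >= planted))
  expect_true(any(planted > 0))
  resid <- corp$labels$label - planted
  expect_lt(max(abs(resid)), 0.1 * 5)
  expect_gt(stats::sd(resid), 0.05)
})

test_that("multilabel corpora record exactly the planted motifs", {
  motifs <- tibble::tibble(class = 0:1, motif = c("DKLIVEQR", "WFYHNSTG"),
                           prob = c(0.6, 0.6))
  spec <- synthetic_spec(n_sequences = 80, motifs = motifs,
                         task_kind = "multilabel", seed = 7)
  corp <- generate_corpus(spec)
  for (i in seq_len(80)) {
    lab <- corp$labels$label[[i]]
    for (r in 1:2) {
      present <- grepl(motifs$motif[r], corp$records$sequence[i], fixed = TRUE)
      if ((r - 1L) %in% lab) expect_true(present)
    }
  }
})

test_that("built stores contain the defining teacher distributions", {
  tk <- tokenize_sequences(random_records(6, seed = 8))
  store <- build_test_store(tk, list(
    u = list(kind = "uniform"),
    o = list(kind = "oracle")), new_store_dir())
  u <- read_outputs(store, "u", tk$id[2])[[1]]
  expect_true(all(u$dists == 1 / 23))
  o <- read_outputs(store, "o", tk$id[2])[[1]]
  expect_equal(o$dists[cbind(seq_along(tk$tokens[[2]]), tk$tokens[[2]])],
               rep(1, tk$length[2]))
})

test_that("complementary motif teachers are closer to the oracle on their own class", {
  spec <- synthetic_spec(n_sequences = 40, task_kind = "binary", seed = 12)
  corp <- generate_corpus(spec)
  tk <- tokenize_sequences(corp$records)
  mt <- spec$motifs
  tA <- make_synthetic_teacher("motif", list(q = 0.9, motifs = mt$motif[1]))
  tB <- make_synthetic_teacher("motif", list(q = 0.9, motifs = mt$motif[2]))
  both <- make_synthetic_teacher("motif", list(q = 0.9, motifs = mt$motif))
  kl_to_oracle <- function(fn, ids) {
    mean(vapply(ids, function(i) {
      distill_loss(both(tk$tokens[[i]], tk$id[i])$dists,
                   fn(tk$tokens[[i]], tk$id[i])$dists)
    }, 0))
  }
  idxA <- which(corp$labels$label == 0)
  idxB <- which(corp$labels$label == 1)
  expect_lt(kl_to_oracle(tA, idxA), kl_to_oracle(tB, idxA))
  expect_lt(kl_to_oracle(tB, idxB), kl_to_oracle(tA, idxB))
})

test_that("the default planted-motif task is solvable by a bag-of-3-mers baseline", {
  skip_if_not_installed("glmnet")
  spec <- synthetic_spec(seed = 1)
  corp <- generate_corpus(spec)
  acc <- kmer_baseline_cv(corp$records, corp$labels, k = 3, seed = 1)
  expect_gte(acc, 0.95)
})
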