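#' Specification of a synthetic planted-motif corpus
#'
#' Generates toy protein corpora in which class identity is carried by a
#' planted motif: background residues are i.i.d. uniform over the 20
#' canonical amino acids and each sequence receives its class motif at a
#' random position with the stated insertion probability.
#'
#' The default class motifs share half of their residue composition and are
#' planted in sequences long enough that composition is a weak cue: a
#' bag-of-residues model sees only a faint signal, while an encoder that
#' detects the exact motif sees a strong one. This mirrors real benchmark
#' task families, whose classes differ partly — but not only — in
#' composition.
#'
#' @param n_sequences Number of sequences (default 200).
#' @param length_range Min and max sequence length, uniform (default
#'   `c(60, 100)` — desk scale).
#' @param motifs Tibble with columns `class` (integer, from 0), `motif`
#'   (string of canonical residues), `prob` (insertion probability). The
#'   default plants one of two length-8 motifs with probability 1.
#' @param task_kind `"binary"`, `"multiclass"`, `"multilabel"` or
#'   `"regression"`.
#' @param background_freqs Optional length-20 vector of residue frequencies
#'   for the background (alphabetical canonical order; normalized
#'   internally). `NULL` (default) uses the uniform composition, whose
#'   masked positions are incompressible; a skewed table gives the
#'   masked-LM objective learnable structure.
#' @param noise_sd Regression only: standard deviation of the Gaussian noise
#'   added to the motif count (default 0.1).
#' @param max_insertions Regression only: maximum motif insertions per
#'   sequence (count target; default 3).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 200L,
                           length_range = c(60L, 100L),
                           motifs = default_motifs(),
                           task_kind = c("binary", "multiclass", "multilabel",
                                         "regression"),
                           background_freqs = NULL,
                           noise_sd = 0.1, max_insertions = 3L, seed = 1L) {
  task_kind <- match.arg(task_kind)
  stopifnot(n_sequences >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            is.data.frame(motifs),
            all(c("class", "motif", "prob") %in% names(motifs)),
            all(motifs$prob >= 0 & motifs$prob <= 1))
  if (any(nchar(motifs$motif) >= length_range[1])) {
    stop("motifs must be shorter than the minimum sequence length", call. = FALSE)
  }
  ok <- vapply(strsplit(motifs$motif, ""), function(ch) {
    all(ch %in% aa_vocabulary()$tokens[1:20])
  }, TRUE)
  if (!all(ok)) stop("motifs must use canonical residues only", call. = FALSE)
  if (!is.null(background_freqs)) {
    stopifnot(length(background_freqs) == 20L, all(background_freqs > 0))
    background_freqs <- background_freqs / sum(background_freqs)
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         length_range = as.integer(length_range),
         motifs = tibble::as_tibble(motifs), task_kind = task_kind,
         background_freqs = background_freqs,
         noise_sd = noise_sd, max_insertions = as.integer(max_insertions),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default pair of class motifs
#'
#' Two length-8 motifs (`DKLIVEQR` and `ILDKWFYH`), inserted with probability
#' 1. They share half of their residues (D, K, L, I) in different order, so
#' residue composition separates the classes only weakly while exact-motif
#' detection separates them fully.
#'
#' @return A tibble with columns `class`, `motif`, `prob`.
#' @export
default_motifs <- function() {
  tibble::tibble(class = c(0L, 1L),
                 motif = c("DKLIVEQR", "ILDKWFYH"),
                 prob = c(1, 1))
}

random_background <- function(len, letters20, freqs = NULL) {
  paste(sample(letters20, len, replace = TRUE, prob = freqs), collapse = "")
}

# Overwrite a random window of the background with the motif, avoiding any
# previously planted window. Returns the sequence and the updated interval
# set; keeps sequence length unchanged.
plant_motif <- function(seq, motif, occupied) {
  L <- nchar(seq); m <- nchar(motif)
  for (try in seq_len(500L)) {
    start <- sample.int(L - m + 1L, 1L)
    stop_ <- start + m - 1L
    clash <- nrow(occupied) > 0L &&
      any(start <= occupied[, 2L] & stop_ >= occupied[, 1L])
    if (!clash) {
      substr(seq, start, stop_) <- motif
      return(list(seq = seq, occupied = rbind(occupied, c(start, stop_))))
    }
  }
  stop("could not place motif without overlap; sequence too short", call. = FALSE)
}

#' Generate a synthetic corpus with labels
#'
#' Backgrounds are i.i.d. over the canonical alphabet (uniform unless the
#' spec carries a frequency table); classes are balanced exactly (as equal
#' as the sequence count allows). Planted motifs overwrite a background
#' window, never overlapping one another, so sequence lengths stay as
#' drawn. Labels are
#' derived from the construction: the planted class for binary/multiclass,
#' motif presence for multilabel, motif count plus Gaussian noise for
#' regression.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `records` (tibble `id`, `sequence`) and `labels`
#'   (tibble `id`, `label`, plus `class` metadata where applicable).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  letters20 <- aa_vocabulary()$tokens[1:20]
  n <- spec$n_sequences
  lens <- if (spec$length_range[1] == spec$length_range[2]) {
    rep(spec$length_range[1], n)
  } else {
    sample(seq.int(spec$length_range[1], spec$length_range[2]), n,
           replace = TRUE)
  }
  ids <- sprintf("seq%04d", seq_len(n))
  seqs <- character(n)
  mt <- spec$motifs

  if (spec$task_kind %in% c("binary", "multiclass")) {
    classes <- sample(rep(mt$class, length.out = n))
    for (i in seq_len(n)) {
      s <- random_background(lens[i], letters20, spec$background_freqs)
      row <- which(mt$class == classes[i])
      if (stats::runif(1) < mt$prob[row]) {
        s <- plant_motif(s, mt$motif[row],
                         matrix(numeric(0), 0L, 2L))$seq
      }
      seqs[i] <- s
    }
    labels <- tibble::tibble(id = ids, label = as.integer(classes))
  } else if (spec$task_kind == "multilabel") {
    present <- matrix(FALSE, n, nrow(mt))
    for (i in seq_len(n)) {
      s <- random_background(lens[i], letters20, spec$background_freqs)
      occ <- matrix(numeric(0), 0L, 2L)
      for (r in seq_len(nrow(mt))) {
        if (stats::runif(1) < mt$prob[r]) {
          pl <- plant_motif(s, mt$motif[r], occ)
          s <- pl$seq; occ <- pl$occupied
          present[i, r] <- TRUE
        }
      }
      seqs[i] <- s
    }
    labels <- tibble::tibble(
      id = ids,
      label = lapply(seq_len(n), function(i) mt$class[present[i, ]]))
  } else {
    counts <- integer(n)
    for (i in seq_len(n)) {
      s <- random_background(lens[i], letters20, spec$background_freqs)
      kmax <- min(spec$max_insertions,
                  floor(lens[i] / (2L * nchar(mt$motif[1]))))
      ki <- stats::rbinom(1L, kmax, mt$prob[1])
      occ <- matrix(numeric(0), 0L, 2L)
      if (ki > 0L) {
        for (r in seq_len(ki)) {
          pl <- plant_motif(s, mt$motif[1], occ)
          s <- pl$seq; occ <- pl$occupied
        }
      }
      counts[i] <- ki
      seqs[i] <- s
    }
    labels <- tibble::tibble(
      id = ids, label = counts + stats::rnorm(n, sd = spec$noise_sd),
      count = counts)
  }
  list(records = tibble::tibble(id = ids, sequence = seqs), labels = labels)
}

#' Build a teacher store for a synthetic corpus
#'
#' Materializes synthetic-teacher outputs for every (teacher, sequence) pair
#' into a validated offline store.
#'
#' @param tokens Tokenized corpus ([tokenize_sequences()]).
#' @param teacher_specs Named list: teacher id -> list(kind = ..., params =
#'   list(...)) as accepted by [make_synthetic_teacher()].
#' @param path Directory for the store.
#' @param vocab Vocabulary.
#' @return An open `teacher_store`.
#' @export
build_test_store <- function(tokens, teacher_specs, path,
                             vocab = aa_vocabulary()) {
  stopifnot(is.list(teacher_specs), length(teacher_specs) >= 1L,
            !is.null(names(teacher_specs)))
  store <- teacher_store_create(path, names(teacher_specs), vocab)
  fns <- lapply(names(teacher_specs), function(tid) {
    sp <- teacher_specs[[tid]]
    make_synthetic_teacher(sp$kind, sp$params %||% list(), vocab,
                           teacher_id = tid)
  })
  names(fns) <- names(teacher_specs)
  export_teacher_outputs(store, tokens, fns)
  store
}

#' Bag-of-k-mers baseline on a labeled corpus
#'
#' A ridge-regularized logistic (multinomial) model on k-mer count features,
#' cross-validated — the reference establishing that a planted-motif
#' classification task is solvable before any embedding model is evaluated.
#'
#' @param records Tibble with `id`, `sequence`.
#' @param labels Tibble with `id`, `label` (class labels).
#' @param k k-mer length (default 3).
#' @param folds Number of CV folds (default 5).
#' @param seed Fold-shuffle seed.
#' @return Mean cross-validated accuracy (scalar).
#' @export
kmer_baseline_cv <- function(records, labels, k = 3L, folds = 5L, seed = 1L) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("kmer_baseline_cv requires the 'glmnet' package", call. = FALSE)
  }
  labels <- labels[match(records$id, labels$id), ]
  kmers <- lapply(records$sequence, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1L), k:L)
  })
  vocab_k <- sort(unique(unlist(kmers)))
  X <- matrix(0, nrow(records), length(vocab_k),
              dimnames = list(records$id, vocab_k))
  for (i in seq_along(kmers)) {
    tb <- table(kmers[[i]])
    X[i, names(tb)] <- as.numeric(tb)
  }
  y <- factor(labels$label)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = nrow(X)))
  acc <- vapply(seq_len(folds), function(f) {
    fit <- glmnet::glmnet(X[fold != f, , drop = FALSE], y[fold != f],
                          family = if (nlevels(y) > 2L) "multinomial" else "binomial",
                          alpha = 0, lambda = 0.01)
    pred <- stats::predict(fit, X[fold == f, , drop = FALSE], type = "class")
    mean(pred == as.character(y[fold == f]))
  }, 0)
  mean(acc)
}
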