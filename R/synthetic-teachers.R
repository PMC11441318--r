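#' Construct a synthetic teacher
#'
#' Synthetic teachers stand in for large pre-trained protein language models
#' when exercising the distillation machinery. Each returned teacher is a
#' pure function `(token vector, sequence id) -> teacher_output`:
#'
#' * `"oracle"`: probability `q` (default 1) on the true token at every
#'   position, the remaining mass spread uniformly over the other `V - 1`
#'   symbols.
#' * `"noisy_oracle"`: the same with `q < 1` required (`q` in `(1/V, 1]`) —
#'   a teacher of controllable quality.
#' * `"uniform"`: `1/V` everywhere; a completely uninformative teacher.
#' * `"motif"`: oracle-like (confidence `q`) at positions lying inside any
#'   occurrence of its declared motifs, uniform elsewhere — a teacher that is
#'   only knowledgeable about part of sequence space. With zero declared
#'   motifs it equals the uniform teacher exactly.
#'
#' @param kind One of `"oracle"`, `"uniform"`, `"motif"`, `"noisy_oracle"`.
#' @param params List of kind-specific parameters: `q` (confidence), `motifs`
#'   (character vector, motif kind only), `embed_dim` (optional; when set the
#'   teacher also emits per-position embeddings: a fixed random linear code of
#'   the true token, seeded by `embed_seed`, default 1).
#' @param vocab An `aa_vocab`.
#' @param teacher_id Id recorded in emitted outputs (defaults to `kind`).
#' @return A function `(tokens, sequence_id) -> teacher_output`.
#' @export
make_synthetic_teacher <- function(kind = c("oracle", "uniform", "motif", "noisy_oracle"),
                                   params = list(), vocab = aa_vocabulary(),
                                   teacher_id = NULL) {
  kind <- match.arg(kind)
  if (is.null(teacher_id)) teacher_id <- kind
  V <- vocab$size
  q <- params$q
  if (is.null(q)) q <- if (kind == "uniform") NA_real_ else 1
  if (kind %in% c("oracle", "noisy_oracle", "motif")) {
    lo <- if (kind == "noisy_oracle") 1 / V else 0
    if (!is.numeric(q) || q <= lo || q > 1) {
      stop("confidence `q` must be in (", format(lo), ", 1]", call. = FALSE)
    }
  }
  motifs <- params$motifs
  if (kind == "motif" && is.null(motifs)) motifs <- character()
  emb_code <- NULL
  if (!is.null(params$embed_dim)) {
    seed <- if (is.null(params$embed_seed)) 1L else params$embed_seed
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    emb_code <- matrix(stats::rnorm(V * params$embed_dim), V, params$embed_dim)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  oracle_rows <- function(tokens, conf) {
    d <- matrix((1 - conf) / (V - 1), length(tokens), V)
    d[cbind(seq_along(tokens), tokens)] <- conf
    d
  }

  function(tokens, sequence_id) {
    tokens <- as.integer(tokens)
    N <- length(tokens)
    d <- switch(kind,
      uniform = matrix(1 / V, N, V),
      oracle = ,
      noisy_oracle = oracle_rows(tokens, q),
      motif = {
        m <- matrix(1 / V, N, V)
        inside <- motif_positions(tokens, motifs, vocab)
        if (length(inside) > 0L) {
          m[inside, ] <- oracle_rows(tokens[inside], q)
        }
        m
      })
    emb <- if (!is.null(emb_code)) emb_code[tokens, , drop = FALSE]
    teacher_output(teacher_id, sequence_id, d, embedding = emb)
  }
}

# 1-based positions covered by any occurrence of any motif in the detokenized
# sequence (mask/pad positions never match since motifs are canonical letters).
motif_positions <- function(tokens, motifs, vocab) {
  if (length(motifs) == 0L) return(integer())
  letters_out <- vocab$tokens
  letters_out[vocab$unk] <- "X"
  letters_out[c(vocab$mask, vocab$pad)] <- c("#", "@")
  s <- paste(letters_out[tokens], collapse = "")
  pos <- integer()
  for (m in motifs) {
    hits <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (h in hits) pos <- c(pos, h:(h + nchar(m) - 1L))
    }
  }
  sort(unique(pos))
}

#' Fill a teacher store from teacher functions
#'
#' Runs each teacher function over every tokenized sequence and writes the
#' outputs, yielding a validated offline store.
#'
#' @param store A `teacher_store` (with matching teacher ids).
#' @param tokens A tibble from [tokenize_sequences()].
#' @param teacher_fns Named list of teacher functions (names = teacher ids).
#' @return The store, invisibly.
#' @export
export_teacher_outputs <- function(store, tokens, teacher_fns) {
  stopifnot(inherits(store, "teacher_store"), is.list(teacher_fns))
  if (is.null(names(teacher_fns)) || any(!nzchar(names(teacher_fns)))) {
    stop("`teacher_fns` must be a named list", call. = FALSE)
  }
  for (tid in names(teacher_fns)) {
    fn <- teacher_fns[[tid]]
    outs <- lapply(seq_len(nrow(tokens)), function(i) {
      o <- fn(tokens$tokens[[i]], tokens$id[[i]])
      o$teacher_id <- tid
      o
    })
    write_outputs(store, outs)
  }
  invisible(store)
}
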