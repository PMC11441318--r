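#' Apply masked-language-model corruption to tokenized sequences
#'
#' Under the default `"token"` scheme each position is independently selected
#' with probability `rate` (so per-sequence masked counts are Binomial(N,
#' rate)); selected positions are replaced by the mask token and their
#' original indices are recorded as prediction targets. The `"span"` scheme
#' instead corrupts contiguous spans whose lengths are geometric with mean 3,
#' calibrated so the expected masked fraction still equals `rate`.
#'
#' By default selected positions are always replaced by the mask token (the
#' minimal reading of a mask-and-predict objective). The common BERT-style
#' 80/10/10 replace/random/keep convention is available via
#' `corruption = "bert"`.
#'
#' @param tokens A tibble from [tokenize_sequences()] (columns `id`, `tokens`).
#' @param rate Masking probability in \[0, 1\] (default 0.15).
#' @param vocab The `aa_vocab` the tokens were produced with.
#' @param scheme `"token"` (independent positions) or `"span"`.
#' @param corruption `"mask"` (always replace with mask token) or `"bert"`
#'   (80% mask, 10% random canonical token, 10% kept).
#' @param seed Optional integer; when supplied, masking is a pure function of
#'   (input, seed). When `NULL`, the current RNG stream is used.
#' @return A tibble of class `masked_batch` with columns `id`, `tokens`
#'   (corrupted), `mask_pos` (list of strictly increasing 1-based positions),
#'   and `targets` (list of original token indices at those positions).
#' @export
apply_mask <- function(tokens, rate = 0.15, vocab = aa_vocabulary(),
                       scheme = c("token", "span"),
                       corruption = c("mask", "bert"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  corruption <- match.arg(corruption)
  stopifnot(is.data.frame(tokens), all(c("id", "tokens") %in% names(tokens)))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop("`rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (nrow(tokens) == 0L) stop("no sequences to mask", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  n <- nrow(tokens)
  out_tokens <- vector("list", n)
  out_pos <- vector("list", n)
  out_tgt <- vector("list", n)
  for (i in seq_len(n)) {
    tk <- tokens$tokens[[i]]
    N <- length(tk)
    sel <- if (scheme == "token") {
      which(stats::runif(N) < rate)
    } else {
      span_positions(N, rate)
    }
    out_pos[[i]] <- sel
    out_tgt[[i]] <- tk[sel]
    if (length(sel) > 0L) {
      if (corruption == "mask") {
        tk[sel] <- vocab$mask
      } else {
        u <- stats::runif(length(sel))
        to_mask <- u < 0.8
        to_rand <- u >= 0.8 & u < 0.9
        tk[sel[to_mask]] <- vocab$mask
        if (any(to_rand)) {
          tk[sel[to_rand]] <- sample(vocab$canonical, sum(to_rand), replace = TRUE)
        }
        # remaining 10%: kept unchanged but still scored
      }
    }
    out_tokens[[i]] <- tk
  }
  structure(
    tibble::tibble(id = tokens$id, tokens = out_tokens,
                   mask_pos = out_pos, targets = out_tgt),
    class = c("masked_batch", class(tibble::tibble()))
  )
}

# Span-corruption position sampler: span lengths are 1 + Geometric(1/mean_len)
# (mean = mean_len); span starts occur at rate -log(1 - rate) / mean_len per
# position, which makes the stationary union coverage equal the target rate
# (overlapping spans count positions once), up to edge effects.
span_positions <- function(N, rate, mean_len = 3) {
  if (rate >= 1) return(seq_len(N))
  starts <- which(stats::runif(N) < -log(1 - rate) / mean_len)
  if (length(starts) == 0L) return(integer())
  lens <- 1L + stats::rgeom(length(starts), prob = 1 / mean_len)
  sel <- unlist(mapply(function(s, l) s:min(N, s + l - 1L), starts, lens,
                       SIMPLIFY = FALSE))
  sort(unique(sel))
}

#' Undo masking
#'
#' Writes the recorded targets back at the masked positions, recovering the
#' original token sequences exactly.
#'
#' @param masked A `masked_batch` from [apply_mask()].
#' @return A tibble with columns `id`, `tokens` (restored), `length`.
#' @export
restore_mask <- function(masked) {
  stopifnot(inherits(masked, "masked_batch"))
  toks <- vector("list", nrow(masked))
  for (i in seq_len(nrow(masked))) {
    tk <- masked$tokens[[i]]
    tk[masked$mask_pos[[i]]] <- masked$targets[[i]]
    toks[[i]] <- tk
  }
  tibble::tibble(id = masked$id, tokens = toks, length = lengths(toks))
}
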