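#' Amino-acid vocabulary
#'
#' The default vocabulary used throughout the package: the 20 canonical amino
#' acids in alphabetical one-letter order, followed by an unknown symbol (to
#' which ambiguity codes such as B, J, O, U, X, Z map), a mask symbol used by
#' the masked-language-modeling objective, and a pad symbol. Size `V = 23`.
#'
#' Token indices are 1-based, following R convention; reports and logs also
#' use 1-based sequence positions.
#'
#' @return An object of class `aa_vocab`: a list with elements `tokens`
#'   (character vector of length `V`), `size`, and the special indices `unk`,
#'   `mask`, `pad`, plus `canonical` (indices of the 20 canonical residues).
#' @examples
#' v <- aa_vocabulary()
#' v$size
#' v$tokens[v$mask]
#' @export
aa_vocabulary <- function() {
  canonical <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  tokens <- c(canonical, "<unk>", "<mask>", "<pad>")
  structure(
    list(
      tokens = tokens,
      size = length(tokens),
      unk = 21L,
      mask = 22L,
      pad = 23L,
      canonical = seq_len(20L)
    ),
    class = "aa_vocab"
  )
}

#' @export
print.aa_vocab <- function(x, ...) {
  cat("<aa_vocab> V =", x$size, "\n")
  cat("  tokens:", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Hash of a vocabulary
#'
#' A short stable fingerprint of the token ordering, stored in checkpoints and
#' teacher stores so that models and teacher outputs are never combined across
#' incompatible vocabularies.
#'
#' @param vocab An `aa_vocab` object.
#' @return A single character string.
#' @keywords internal
vocab_hash <- function(vocab) {
  paste0("V", vocab$size, ":", paste(vocab$tokens, collapse = ""))
}

# Lookup table letter -> index under a vocabulary; non-canonical A-Z letters
# map to the unknown index.
vocab_lookup <- function(vocab) {
  lut <- rep(vocab$unk, 26L)
  names(lut) <- LETTERS
  for (i in vocab$canonical) lut[vocab$tokens[i]] <- i
  lut
}

#' Tokenize protein records
#'
#' Maps each sequence to a vector of vocabulary indices, truncating to the
#' first `max_length` residues (1000 by default, matching the convention of
#' keeping only the first 1000 amino acids of long proteins). Non-canonical
#' letters (B, J, O, U, X, Z) map to the unknown token. The pre-truncation
#' length is retained so clipping is auditable.
#'
#' @param records A data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param vocab An `aa_vocab`; defaults to [aa_vocabulary()].
#' @param max_length Maximum number of residues kept per sequence (default
#'   1000).
#' @return A tibble with columns `id`, `tokens` (list column of integer
#'   vectors), `length` (post-truncation), and `original_length`.
#' @examples
#' recs <- tibble::tibble(id = "p1", sequence = "ACDE")
#' tokenize_sequences(recs)
#' @export
tokenize_sequences <- function(records, vocab = aa_vocabulary(), max_length = 1000L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (max_length < 1) stop("`max_length` must be >= 1", call. = FALSE)
  lut <- vocab_lookup(vocab)
  toks <- vector("list", nrow(records))
  orig_len <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !chars %in% LETTERS
    if (any(bad)) {
      stop("sequence '", records$id[[i]], "' contains non-letter character(s): ",
           paste(unique(chars[bad]), collapse = " "), call. = FALSE)
    }
    orig_len[i] <- length(chars)
    if (length(chars) > max_length) chars <- chars[seq_len(max_length)]
    toks[[i]] <- unname(lut[chars])
  }
  tibble::tibble(
    id = records$id,
    tokens = toks,
    length = lengths(toks),
    original_length = orig_len
  )
}

#' Reconstruct a sequence string from token indices
#'
#' Inverse of tokenization on canonical sequences (up to truncation). Refuses
#' sequences containing mask or pad tokens, which have no residue meaning.
#'
#' @param tokens Integer vector of vocabulary indices.
#' @param vocab An `aa_vocab`.
#' @return A single string of amino-acid letters (unknown tokens render as
#'   `"X"`).
#' @export
detokenize <- function(tokens, vocab = aa_vocabulary()) {
  stopifnot(is.numeric(tokens))
  tokens <- as.integer(tokens)
  if (any(tokens < 1L | tokens > vocab$size)) {
    stop("token index out of range [1, ", vocab$size, "]", call. = FALSE)
  }
  if (any(tokens %in% c(vocab$mask, vocab$pad))) {
    stop("cannot detokenize: mask or pad token present", call. = FALSE)
  }
  letters_out <- vocab$tokens
  letters_out[vocab$unk] <- "X"
  paste(letters_out[tokens], collapse = "")
}
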