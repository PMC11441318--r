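#' Read protein records from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file of amino-acid sequences. The
#' record id is the first whitespace-delimited token of the header; sequences
#' are uppercased and whitespace-stripped. Entry order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACDE", ">b", "pqr"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("malformed FASTA header: empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
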