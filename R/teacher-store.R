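#' Create an offline teacher-output store
#'
#' The offline-training substrate: teacher models are run once over the
#' corpus and their per-position output distributions (and optionally
#' per-position embeddings) are persisted; during student pre-training the
#' teachers never run. The container is a directory holding a JSON manifest
#' (teacher ids, vocabulary, storage precision) and one binary record per
#' `(teacher_id, sequence_id)` key, so every key is either fully present or
#' absent — no partial records.
#'
#' @param path Directory to create (must not already contain a store).
#' @param teachers Character vector of teacher ids.
#' @param vocab The `aa_vocab` all stored distributions are expressed in.
#' @return A `teacher_store` handle.
#' @export
teacher_store_create <- function(path, teachers, vocab = aa_vocabulary()) {
  stopifnot(is.character(teachers), length(teachers) >= 1L)
  if (file.exists(file.path(path, "manifest.json"))) {
    stop("a teacher store already exists at ", path, call. = FALSE)
  }
  dir.create(file.path(path, "records"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "protdistill-teacher-store",
    version = 1L,
    teachers = as.list(teachers),
    vocab = as.list(vocab$tokens),
    dtype = "float64",
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (t in teachers) {
    dir.create(file.path(path, "records", store_key(t)), showWarnings = FALSE)
  }
  teacher_store_open(path)
}

#' Open an existing teacher store
#'
#' @param path Store directory.
#' @return A `teacher_store` handle: list with `path`, `teachers`, `vocab`
#'   tokens and an in-memory read cache.
#' @export
teacher_store_open <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no teacher store at ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  structure(
    list(path = path,
         teachers = as.character(manifest$teachers),
         vocab_tokens = as.character(manifest$vocab),
         cache = new.env(parent = emptyenv())),
    class = "teacher_store"
  )
}

#' @export
print.teacher_store <- function(x, ...) {
  n <- length(store_sequence_ids(x, x$teachers[[1]]))
  cat("<teacher_store>", x$path, "\n  teachers:",
      paste(x$teachers, collapse = ", "), "\n  sequences (first teacher):",
      n, "\n")
  invisible(x)
}

# Filesystem-safe key for ids.
store_key <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

record_path <- function(store, teacher_id, sequence_id) {
  file.path(store$path, "records", store_key(teacher_id),
            paste0(store_key(sequence_id), ".rds"))
}

#' Construct a teacher output record
#'
#' @param teacher_id,sequence_id Identifiers.
#' @param dists `N x V` row-stochastic matrix of per-position distributions.
#' @param embedding Optional `N x d_T` embedding matrix.
#' @return A `teacher_output` list.
#' @export
teacher_output <- function(teacher_id, sequence_id, dists, embedding = NULL) {
  structure(list(teacher_id = teacher_id, sequence_id = sequence_id,
                 dists = dists, embedding = embedding),
            class = "teacher_output")
}

validate_teacher_output <- function(out, V, tol = 1e-6) {
  if (!inherits(out, "teacher_output")) stop("not a teacher_output", call. = FALSE)
  d <- out$dists
  if (!is.matrix(d) || ncol(d) != V) {
    stop("teacher output for '", out$sequence_id, "' has ", ncol(d),
         " columns; vocabulary size is ", V, call. = FALSE)
  }
  rs <- rowSums(d)
  if (any(abs(rs - 1) > tol) || any(d < 0)) {
    stop("teacher output for (", out$teacher_id, ", ", out$sequence_id,
         ") is not row-stochastic (worst row sum ", format(rs[which.max(abs(rs - 1))]),
         ")", call. = FALSE)
  }
  if (!is.null(out$embedding) && nrow(out$embedding) != nrow(d)) {
    stop("embedding rows do not match sequence length", call. = FALSE)
  }
  invisible(out)
}

#' Write teacher outputs to a store
#'
#' Validates each record (known teacher, row-stochastic distributions,
#' no duplicate keys) and persists it. Read-after-write returns numerically
#' identical arrays.
#'
#' @param store A `teacher_store`.
#' @param outputs A list of [teacher_output()] records.
#' @return The store, invisibly.
#' @export
write_outputs <- function(store, outputs) {
  stopifnot(inherits(store, "teacher_store"))
  if (inherits(outputs, "teacher_output")) outputs <- list(outputs)
  V <- length(store$vocab_tokens)
  for (out in outputs) {
    if (!out$teacher_id %in% store$teachers) {
      stop("unknown teacher id '", out$teacher_id, "'", call. = FALSE)
    }
    validate_teacher_output(out, V)
    p <- record_path(store, out$teacher_id, out$sequence_id)
    if (file.exists(p)) {
      stop("duplicate record for (", out$teacher_id, ", ", out$sequence_id, ")",
           call. = FALSE)
    }
    saveRDS(out, p)
  }
  invisible(store)
}

#' Read teacher outputs from a store
#'
#' @param store A `teacher_store`.
#' @param teacher_id One teacher id.
#' @param sequence_ids Character vector of sequence ids; records are returned
#'   in request order.
#' @return A list of `teacher_output` records.
#' @export
read_outputs <- function(store, teacher_id, sequence_ids) {
  stopifnot(inherits(store, "teacher_store"))
  if (!teacher_id %in% store$teachers) {
    stop("unknown teacher id '", teacher_id, "'", call. = FALSE)
  }
  lapply(sequence_ids, function(sid) {
    key <- paste0(store_key(teacher_id), "/", store_key(sid))
    rec <- store$cache[[key]]
    if (is.null(rec)) {
      p <- record_path(store, teacher_id, sid)
      if (!file.exists(p)) {
        stop("no stored output for teacher '", teacher_id,
             "', sequence '", sid, "'", call. = FALSE)
      }
      rec <- readRDS(p)
      store$cache[[key]] <- rec
    }
    rec
  })
}

#' Sequence ids present in a store for one teacher
#'
#' @param store A `teacher_store`.
#' @param teacher_id One teacher id.
#' @return Character vector of (filesystem-keyed) sequence ids.
#' @export
store_sequence_ids <- function(store, teacher_id) {
  sub("\\.rds$", "",
      list.files(file.path(store$path, "records", store_key(teacher_id))))
}

# Check that every (teacher, sequence) pair needed for a run is resolvable.
store_preflight <- function(store, sequence_ids, teachers = store$teachers) {
  for (t in teachers) {
    have <- store_sequence_ids(store, t)
    miss <- setdiff(store_key(sequence_ids), have)
    if (length(miss) > 0L) {
      stop("teacher store is missing ", length(miss), " record(s) for teacher '",
           t, "' (e.g. ", miss[[1]], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}
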