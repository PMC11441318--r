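#' Loss configuration
#'
#' Controls the joint pre-training objective
#' `L = alpha * L_MLM + (1 - alpha) * L_Distill`. The default mixing weight
#' `alpha = 0.2` is the value found to perform best, giving the distillation
#' term the larger share. Both component losses are means over their scored
#' positions, so the trade-off set by `alpha` does not drift with sequence
#' length or batch size.
#'
#' @param alpha Mixing weight in \[0, 1\] (default 0.2).
#' @param distill_positions Positions scored by the distillation loss:
#'   `"all"` (default) or `"masked_only"`.
#' @param mlm_positions Positions scored by the masked-LM loss:
#'   `"masked_only"` (default, standard MLM) or `"all"`.
#' @param distill_space `"distribution"` (default): KL divergence between
#'   per-position output distributions; or `"embedding"`: mean squared error
#'   between teacher embeddings and linearly projected student hidden states.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.2,
                        distill_positions = c("all", "masked_only"),
                        mlm_positions = c("masked_only", "all"),
                        distill_space = c("distribution", "embedding")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(alpha = alpha,
         distill_positions = match.arg(distill_positions),
         mlm_positions = match.arg(mlm_positions),
         distill_space = match.arg(distill_space)),
    class = "loss_config"
  )
}

#' Masked-language-modeling loss
#'
#' The negative log-likelihood of the original residues under the student's
#' per-position output distributions, averaged over the scored positions
#' (the masked positions by default).
#'
#' @param dists `N x V` row-stochastic matrix of student distributions,
#'   computed on the corrupted tokens.
#' @param mask_pos Integer vector of 1-based masked positions.
#' @param targets Integer vector of original token indices at those
#'   positions.
#' @param positions `"masked_only"` (default) or `"all"`; under `"all"`,
#'   every position is scored against `all_targets`.
#' @param all_targets Original (uncorrupted) token vector, required when
#'   `positions = "all"`.
#' @return A single non-negative number.
#' @export
mlm_loss <- function(dists, mask_pos, targets,
                     positions = c("masked_only", "all"), all_targets = NULL) {
  positions <- match.arg(positions)
  if (positions == "all") {
    if (is.null(all_targets)) stop("`all_targets` required when positions = 'all'")
    mask_pos <- seq_len(nrow(dists))
    targets <- all_targets
  }
  if (length(mask_pos) == 0L) {
    stop("masked-LM loss undefined with zero scored positions", call. = FALSE)
  }
  stopifnot(length(mask_pos) == length(targets))
  p <- dists[cbind(mask_pos, targets)]
  -mean(log(p))
}

# Gradient of mlm_loss w.r.t. the logits (softmax + NLL shortcut).
mlm_loss_grad <- function(dists, mask_pos, targets) {
  dlog <- matrix(0, nrow(dists), ncol(dists))
  n <- length(mask_pos)
  dlog[mask_pos, ] <- dists[mask_pos, , drop = FALSE] / n
  dlog[cbind(mask_pos, targets)] <- dlog[cbind(mask_pos, targets)] - 1 / n
  dlog
}

#' Kullback-Leibler distillation loss
#'
#' `mean over positions of KL(p_T || p_S) = sum_j p_T (ln p_T - ln p_S)`,
#' with the convention `0 * ln 0 = 0`. The direction is teacher-to-student:
#' the student is penalized wherever it fails to cover the teacher's mass.
#' If the student assigns zero probability where the teacher does not, the
#' result is `+Inf` (softmax outputs avoid this in practice).
#'
#' @param teacher `N x V` row-stochastic matrix of teacher distributions.
#' @param student `N x V` row-stochastic matrix of student distributions.
#' @param positions Integer vector of scored positions (default: all rows).
#' @return A single non-negative number (possibly `Inf`).
#' @export
distill_loss <- function(teacher, student, positions = seq_len(nrow(teacher))) {
  stopifnot(all(dim(teacher) == dim(student)))
  if (length(positions) == 0L) stop("no positions to score", call. = FALSE)
  tt <- teacher[positions, , drop = FALSE]
  ss <- student[positions, , drop = FALSE]
  pos <- tt > 0
  term <- matrix(0, nrow(tt), ncol(tt))
  term[pos] <- tt[pos] * (log(tt[pos]) - log(ss[pos]))
  mean(rowSums(term))
}

# Gradient of distill_loss w.r.t. the student logits: (p_S - p_T) / n at
# scored positions (softmax + KL shortcut).
distill_loss_grad <- function(teacher, student, positions = seq_len(nrow(teacher))) {
  dlog <- matrix(0, nrow(student), ncol(student))
  n <- length(positions)
  dlog[positions, ] <- (student[positions, , drop = FALSE] -
                          teacher[positions, , drop = FALSE]) / n
  dlog
}

#' Embedding-space distillation loss
#'
#' The optional alternative reading of the distillation objective: mean
#' squared error between the teacher's per-position embedding vectors and the
#' student hidden states passed through a learned linear projection
#' (`d -> d_T`), averaged over positions and embedding dimensions.
#'
#' @param teacher_emb `N x d_T` teacher embedding matrix.
#' @param hidden `N x d` student hidden states.
#' @param proj `d x d_T` projection matrix.
#' @return A list with `loss`, `dhidden` (`N x d`) and `dproj` (`d x d_T`)
#'   gradients.
#' @export
distill_loss_embedding <- function(teacher_emb, hidden, proj) {
  stopifnot(nrow(teacher_emb) == nrow(hidden), ncol(hidden) == nrow(proj),
            ncol(teacher_emb) == ncol(proj))
  pred <- hidden %*% proj
  resid <- pred - teacher_emb
  n <- length(resid)
  list(loss = sum(resid * resid) / n,
       dhidden = (2 / n) * resid %*% t(proj),
       dproj = (2 / n) * crossprod(hidden, resid))
}

#' Combine the masked-LM and distillation losses
#'
#' `L = alpha * L_MLM + (1 - alpha) * L_Distill`.
#'
#' @param l_mlm Masked-LM loss value.
#' @param l_distill Distillation loss value.
#' @param config A [loss_config()].
#' @param n_masked Optional count of masked positions, carried through to the
#'   report.
#' @param per_teacher Optional named vector of per-teacher distillation
#'   losses, carried through to the report.
#' @return A one-row tibble of class `loss_report` with columns `l_mlm`,
#'   `l_distill`, `l_total`, `alpha`, `n_masked`, and a `per_teacher` list
#'   column.
#' @examples
#' combined_loss(1.0, 0.5, loss_config(alpha = 0.2))$l_total  # 0.6
#' @export
combined_loss <- function(l_mlm, l_distill, config = loss_config(),
                          n_masked = NA_integer_, per_teacher = NULL) {
  stopifnot(is.finite(l_mlm), is.finite(l_distill))
  a <- config$alpha
  structure(
    tibble::tibble(
      l_mlm = l_mlm, l_distill = l_distill,
      l_total = a * l_mlm + (1 - a) * l_distill,
      alpha = a, n_masked = n_masked,
      per_teacher = list(per_teacher)
    ),
    class = c("loss_report", class(tibble::tibble()))
  )
}
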