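#' Initialize the teacher-selection policy
#'
#' The per-instance adaptive teacher selector. Each teacher `k` owns a
#' logistic unit over an instance feature vector `f_k`: raw weight
#' `s_k = logistic(w_k' f_k + b_k)`. The raw weights are normalized to a
#' probability vector from which the supervising teacher is sampled; a
#' REINFORCE update with an exponential-moving-average reward baseline
#' adapts the parameters.
#'
#' With all parameters at zero (the initial state) every raw weight is 0.5,
#' so the normalized weights start uniform.
#'
#' @param n_teachers Number of teachers `K` (>= 1).
#' @param feat_dim Feature dimension (fixed at construction).
#' @param baseline_decay EMA decay for the reward baseline (default 0.9).
#' @return A `policy_state` list: `W` (`K x feat_dim`), `b` (`K`),
#'   `baseline`, `baseline_init`, `step`.
#' @export
policy_init <- function(n_teachers, feat_dim, baseline_decay = 0.9) {
  stopifnot(n_teachers >= 1L, feat_dim >= 1L)
  structure(
    list(W = matrix(0, n_teachers, feat_dim), b = rep(0, n_teachers),
         baseline = 0, adv_sq = 0, baseline_init = FALSE,
         baseline_decay = baseline_decay, step = 0L),
    class = "policy_state"
  )
}

#' Featurize an instance for teacher selection
#'
#' Builds one feature vector per teacher from the three ingredient families
#' the selector conditions on: the input representation (mean-pooled student
#' hidden states), summaries of each teacher's predictions (mean entropy and
#' mean maximum probability of its per-position distributions), and each
#' teacher's current distillation loss on the instance.
#'
#' @param hidden `N x d` student hidden states for the instance.
#' @param teacher_dists List (length `K`) of `N x V` teacher distribution
#'   matrices.
#' @param teacher_losses Numeric vector (length `K`) of current per-teacher
#'   distillation losses.
#' @return A `K x (d + 4)` feature matrix (one row per teacher): the pooled
#'   representation, the teacher's mean prediction entropy and mean maximum
#'   probability, its distillation loss, and its loss relative to the mean
#'   over teachers (the instance-level routing signal).
#' @export
policy_features <- function(hidden, teacher_dists, teacher_losses) {
  K <- length(teacher_dists)
  stopifnot(length(teacher_losses) == K)
  pooled <- colMeans(hidden)
  lbar <- mean(teacher_losses)
  t(vapply(seq_len(K), function(k) {
    d <- teacher_dists[[k]]
    ent <- mean(-rowSums(ifelse(d > 0, d * log(d), 0)))
    mx <- mean(apply(d, 1L, max))
    c(pooled, ent, mx, teacher_losses[[k]], teacher_losses[[k]] - lbar)
  }, numeric(length(pooled) + 4L)))
}

#' Per-teacher selection weights
#'
#' @param state A `policy_state`.
#' @param feats `K x feat_dim` feature matrix from [policy_features()].
#' @return A list with `raw` (independent logistic outputs in (0,1)) and
#'   `prob` (raw weights normalized to sum to 1).
#' @export
teacher_weights <- function(state, feats) {
  stopifnot(inherits(state, "policy_state"))
  if (!is.matrix(feats)) feats <- matrix(feats, nrow = nrow(state$W), byrow = TRUE)
  if (ncol(feats) != ncol(state$W) || nrow(feats) != nrow(state$W)) {
    stop("feature dimensions (", nrow(feats), " x ", ncol(feats),
         ") do not match policy (", nrow(state$W), " x ", ncol(state$W), ")",
         call. = FALSE)
  }
  z <- rowSums(state$W * feats) + state$b
  s <- stats::plogis(z)
  list(raw = s, prob = s / sum(s))
}

#' Sample a teacher index from normalized weights
#'
#' @param prob Probability vector over teachers (must sum to 1).
#' @param floor Optional exploration floor: probabilities are clipped to at
#'   least `floor` and renormalized before sampling (default 0, no floor).
#' @return A single teacher index.
#' @export
sample_teacher <- function(prob, floor = 0) {
  if (abs(sum(prob) - 1) > 1e-8 || any(prob < 0)) {
    stop("`prob` must be a normalized probability vector", call. = FALSE)
  }
  if (floor > 0) {
    prob <- pmax(prob, floor)
    prob <- prob / sum(prob)
  }
  if (length(prob) == 1L) return(1L)
  sample.int(length(prob), 1L, prob = prob)
}

#' REINFORCE update of the policy
#'
#' Moves the chosen teacher's logistic parameters along the gradient of the
#' log normalized weight of the chosen teacher, scaled by
#' `lr * advantage`, where the advantage is the reward minus an exponential
#' moving-average baseline (decay 0.9), divided by a running estimate of the
#' advantage scale (an EMA of squared advantages) so the update size is
#' invariant to the numerical scale of the reward. A zero advantage or
#' `lr = 0` leaves the parameters unchanged.
#'
#' @param state A `policy_state`.
#' @param feats The `K x feat_dim` feature matrix used for the decision.
#' @param chosen Index of the sampled teacher.
#' @param reward Scalar reward (improvement in the student objective).
#' @param lr Policy learning rate.
#' @return The updated `policy_state`.
#' @export
policy_update <- function(state, feats, chosen, reward, lr) {
  stopifnot(is.finite(reward))
  w <- teacher_weights(state, feats)
  s <- w$raw
  baseline <- if (state$baseline_init) state$baseline else reward
  adv <- reward - baseline
  scale <- sqrt(state$adv_sq)
  adv_n <- if (scale > 0) adv / scale else adv
  # d log p_c / d z_c with p_c = s_c / sum(s), s = logistic(z):
  gz <- (1 - s[chosen]) * (1 - s[chosen] / sum(s))
  state$W[chosen, ] <- state$W[chosen, ] + lr * adv_n * gz * feats[chosen, ]
  state$b[chosen] <- state$b[chosen] + lr * adv_n * gz
  dec <- state$baseline_decay
  state$baseline <- dec * baseline + (1 - dec) * reward
  state$adv_sq <- dec * state$adv_sq + (1 - dec) * adv^2
  state$baseline_init <- TRUE
  state$step <- state$step + 1L
  state
}
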