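`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pre-training configuration
#'
#' Optimization schedule for distillation pre-training. Defaults follow the
#' published recipe: AdamW at a base learning rate of 3e-4, ten epochs, batch
#' size 16, linear warm-up over the first 10% of steps, and a 15% masking
#' probability. The learning rate decays linearly to zero after warm-up.
#'
#' @param epochs Number of passes over the corpus (default 10).
#' @param batch_size Sequences per optimizer step (default 16).
#' @param base_lr Peak learning rate (default 3e-4).
#' @param warmup_ratio Fraction of total steps spent warming up (default 0.1).
#' @param mask_rate Masking probability (default 0.15).
#' @param mask_scheme `"token"` or `"span"` (see [apply_mask()]).
#' @param loss A [loss_config()].
#' @param seed Integer seed controlling every random choice of the run.
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param policy_lr Learning rate of the REINFORCE teacher-selection policy.
#' @param exploration_floor Minimum per-teacher sampling probability during
#'   training (default 0.02), preventing premature teacher starvation.
#' @param reward Reward signal for the policy: `"instance"` (default;
#'   improvement of the instance's combined loss across the update) or
#'   `"validation"` (decrease of the masked-LM loss on a fixed validation
#'   batch — a teacher-independent measure of student quality; requires a
#'   validation set).
#' @param selection `"sample"` (default; one teacher sampled per instance) or
#'   `"mixture"` (distillation loss averaged over teachers under the current
#'   policy weights; the policy is not updated in this mode).
#' @return An object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 10L, batch_size = 16L, base_lr = 3e-4,
                            warmup_ratio = 0.1, mask_rate = 0.15,
                            mask_scheme = c("token", "span"),
                            loss = loss_config(), seed = 1L,
                            weight_decay = 0.01, policy_lr = 0.03,
                            exploration_floor = 0.02,
                            reward = c("instance", "validation"),
                            selection = c("sample", "mixture")) {
  stopifnot(epochs >= 1L, batch_size >= 1L, base_lr > 0,
            warmup_ratio >= 0, warmup_ratio < 1,
            mask_rate >= 0, mask_rate <= 1, inherits(loss, "loss_config"),
            weight_decay >= 0, policy_lr >= 0,
            exploration_floor >= 0, exploration_floor < 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         base_lr = base_lr, warmup_ratio = warmup_ratio,
         mask_rate = mask_rate, mask_scheme = match.arg(mask_scheme),
         loss = loss, seed = as.integer(seed), weight_decay = weight_decay,
         policy_lr = policy_lr, exploration_floor = exploration_floor,
         reward = match.arg(reward), selection = match.arg(selection)),
    class = "pretrain_config"
  )
}

#' Learning-rate schedule
#'
#' Linear warm-up from 0 to `base_lr` over the first
#' `ceiling(warmup_ratio * total_steps)` steps, then linear decay to 0 at
#' `total_steps`.
#'
#' @param step Current step (0-based at the start of training).
#' @param total_steps Total planned optimizer steps.
#' @param config A [pretrain_config()].
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, config) {
  stopifnot(step >= 0, step <= total_steps)
  warmup <- ceiling(config$warmup_ratio * total_steps)
  if (step <= warmup) {
    if (warmup == 0L) return(config$base_lr)
    config$base_lr * step / warmup
  } else {
    config$base_lr * (total_steps - step) / (total_steps - warmup)
  }
}

# Mean masked-LM loss of `params` over a fixed masked batch (no gradients).
batch_mlm_loss <- function(params, masked, student_cfg) {
  tot <- 0; n <- 0L
  for (i in seq_len(nrow(masked))) {
    mpos <- masked$mask_pos[[i]]
    if (length(mpos) == 0L) next
    fw <- encode_sequence(params, masked$tokens[[i]], student_cfg)
    tot <- tot - sum(log(fw$dists[cbind(mpos, masked$targets[[i]])]))
    n <- n + length(mpos)
  }
  if (n == 0L) stop("validation batch has no masked positions", call. = FALSE)
  tot / n
}

#' Mean per-position KL divergence of a model against a teacher
#'
#' Runs the student over clean (uncorrupted) sequences and averages
#' `KL(teacher || student)` over all positions of all sequences — the
#' held-out measure of how closely the student mimics a teacher.
#'
#' @param model An `mtdp_model` (or bare `student_params`).
#' @param tokens A tibble from [tokenize_sequences()].
#' @param teacher Either a teacher function from [make_synthetic_teacher()]
#'   or a `teacher_store`; in the latter case `teacher_id` selects the
#'   teacher.
#' @param teacher_id Required when `teacher` is a store.
#' @return Mean per-position KL divergence (scalar).
#' @export
evaluate_kl <- function(model, tokens, teacher, teacher_id = NULL) {
  params <- if (inherits(model, "mtdp_model")) model$params else model
  scfg <- attr(params, "config")
  tot <- 0; n <- 0L
  for (i in seq_len(nrow(tokens))) {
    tk <- tokens$tokens[[i]]
    fw <- encode_sequence(params, tk, scfg)
    tdists <- if (inherits(teacher, "teacher_store")) {
      read_outputs(teacher, teacher_id, tokens$id[[i]])[[1]]$dists
    } else {
      teacher(tk, tokens$id[[i]])$dists
    }
    tot <- tot + distill_loss(tdists, fw$dists) * length(tk)
    n <- n + length(tk)
  }
  tot / n
}

#' Distillation pre-training of the student encoder
#'
#' The joint pre-training loop: every step draws a batch, corrupts it with
#' the masking scheme, runs the student, reads the offline teacher outputs,
#' computes per-teacher distillation losses, lets the selection policy sample
#' one supervising teacher per instance, backpropagates the combined
#' objective `alpha * L_MLM + (1 - alpha) * L_Distill`, takes an AdamW step
#' under the warm-up/decay schedule, and finally updates the policy with the
#' observed reward. All teacher records are checked up front so a missing
#' record can never interrupt training. Runs are exactly reproducible from
#' `config$seed`.
#'
#' @param corpus A tibble from [tokenize_sequences()] — the pre-training
#'   sequences.
#' @param store A `teacher_store` holding outputs for every corpus sequence
#'   and every teacher in `teachers`.
#' @param student A [student_config()].
#' @param config A [pretrain_config()].
#' @param validation Optional tokenized validation set; enables per-epoch
#'   validation losses and the `"validation"` reward.
#' @param teachers Teacher ids to use (default: all teachers in the store).
#' @param vocab The vocabulary (hashed into the checkpoint).
#' @param resume An `mtdp_model` from an earlier (shorter) run with the same
#'   configuration; training continues from its recorded state and RNG
#'   stream.
#' @param stop_after_epoch Stop after this many epochs while keeping the
#'   learning-rate horizon at `config$epochs` (for later resumption).
#' @param verbose Print per-epoch progress.
#' @return An object of class `mtdp_model`: parameters, configs, policy
#'   state, per-step training log (`$log`), per-instance teacher choices
#'   (`$choices`), and per-epoch validation losses (`$val_log`).
#' @export
pretrain <- function(corpus, store, student = student_config(),
                     config = pretrain_config(), validation = NULL,
                     teachers = NULL, vocab = aa_vocabulary(),
                     resume = NULL, stop_after_epoch = Inf, verbose = FALSE) {
  run_pretrain(corpus, store, student, config, validation, teachers,
               fixed_teacher = NULL, vocab = vocab, resume = resume,
               stop_after_epoch = stop_after_epoch, verbose = verbose)
}

#' Single-teacher distillation pre-training
#'
#' As [pretrain()] with the selection policy disabled and the full weight on
#' one named teacher — the single-teacher ablation baseline.
#'
#' @inheritParams pretrain
#' @param teacher_id The teacher to distill from.
#' @return An `mtdp_model`; its log carries no policy columns.
#' @export
single_teacher_pretrain <- function(corpus, store, teacher_id,
                                    student = student_config(),
                                    config = pretrain_config(),
                                    validation = NULL,
                                    vocab = aa_vocabulary(),
                                    resume = NULL, stop_after_epoch = Inf,
                                    verbose = FALSE) {
  if (!teacher_id %in% store$teachers) {
    stop("unknown teacher id '", teacher_id, "'", call. = FALSE)
  }
  run_pretrain(corpus, store, student, config, validation,
               teachers = teacher_id, fixed_teacher = teacher_id,
               vocab = vocab, resume = resume,
               stop_after_epoch = stop_after_epoch, verbose = verbose)
}

run_pretrain <- function(corpus, store, student_cfg, cfg, validation,
                         teachers, fixed_teacher, vocab, resume,
                         stop_after_epoch, verbose) {
  stopifnot(inherits(store, "teacher_store"), inherits(cfg, "pretrain_config"),
            inherits(student_cfg, "student_config"), nrow(corpus) >= 1L)
  teachers <- teachers %||% store$teachers
  K <- length(teachers)
  store_preflight(store, corpus$id, teachers)
  loss_cfg <- cfg$loss
  alpha <- loss_cfg$alpha
  emb_space <- loss_cfg$distill_space == "embedding"
  use_policy <- is.null(fixed_teacher) && K > 1L && cfg$selection == "sample"
  mixture <- is.null(fixed_teacher) && K > 1L && cfg$selection == "mixture"
  if (cfg$reward == "validation" && is.null(validation) && use_policy) {
    stop("reward = 'validation' requires a validation set", call. = FALSE)
  }

  n <- nrow(corpus)
  B <- cfg$batch_size
  batches_per_epoch <- ceiling(n / B)
  total_steps <- cfg$epochs * batches_per_epoch

  if (is.null(resume)) {
    set.seed(cfg$seed)
    params <- init_student(student_cfg)
    if (emb_space) params <- add_projections(params, store, corpus, teachers)
    pvec <- flatten_params(params)
    opt <- adamw_init(length(pvec))
    policy <- if (use_policy) policy_init(K, student_cfg$hidden_dim + 4L)
    step <- 0L; start_epoch <- 1L
    log_rows <- list(); choice_rows <- list(); val_rows <- list()
    prev_val <- NULL
  } else {
    stopifnot(inherits(resume, "mtdp_model"))
    params <- resume$params
    pvec <- flatten_params(params)
    opt <- resume$optimizer
    policy <- resume$policy
    step <- resume$steps_done; start_epoch <- resume$epochs_done + 1L
    log_rows <- list(resume$log); choice_rows <- list(resume$choices)
    val_rows <- list(resume$val_log)
    prev_val <- resume$prev_val
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  val_masked <- NULL
  if (!is.null(validation)) {
    val_masked <- apply_mask(validation, rate = cfg$mask_rate, vocab = vocab,
                             scheme = cfg$mask_scheme, seed = cfg$seed + 77777L)
    if (use_policy && cfg$reward == "validation" && is.null(prev_val)) {
      prev_val <- batch_mlm_loss(params, val_masked, student_cfg)
    }
  }

  last_epoch <- min(cfg$epochs, stop_after_epoch)
  for (epoch in seq.int(start_epoch, last_epoch)) {
    ord <- sample.int(n)
    for (bi in seq_len(batches_per_epoch)) {
      idx <- ord[((bi - 1L) * B + 1L):min(bi * B, n)]
      step <- step + 1L
      lr <- lr_schedule(step, total_steps, cfg)
      masked <- apply_mask(corpus[idx, , drop = FALSE], rate = cfg$mask_rate,
                           vocab = vocab, scheme = cfg$mask_scheme)
      gsum <- NULL
      inst <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        inst[[j]] <- pretrain_instance(params, student_cfg, masked, j, store,
                                       teachers, loss_cfg, policy, cfg,
                                       use_policy, mixture, fixed_teacher)
        gsum <- if (is.null(gsum)) inst[[j]]$gvec else gsum + inst[[j]]$gvec
      }
      res <- adamw_step(pvec, gsum / length(idx), opt, lr, cfg$weight_decay)
      pvec <- res$pvec; opt <- res$opt
      if (any(!is.finite(pvec))) {
        stop("non-finite parameters at step ", step, "; aborting", call. = FALSE)
      }
      params <- unflatten_params(pvec, params)

      # policy reward and update
      if (use_policy) {
        if (cfg$reward == "validation") {
          cur <- batch_mlm_loss(params, val_masked, student_cfg)
          rewards <- rep(prev_val - cur, length(idx))
          prev_val <- cur
        } else {
          rewards <- vapply(seq_along(idx), function(j) {
            ii <- inst[[j]]
            fw2 <- encode_sequence(params, masked$tokens[[j]], student_cfg)
            after <- instance_loss(fw2, masked, j, ii$teacher_out, loss_cfg, params, ii$chosen_id)
            ii$l_total - after
          }, 0)
        }
        # policy lr follows the same warm-up/decay shape as the optimizer,
        # so selection freezes as per-step rewards vanish late in training;
        # per-instance updates within a batch are averaged (1/B scaling),
        # keeping the per-step update size independent of batch size
        plr <- cfg$policy_lr * (lr / cfg$base_lr) / length(idx)
        for (j in seq_along(idx)) {
          policy <- policy_update(policy, inst[[j]]$feats, inst[[j]]$chosen,
                                  rewards[[j]], plr)
        }
      }

      lm <- mean(vapply(inst, `[[`, 0, "l_mlm"))
      ld <- mean(vapply(inst, `[[`, 0, "l_distill"))
      lt <- mean(vapply(inst, `[[`, 0, "l_total"))
      if (!all(is.finite(c(lm, ld, lt)))) {
        stop("non-finite loss at step ", step, "; aborting", call. = FALSE)
      }
      row <- tibble::tibble(step = step, epoch = epoch, lr = lr,
                            l_mlm = lm, l_distill = ld, l_total = lt)
      if (use_policy || mixture) {
        ch <- vapply(inst, `[[`, 0L, "chosen")
        row$chosen_teacher <- teachers[[as.integer(names(which.max(table(ch))))]]
        wbar <- Reduce(`+`, lapply(inst, `[[`, "prob")) / length(inst)
        for (k in seq_len(K)) row[[paste0("w_", teachers[[k]])]] <- wbar[[k]]
        choice_rows[[length(choice_rows) + 1L]] <- tibble::tibble(
          step = step, sequence_id = masked$id,
          chosen_teacher = teachers[ch],
          weights = lapply(inst, function(x) stats::setNames(x$prob, teachers))
        )
      }
      log_rows[[length(log_rows) + 1L]] <- row
    }
    if (!is.null(validation)) {
      vml <- batch_mlm_loss(params, val_masked, student_cfg)
      vkl <- vapply(teachers, function(t) {
        evaluate_kl(params, validation, store, t)
      }, 0)
      vrow <- tibble::tibble(epoch = epoch, val_mlm = vml,
                             val_distill = mean(vkl))
      for (k in seq_len(K)) vrow[[paste0("val_kl_", teachers[[k]])]] <- vkl[[k]]
      val_rows[[length(val_rows) + 1L]] <- vrow
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  l_total %.4f", epoch, last_epoch,
                      log_rows[[length(log_rows)]]$l_total))
    }
  }

  structure(
    list(params = params, student_config = student_cfg, config = cfg,
         teachers = teachers, fixed_teacher = fixed_teacher,
         policy = if (use_policy) policy,
         vocab_hash = vocab_hash(vocab),
         log = dplyr::bind_rows(log_rows),
         choices = if (length(choice_rows)) dplyr::bind_rows(choice_rows),
         val_log = if (length(val_rows)) dplyr::bind_rows(val_rows),
         optimizer = opt, prev_val = prev_val,
         rng_state = get(".Random.seed", envir = globalenv()),
         epochs_done = last_epoch, steps_done = step,
         total_steps = total_steps),
    class = "mtdp_model"
  )
}

# Forward + loss + gradient for one instance of a batch. Returns the flat
# gradient and the bookkeeping the policy update needs.
pretrain_instance <- function(params, student_cfg, masked, j, store, teachers,
                              loss_cfg, policy, cfg, use_policy, mixture,
                              fixed_teacher) {
  tk <- masked$tokens[[j]]
  mpos <- masked$mask_pos[[j]]
  tgt <- masked$targets[[j]]
  alpha <- loss_cfg$alpha
  fw <- encode_sequence(params, tk, student_cfg, want_cache = TRUE)
  t_outs <- lapply(teachers, function(t) read_outputs(store, t, masked$id[[j]])[[1]])
  dpos <- if (loss_cfg$distill_positions == "all") seq_along(tk) else mpos
  emb_space <- loss_cfg$distill_space == "embedding"
  if (emb_space) {
    embs <- lapply(seq_along(teachers), function(k) {
      distill_loss_embedding(t_outs[[k]]$embedding, fw$hidden,
                             params$proj[[teachers[[k]]]])
    })
    dl_k <- vapply(embs, `[[`, 0, "loss")
  } else {
    dl_k <- vapply(t_outs, function(o) distill_loss(o$dists, fw$dists, dpos), 0)
  }

  K <- length(teachers)
  if (use_policy) {
    feats <- policy_features(fw$hidden, lapply(t_outs, `[[`, "dists"), dl_k)
    w <- teacher_weights(policy, feats)
    chosen <- sample_teacher(w$prob, floor = cfg$exploration_floor)
    prob <- w$prob
  } else if (mixture) {
    feats <- NULL
    prob <- rep(1 / K, K)
    chosen <- which.max(prob)
  } else {
    feats <- NULL
    chosen <- if (!is.null(fixed_teacher)) match(fixed_teacher, teachers) else 1L
    prob <- replace(rep(0, K), chosen, 1)
  }

  # masked-LM term
  has_mask <- length(mpos) > 0L
  if (loss_cfg$mlm_positions == "all") {
    orig <- tk; orig[mpos] <- tgt
    l_mlm <- mlm_loss(fw$dists, mpos, tgt, positions = "all", all_targets = orig)
    g_mlm <- mlm_loss_grad(fw$dists, seq_along(tk), orig)
  } else if (has_mask) {
    l_mlm <- mlm_loss(fw$dists, mpos, tgt)
    g_mlm <- mlm_loss_grad(fw$dists, mpos, tgt)
  } else {
    l_mlm <- 0
    g_mlm <- matrix(0, nrow(fw$dists), ncol(fw$dists))
  }

  # distillation term (gradient through the chosen teacher, or the mixture)
  dhidden <- NULL
  dproj <- NULL
  if (emb_space) {
    l_distill <- if (mixture) sum(prob * dl_k) else dl_k[[chosen]]
    if (mixture) {
      dhidden <- Reduce(`+`, lapply(seq_len(K), function(k) prob[[k]] * embs[[k]]$dhidden))
      dproj <- lapply(seq_len(K), function(k) prob[[k]] * embs[[k]]$dproj)
    } else {
      dhidden <- embs[[chosen]]$dhidden
      dproj <- stats::setNames(list(embs[[chosen]]$dproj), teachers[[chosen]])
    }
    g_dist <- matrix(0, nrow(fw$dists), ncol(fw$dists))
  } else if (mixture) {
    l_distill <- sum(prob * dl_k)
    g_dist <- Reduce(`+`, lapply(seq_len(K), function(k) {
      prob[[k]] * distill_loss_grad(t_outs[[k]]$dists, fw$dists, dpos)
    }))
  } else {
    l_distill <- dl_k[[chosen]]
    g_dist <- distill_loss_grad(t_outs[[chosen]]$dists, fw$dists, dpos)
  }

  dlog <- alpha * g_mlm + (1 - alpha) * g_dist
  dhid <- if (!is.null(dhidden)) (1 - alpha) * dhidden
  g <- backward_sequence(params, fw, dlog, student_cfg, dhidden = dhid)
  if (emb_space && !is.null(dproj)) {
    if (mixture) {
      for (k in seq_len(K)) {
        g$proj[[teachers[[k]]]] <- g$proj[[teachers[[k]]]] + (1 - alpha) * dproj[[k]]
      }
    } else {
      g$proj[[teachers[[chosen]]]] <- g$proj[[teachers[[chosen]]]] +
        (1 - alpha) * dproj[[teachers[[chosen]]]]
    }
  }

  list(gvec = flatten_params(g), chosen = chosen, chosen_id = teachers[[chosen]],
       prob = prob, feats = feats,
       l_mlm = l_mlm, l_distill = l_distill,
       l_total = alpha * l_mlm + (1 - alpha) * l_distill,
       teacher_out = t_outs[[chosen]])
}

# Combined loss of current params on one already-masked instance against one
# fixed teacher (used for the instance reward).
instance_loss <- function(fw, masked, j, teacher_out, loss_cfg, params, teacher_id) {
  mpos <- masked$mask_pos[[j]]
  tgt <- masked$targets[[j]]
  tk <- masked$tokens[[j]]
  alpha <- loss_cfg$alpha
  l_mlm <- if (loss_cfg$mlm_positions == "all") {
    orig <- tk; orig[mpos] <- tgt
    mlm_loss(fw$dists, mpos, tgt, positions = "all", all_targets = orig)
  } else if (length(mpos) > 0L) {
    mlm_loss(fw$dists, mpos, tgt)
  } else 0
  dpos <- if (loss_cfg$distill_positions == "all") seq_along(tk) else mpos
  l_dist <- if (loss_cfg$distill_space == "embedding") {
    distill_loss_embedding(teacher_out$embedding, fw$hidden,
                           params$proj[[teacher_id]])$loss
  } else {
    distill_loss(teacher_out$dists, fw$dists, dpos)
  }
  alpha * l_mlm + (1 - alpha) * l_dist
}

# Attach per-teacher embedding projection matrices (for embedding-space
# distillation), sized from the first stored record of each teacher.
add_projections <- function(params, store, corpus, teachers) {
  scfg <- attr(params, "config")
  params$proj <- stats::setNames(lapply(teachers, function(t) {
    rec <- read_outputs(store, t, corpus$id[[1]])[[1]]
    if (is.null(rec$embedding)) {
      stop("embedding-space distillation requires stored teacher embeddings (teacher '",
           t, "' has none)", call. = FALSE)
    }
    matrix(stats::rnorm(scfg$hidden_dim * ncol(rec$embedding), sd = 0.02),
           scfg$hidden_dim, ncol(rec$embedding))
  }), teachers)
  params
}

#' @export
print.mtdp_model <- function(x, ...) {
  cat("<mtdp_model> ", count_parameters(x$student_config), " parameters, ",
      x$epochs_done, " epochs, ", x$steps_done, " steps\n", sep = "")
  cat("  teachers:", paste(x$teachers, collapse = ", "),
      if (!is.null(x$fixed_teacher)) paste0("(fixed: ", x$fixed_teacher, ")"), "\n")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: mlm %.4f  distill %.4f  total %.4f\n",
              last$l_mlm, last$l_distill, last$l_total))
  invisible(x)
}

#' Save a model checkpoint
#'
#' A single container holding the configuration, parameters, optimizer and
#' policy state, logs, and the vocabulary hash.
#'
#' @param model An `mtdp_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mtdp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Refuses to load when the checkpoint's vocabulary differs from `vocab`.
#'
#' @param path File path written by [save_checkpoint()].
#' @param vocab The vocabulary the model is expected to use.
#' @return An `mtdp_model`.
#' @export
load_checkpoint <- function(path, vocab = aa_vocabulary()) {
  if (!file.exists(path)) stop("no checkpoint at ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "mtdp_model")) stop("not a model checkpoint", call. = FALSE)
  if (!identical(model$vocab_hash, vocab_hash(vocab))) {
    stop("vocabulary mismatch: checkpoint was trained with a different vocabulary",
         call. = FALSE)
  }
  model
}
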