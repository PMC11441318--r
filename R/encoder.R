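#' Student encoder configuration
#'
#' Architecture of the small trainable sequence encoder: an encoder-only,
#' pre-norm transformer in the T5 style — RMSNorm instead of LayerNorm, no
#' bias terms, learned relative-position biases added to attention scores,
#' and input/output embeddings tied. Per-position vocabulary distributions
#' come from a softmax over the hidden states projected through the
#' transposed embedding matrix.
#'
#' The default depth is six layers, the depth at which a T5-style student is
#' the most cost-effective; test-scale configurations typically use 2 layers
#' and a hidden size of 32-64.
#'
#' @param num_layers Number of transformer layers (default 6).
#' @param hidden_dim Hidden size `d` (must be divisible by `num_heads`).
#' @param num_heads Number of attention heads.
#' @param feedforward_dim Inner width of the position-wise feed-forward block.
#' @param vocab_size Vocabulary size `V` (default 23).
#' @param max_length Maximum sequence length accepted (default 1000).
#' @param dropout Dropout probability applied to the attention and
#'   feed-forward block outputs during training (default 0).
#' @param rel_window Relative-position bias window: offsets are clipped to
#'   `[-rel_window, rel_window]` (default 8), giving a shared bias table of
#'   `num_heads x (2 * rel_window + 1)` entries.
#' @return An object of class `student_config`.
#' @export
student_config <- function(num_layers = 6L, hidden_dim = 256L, num_heads = 4L,
                           feedforward_dim = 4L * hidden_dim,
                           vocab_size = 23L, max_length = 1000L,
                           dropout = 0, rel_window = 8L) {
  num_layers <- as.integer(num_layers)
  hidden_dim <- as.integer(hidden_dim)
  num_heads <- as.integer(num_heads)
  feedforward_dim <- as.integer(feedforward_dim)
  stopifnot(num_layers >= 0L, hidden_dim >= 1L, num_heads >= 1L,
            feedforward_dim >= 1L, vocab_size >= 2L, max_length >= 1L,
            dropout >= 0, dropout < 1, rel_window >= 1L)
  if (hidden_dim %% num_heads != 0L) {
    stop("`num_heads` must divide `hidden_dim`", call. = FALSE)
  }
  structure(
    list(num_layers = num_layers, hidden_dim = hidden_dim,
         num_heads = num_heads, feedforward_dim = feedforward_dim,
         vocab_size = as.integer(vocab_size), max_length = as.integer(max_length),
         dropout = dropout, rel_window = as.integer(rel_window)),
    class = "student_config"
  )
}

#' @export
print.student_config <- function(x, ...) {
  cat("<student_config> layers:", x$num_layers, " d:", x$hidden_dim,
      " heads:", x$num_heads, " ffw:", x$feedforward_dim,
      " V:", x$vocab_size, " max_len:", x$max_length, "\n")
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Count trainable parameters of a student configuration
#'
#' Closed form: the tied embedding matrix (`V * d`), plus — when at least one
#' layer is present — the shared relative-bias table
#' (`heads * (2 * rel_window + 1)`) and the final RMSNorm gain (`d`), plus per
#' layer four `d x d` attention projections, two RMSNorm gains (`2d`) and the
#' two feed-forward matrices (`2 * d * f`). No bias vectors exist anywhere
#' (T5 convention). A zero-layer configuration degenerates to the embedding
#' table alone.
#'
#' @param config A `student_config`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "student_config"))
  d <- config$hidden_dim; f <- config$feedforward_dim
  V <- config$vocab_size; L <- config$num_layers
  n <- V * d
  if (L > 0L) {
    n <- n + config$num_heads * (2L * config$rel_window + 1L) + d
    n <- n + L * (4L * d * d + 2L * d + 2L * d * f)
  }
  as.integer(n)
}

#' Initialize student parameters
#'
#' All weight matrices are drawn i.i.d. Normal(0, 0.02^2); RMSNorm gains start
#' at 1 and relative biases at 0.
#'
#' @param config A `student_config`.
#' @param seed Optional integer seed (uses the current RNG stream when `NULL`).
#' @return A `student_params` list of parameter arrays.
#' @export
init_student <- function(config, seed = NULL) {
  stopifnot(inherits(config, "student_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$hidden_dim; f <- config$feedforward_dim
  V <- config$vocab_size; H <- config$num_heads
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(emb = rn(V, d))
  if (config$num_layers > 0L) {
    p$rel <- matrix(0, H, 2L * config$rel_window + 1L)
    p$gf <- rep(1, d)
    p$layers <- lapply(seq_len(config$num_layers), function(l) {
      list(wq = rn(d, d), wk = rn(d, d), wv = rn(d, d), wo = rn(d, d),
           w1 = rn(d, f), w2 = rn(f, d), g1 = rep(1, d), g2 = rep(1, d))
    })
  }
  structure(p, class = "student_params", config = config)
}

# ---- numerical primitives --------------------------------------------------

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

rmsnorm_fwd <- function(x, g, eps = 1e-6) {
  r <- sqrt(rowMeans(x * x) + eps)
  xr <- x / r
  list(y = xr * rep(g, each = nrow(x)), xr = xr, r = r)
}

rmsnorm_bwd <- function(x, g, cache, dy) {
  N <- nrow(x); d <- ncol(x)
  dg <- colSums(dy * cache$xr)
  dxr <- dy * rep(g, each = N)
  dx <- dxr / cache$r - x * (rowSums(dxr * x) / (d * cache$r^3))
  list(dx = dx, dg = dg)
}

# Relative-position bucket index vector for an N x N score matrix, cached per
# (N, window). Bucket = clip(j - i, -w, w) + w + 1.
.pd_cache <- new.env(parent = emptyenv())
rel_buckets <- function(N, window) {
  key <- paste0(N, "_", window)
  b <- .pd_cache[[key]]
  if (is.null(b)) {
    off <- outer(seq_len(N), seq_len(N), function(i, j) j - i)
    b <- pmin(pmax(off, -window), window) + window + 1L
    storage.mode(b) <- "integer"
    .pd_cache[[key]] <- b
  }
  b
}

# ---- forward ----------------------------------------------------------------

#' Run the student encoder over one token sequence
#'
#' @param params A `student_params` object.
#' @param tokens Integer vector of vocabulary indices (length `N <=
#'   max_length`).
#' @param config The matching `student_config`.
#' @param want_cache Keep intermediate activations for backpropagation
#'   (internal use).
#' @param dropout_on Apply dropout (training mode). Evaluation mode
#'   (default) is deterministic.
#' @return A list of class `student_output` with `hidden` (`N x d`), `dists`
#'   (`N x V`, rows summing to 1), `logits`, and (optionally) `cache`.
#' @export
encode_sequence <- function(params, tokens, config = attr(params, "config"),
                            want_cache = FALSE, dropout_on = FALSE) {
  tokens <- as.integer(tokens)
  N <- length(tokens)
  if (N < 1L) stop("empty token sequence", call. = FALSE)
  if (N > config$max_length) {
    stop("sequence length ", N, " exceeds max_length ", config$max_length,
         "; truncate during tokenization", call. = FALSE)
  }
  if (any(tokens < 1L | tokens > config$vocab_size)) {
    stop("token index out of range", call. = FALSE)
  }
  d <- config$hidden_dim; H <- config$num_heads; dh <- d %/% H
  sc <- 1 / sqrt(dh)
  drop_p <- if (dropout_on) config$dropout else 0

  x <- params$emb[tokens, , drop = FALSE]
  L <- config$num_layers
  cache <- if (want_cache) list(tokens = tokens, layers = vector("list", L))

  if (L > 0L) {
    buckets <- rel_buckets(N, config$rel_window)
    for (l in seq_len(L)) {
      ly <- params$layers[[l]]
      n1 <- rmsnorm_fwd(x, ly$g1)
      u <- n1$y
      Q <- u %*% ly$wq; K <- u %*% ly$wk; Vv <- u %*% ly$wv
      O <- matrix(0, N, d)
      A <- if (want_cache) vector("list", H)
      for (h in seq_len(H)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * sc
        S <- S + matrix(params$rel[h, ][buckets], N, N)
        Ah <- softmax_rows(S)
        if (want_cache) A[[h]] <- Ah
        O[, idx] <- Ah %*% Vv[, idx, drop = FALSE]
      }
      attn <- O %*% ly$wo
      dm1 <- NULL
      if (drop_p > 0) {
        dm1 <- matrix(stats::runif(N * d) >= drop_p, N, d) / (1 - drop_p)
        attn <- attn * dm1
      }
      x1 <- x + attn
      n2 <- rmsnorm_fwd(x1, ly$g2)
      v <- n2$y
      f1 <- v %*% ly$w1
      a <- f1 * (f1 > 0)
      ffn <- a %*% ly$w2
      dm2 <- NULL
      if (drop_p > 0) {
        dm2 <- matrix(stats::runif(N * d) >= drop_p, N, d) / (1 - drop_p)
        ffn <- ffn * dm2
      }
      x2 <- x1 + ffn
      if (want_cache) {
        cache$layers[[l]] <- list(x = x, n1 = n1, Q = Q, K = K, Vv = Vv,
                                  A = A, O = O, dm1 = dm1, x1 = x1, n2 = n2,
                                  f1 = f1, a = a, dm2 = dm2)
      }
      x <- x2
    }
    nf <- rmsnorm_fwd(x, params$gf)
    hidden <- nf$y
    if (want_cache) { cache$xL <- x; cache$nf <- nf }
  } else {
    hidden <- x
  }
  logits <- tcrossprod(hidden, params$emb)
  dists <- softmax_rows(logits)
  out <- list(hidden = hidden, dists = dists, logits = logits)
  if (want_cache) out$cache <- cache
  class(out) <- "student_output"
  out
}

# ---- backward ---------------------------------------------------------------

# Zero-filled gradient structure matching params.
zero_grads <- function(params) {
  z <- function(x) { x[] <- 0; x }
  g <- list(emb = z(params$emb))
  if (!is.null(params$layers)) {
    g$rel <- z(params$rel)
    g$gf <- z(params$gf)
    g$layers <- lapply(params$layers, function(ly) lapply(ly, z))
  }
  if (!is.null(params$proj)) g$proj <- lapply(params$proj, z)
  g
}

# Backpropagate through one cached forward pass.
# dlogits: N x V gradient of the loss w.r.t. the output logits.
# dhidden: optional N x d gradient entering the final hidden states directly
#   (e.g. from an embedding-space distillation term).
# Returns a gradient structure matching params.
backward_sequence <- function(params, out, dlogits, config = attr(params, "config"),
                              dhidden = NULL) {
  cache <- out$cache
  if (is.null(cache)) stop("forward pass was run without want_cache = TRUE")
  g <- zero_grads(params)
  N <- nrow(out$hidden); d <- config$hidden_dim
  H <- config$num_heads; dh <- d %/% H
  sc <- 1 / sqrt(dh)

  # logits = hidden %*% t(emb)
  dhid <- dlogits %*% params$emb
  g$emb <- g$emb + crossprod(dlogits, out$hidden)
  if (!is.null(dhidden)) dhid <- dhid + dhidden

  L <- config$num_layers
  if (L > 0L) {
    bw <- rmsnorm_bwd(cache$xL, params$gf, cache$nf, dhid)
    dx <- bw$dx
    g$gf <- g$gf + bw$dg
    buckets <- rel_buckets(N, config$rel_window)
    bvec <- as.vector(buckets)
    for (l in rev(seq_len(L))) {
      ly <- params$layers[[l]]
      cl <- cache$layers[[l]]
      # x2 = x1 + ffn ; ffn possibly dropped out
      dffn <- dx
      if (!is.null(cl$dm2)) dffn <- dffn * cl$dm2
      da <- dffn %*% t(ly$w2)
      g$layers[[l]]$w2 <- g$layers[[l]]$w2 + crossprod(cl$a, dffn)
      df1 <- da * (cl$f1 > 0)
      dv <- df1 %*% t(ly$w1)
      g$layers[[l]]$w1 <- g$layers[[l]]$w1 + crossprod(cl$n2$y, df1)
      bw2 <- rmsnorm_bwd(cl$x1, ly$g2, cl$n2, dv)
      g$layers[[l]]$g2 <- g$layers[[l]]$g2 + bw2$dg
      dx1 <- dx + bw2$dx
      # x1 = x + attn ; attn = (O %*% wo) [* dm1]
      dattn <- dx1
      if (!is.null(cl$dm1)) dattn <- dattn * cl$dm1
      dO <- dattn %*% t(ly$wo)
      g$layers[[l]]$wo <- g$layers[[l]]$wo + crossprod(cl$O, dattn)
      dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
      for (h in seq_len(H)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        Ah <- cl$A[[h]]
        dOh <- dO[, idx, drop = FALSE]
        dAh <- tcrossprod(dOh, cl$Vv[, idx, drop = FALSE])
        dV[, idx] <- crossprod(Ah, dOh)
        dS <- Ah * (dAh - rowSums(dAh * Ah))
        rsb <- rowsum(as.vector(dS), bvec)
        bidx <- as.integer(rownames(rsb))
        g$rel[h, bidx] <- g$rel[h, bidx] + rsb[, 1L]
        dQ[, idx] <- (dS %*% cl$K[, idx, drop = FALSE]) * sc
        dK[, idx] <- (crossprod(dS, cl$Q[, idx, drop = FALSE])) * sc
      }
      u <- cl$n1$y
      du <- dQ %*% t(ly$wq) + dK %*% t(ly$wk) + dV %*% t(ly$wv)
      g$layers[[l]]$wq <- g$layers[[l]]$wq + crossprod(u, dQ)
      g$layers[[l]]$wk <- g$layers[[l]]$wk + crossprod(u, dK)
      g$layers[[l]]$wv <- g$layers[[l]]$wv + crossprod(u, dV)
      bw1 <- rmsnorm_bwd(cl$x, ly$g1, cl$n1, du)
      g$layers[[l]]$g1 <- g$layers[[l]]$g1 + bw1$dg
      dx <- dx1 + bw1$dx
    }
  } else {
    dx <- dhid
  }
  # input embedding rows (scatter-add)
  rs <- rowsum(dx, cache$tokens, reorder = FALSE)
  rows <- as.integer(rownames(rs))
  g$emb[rows, ] <- g$emb[rows, ] + rs
  g
}
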