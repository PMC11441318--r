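# Parameter trees are nested lists of numeric arrays. The optimizer works on
# a flat vector view; these helpers convert both ways with a stable ordering.

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(sk) {
    if (is.list(sk)) {
      out <- lapply(sk, fill)
      attributes(out) <- attributes(sk)
      out
    } else {
      n <- length(sk)
      x <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      attributes(x) <- attributes(sk)
      x
    }
  }
  out <- fill(skeleton)
  stopifnot(pos == length(vec))
  out
}

#' @noRd
adamw_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# One AdamW step on flat vectors: decoupled weight decay, betas 0.9/0.999.
adamw_step <- function(pvec, gvec, opt, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * gvec
  opt$v <- beta2 * opt$v + (1 - beta2) * gvec * gvec
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  pvec <- pvec - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * pvec)
  list(pvec = pvec, opt = opt)
}
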