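# Independent naive-loop references for the two loss terms.
mlm_loss_naive <- function(dists, mask_pos, targets) {
  V <- ncol(dists)
  tot <- 0
  for (k in seq_along(mask_pos)) {
    i <- mask_pos[k]
    for (j in seq_len(V)) {
      if (targets[k] == j) tot <- tot - log(dists[i, j])
    }
  }
  tot / length(mask_pos)
}

kl_naive <- function(teacher, student, positions = seq_len(nrow(teacher))) {
  tot <- 0
  for (i in positions) {
    for (j in seq_len(ncol(teacher))) {
      p <- teacher[i, j]
      if (p > 0) tot <- tot + p * (log(p) - log(student[i, j]))
    }
  }
  tot / length(positions)
}

test_that("masked-LM loss hits its analytic boundary cases", {
  # perfect student: probability 1 at the true token -> loss 0
  d <- matrix(1e-12, 3, 4)
  tg <- c(2L, 1L, 4L)
  d[cbind(1:3, tg)] <- 1
  expect_equal(mlm_loss(d, 1:3, tg), 0, tolerance = 1e-9)

  # one masked position, uniform student over a 2-token toy vocabulary -> ln 2
  expect_equal(mlm_loss(matrix(0.5, 1, 2), 1L, 1L), log(2), tolerance = 1e-12)

  expect_error(mlm_loss(d, integer(), integer()), "zero scored positions")
})

test_that("masked-LM and KL losses match naive double-loop references on random instances", {
  set.seed(101)
  for (r in 1:200) {
    N <- sample(1:10, 1); V <- sample(2:5, 1)
    s <- random_simplex(N, V)
    t <- random_simplex(N, V)
    nm <- sample(1:N, 1)
    mpos <- sort(sample(N, nm))
    tgt <- sample(V, nm, replace = TRUE)
    expect_equal(mlm_loss(s, mpos, tgt), mlm_loss_naive(s, mpos, tgt),
                 tolerance = 1e-6)
    expect_equal(distill_loss(t, s), kl_naive(t, s), tolerance = 1e-6)
    pos <- sort(sample(N, sample(1:N, 1)))
    expect_equal(distill_loss(t, s, pos), kl_naive(t, s, pos), tolerance = 1e-6)
  }
})

test_that("KL distillation loss is zero on identical inputs and matches the hand case", {
  p <- random_simplex(6, 23)
  expect_equal(distill_loss(p, p), 0, tolerance = 1e-12)
  # single position, p_T = (0.75, 0.25) vs uniform student
  expect_equal(distill_loss(matrix(c(0.75, 0.25), 1), matrix(0.5, 1, 2)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-9)
  expect_equal(distill_loss(matrix(c(0.75, 0.25), 1), matrix(0.5, 1, 2)),
               0.130812, tolerance = 1e-6)
})

test_that("KL is non-negative and zero only for matching distributions", {
  set.seed(7)
  for (r in 1:500) {
    N <- sample(1:6, 1); V <- sample(2:6, 1)
    t <- random_simplex(N, V); s <- random_simplex(N, V)
    kl <- distill_loss(t, s)
    expect_gte(kl, 0)
    if (max(abs(t - s)) > 1e-3) expect_gt(kl, 0)
  }
  # zero teacher mass contributes nothing (0 * log 0 convention)
  t0 <- matrix(c(1, 0), 1)
  s0 <- matrix(c(0.6, 0.4), 1)
  expect_equal(distill_loss(t0, s0), log(1 / 0.6), tolerance = 1e-12)
  # vanished student mass where the teacher has mass -> +Inf
  expect_equal(distill_loss(s0, t0), Inf)
})

test_that("the combined objective is the stated convex combination", {
  expect_equal(combined_loss(1.3, 0.4, loss_config(alpha = 1))$l_total, 1.3)
  expect_equal(combined_loss(1.3, 0.4, loss_config(alpha = 0))$l_total, 0.4)
  expect_equal(combined_loss(1.0, 0.5, loss_config(alpha = 0.2))$l_total, 0.6,
               tolerance = 1e-12)

  # linear and monotone in both arguments; report satisfies its own identity
  set.seed(3)
  cfg <- loss_config(alpha = 0.3)
  for (r in 1:20) {
    a <- runif(1, 0, 3); b <- runif(1, 0, 3); h <- runif(1, 0, 1)
    r1 <- combined_loss(a, b, cfg); r2 <- combined_loss(a + h, b, cfg)
    r3 <- combined_loss(a, b + h, cfg)
    expect_equal(r2$l_total - r1$l_total, 0.3 * h, tolerance = 1e-12)
    expect_equal(r3$l_total - r1$l_total, 0.7 * h, tolerance = 1e-12)
    expect_equal(r1$l_total, cfg$alpha * r1$l_mlm + (1 - cfg$alpha) * r1$l_distill,
                 tolerance = 1e-9)
  }
  expect_error(loss_config(alpha = 1.2), "alpha")
})

test_that("embedding-space distillation loss and gradients agree with finite differences", {
  set.seed(21)
  N <- 5; d <- 4; dT <- 6
  H <- matrix(rnorm(N * d), N, d)
  E <- matrix(rnorm(N * dT), N, dT)
  P <- matrix(rnorm(d * dT, sd = 0.3), d, dT)
  res <- distill_loss_embedding(E, H, P)
  expect_equal(res$loss, mean((H %*% P - E)^2), tolerance = 1e-12)
  eps <- 1e-6
  for (probe in 1:5) {
    i <- sample(d, 1); j <- sample(dT, 1)
    Pp <- P; Pp[i, j] <- Pp[i, j] + eps
    fd <- (distill_loss_embedding(E, H, Pp)$loss - res$loss) / eps
    expect_equal(res$dproj[i, j], fd, tolerance = 1e-4)
    a <- sample(N, 1); b <- sample(d, 1)
    Hp <- H; Hp[a, b] <- Hp[a, b] + eps
    fd2 <- (distill_loss_embedding(E, Hp, P)$loss - res$loss) / eps
    expect_equal(res$dhidden[a, b], fd2, tolerance = 1e-4)
  }
})
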