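# The loss implementations are checked against literal-loop oracles and
# against hand-computed closed forms.

test_that("replicate contrastive loss reproduces hand-computed values", {
  # R=2, S=2, tau=0.5, x_11=x_21=(1,0), x_12=x_22=(0,1): each term
  # -log(e^2 / e^0) = -2, so l1 = -2
  x <- array(0, c(2, 2, 2))
  x[1, 1, ] <- c(1, 0); x[1, 2, ] <- c(1, 0)
  x[2, 1, ] <- c(0, 1); x[2, 2, ] <- c(0, 1)
  expect_equal(lossReplicate(x, tau1 = 0.5), -2)
  expect_equal(naive_l1(x, 0.5), -2)

  # all embeddings identical: every term reduces to log(S-1)
  for (S in c(2, 3, 7)) {
    xx <- array(rep(c(0.3, -0.2, 0.9), each = S * 2), c(S, 2, 3))
    expect_equal(lossReplicate(xx, tau1 = 0.5), log(S - 1), tolerance = 1e-12)
  }
})

test_that("class-similarity loss reproduces hand-computed values", {
  # R=2, S=2, q identical across replicates, q_r1=(1,0), q_r2=(0,1):
  # per (k, pair) term (1-0)/0.5 = 2 -> l2 = -2
  q <- array(0, c(2, 2, 2))
  q[1, , 1] <- 1; q[2, , 2] <- 1
  expect_equal(lossClass(q, tau2 = 0.5), -2)
  expect_equal(naive_l2(q, 0.5), -2)

  # uniform probabilities are a fixed point: cos(p,p) = cos(p,1-p) = 1
  qu <- array(0.5, c(4, 3, 2))
  expect_equal(lossClass(qu, tau2 = 0.5), 0)
})

test_that("losses agree with naive loop oracles on random inputs", {
  set.seed(99)
  for (trial in 1:100) {
    S <- sample(2:16, 1); R <- sample(2:4, 1); D <- sample(2:8, 1)
    tau <- runif(1, 0.2, 1)
    x <- array(rnorm(S * R * D), c(S, R, D))
    expect_equal(lossReplicate(x, tau), naive_l1(x, tau), tolerance = 1e-6)
    q1 <- matrix(runif(S * R), S, R)
    q <- array(c(q1, 1 - q1), c(S, R, 2))
    expect_equal(lossClass(q, tau), naive_l2(q, tau), tolerance = 1e-6)
  }
})

test_that("losses are invariant under replicate permutation", {
  set.seed(12)
  S <- 9; R <- 4; D <- 6
  x <- array(rnorm(S * R * D), c(S, R, D))
  q1 <- matrix(runif(S * R), S, R)
  q <- array(c(q1, 1 - q1), c(S, R, 2))
  perm <- sample(R)
  expect_equal(lossReplicate(x[, perm, ], 0.5), lossReplicate(x, 0.5),
               tolerance = 1e-12)
  expect_equal(lossClass(q[, perm, ], 0.5), lossClass(q, 0.5),
               tolerance = 1e-12)
  # l1 also invariant under simultaneous segment permutation
  sp <- sample(S)
  expect_equal(lossReplicate(x[sp, , ], 0.5), lossReplicate(x, 0.5),
               tolerance = 1e-12)
})

test_that("autoencoder loss is a mean squared error with its invariances", {
  m <- array(c(0, 2), c(1, 1, 2)); mh <- array(c(1, 1), c(1, 1, 2))
  expect_equal(lossAutoencoder(m, mh), 1) # ((0-1)^2 + (2-1)^2)/2
  expect_equal(lossAutoencoder(m, m), 0)
  set.seed(4)
  a <- array(rnorm(24), c(3, 2, 4)); b <- array(rnorm(24), c(3, 2, 4))
  expect_gte(lossAutoencoder(a, b), 0)
  expect_equal(lossAutoencoder(a, a + 3 * (b - a)), 9 * lossAutoencoder(a, b))
})

test_that("total loss is the weighted sum of components", {
  tl <- totalLoss(-2, -2, 1)
  expect_equal(tl$L, -3)
  expect_equal(totalLoss(-2, -2, 1, weights = c(0, 0, 1))$L, 1)
  expect_equal(totalLoss(5, -1, 2, weights = c(1, 1, 0))$L, 4)
})

test_that("degenerate loss inputs are rejected or guarded", {
  x <- array(0, c(2, 2, 3)) # zero-norm embeddings
  expect_error(lossReplicate(x), "zero-norm")
  x1 <- array(rnorm(1 * 2 * 3), c(1, 2, 3))
  expect_error(lossReplicate(x1), "2 segments")
  xr <- array(rnorm(4 * 1 * 3), c(4, 1, 3))
  expect_error(lossReplicate(xr), "2 replicates")
  # one all-zero class column is guarded by the norm floor, not an error
  q <- array(0, c(3, 2, 2)); q[, , 1] <- 1
  expect_true(is.finite(lossClass(q)))
})

test_that("compiled loss gradients match finite differences", {
  set.seed(21)
  B <- 5; R <- 3; D <- 4
  x <- matrix(rnorm(D * B * R), D, B * R)
  res <- contrastPeaks:::.cp_l1_grad(x, B, R, 0.5)
  # loss value agrees with the array-form reference implementation
  xa <- array(0, c(B, R, D))
  for (r in 1:R) xa[, r, ] <- t(x[, (r - 1) * B + 1:B])
  expect_equal(res$loss, lossReplicate(xa, 0.5), tolerance = 1e-10)
  h <- 1e-6
  idx <- cbind(sample(D, 8, TRUE), sample(B * R, 8, TRUE))
  for (k in 1:8) {
    xp <- x; xp[idx[k, 1], idx[k, 2]] <- xp[idx[k, 1], idx[k, 2]] + h
    xm <- x; xm[idx[k, 1], idx[k, 2]] <- xm[idx[k, 1], idx[k, 2]] - h
    fd <- (contrastPeaks:::.cp_l1_grad(xp, B, R, 0.5)$loss -
           contrastPeaks:::.cp_l1_grad(xm, B, R, 0.5)$loss) / (2 * h)
    expect_equal(res$grad[idx[k, 1], idx[k, 2]], fd, tolerance = 1e-4)
  }

  qm <- matrix(runif(2 * B * R, 0.05, 0.95), 2, B * R)
  res2 <- contrastPeaks:::.cp_l2_grad(qm, B, R, 0.5)
  qa <- array(0, c(B, R, 2))
  for (r in 1:R) qa[, r, ] <- t(qm[, (r - 1) * B + 1:B])
  # reference lossClass assumes complementary columns; the compiled version
  # uses the other softmax column as the complement, so compare on
  # complementary input
  qc <- qm; qc[2, ] <- 1 - qc[1, ]
  res2c <- contrastPeaks:::.cp_l2_grad(qc, B, R, 0.5)
  qac <- qa; qac[, , 2] <- 1 - qac[, , 1]
  expect_equal(res2c$loss, lossClass(qac, 0.5), tolerance = 1e-10)
  for (k in 1:8) {
    i <- sample(2, 1); j <- sample(B * R, 1)
    qp <- qm; qp[i, j] <- qp[i, j] + h
    qn <- qm; qn[i, j] <- qn[i, j] - h
    fd <- (contrastPeaks:::.cp_l2_grad(qp, B, R, 0.5)$loss -
           contrastPeaks:::.cp_l2_grad(qn, B, R, 0.5)$loss) / (2 * h)
    expect_equal(res2$grad[i, j], fd, tolerance = 1e-4)
  }
})
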