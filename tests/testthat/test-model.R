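# Network building blocks: the compiled convolution against a literal R
# oracle, shape/determinism contracts, and the softmax head.

test_that("compiled dilated convolution matches a literal R implementation", {
  set.seed(31)
  for (trial in 1:25) {
    Cin <- sample(1:4, 1); Cout <- sample(1:4, 1)
    K <- sample(c(3, 5, 7), 1); dil <- sample(1:3, 1)
    L <- sample(12:40, 1); N <- sample(1:3, 1)
    stride <- sample(1:2, 1)
    W <- matrix(rnorm(Cout * Cin * K), Cout, Cin * K)
    b <- rnorm(Cout)
    xs <- lapply(seq_len(N), function(i) matrix(rnorm(Cin * L), Cin, L))
    x <- do.call(cbind, xs)
    got <- contrastPeaks:::.cp_conv1d(x, W, b, L, N, dil, stride)
    expected <- do.call(cbind, lapply(xs, naive_conv1d, W = W, b = b,
                                      dil = dil, stride = stride))
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("encoder output has the configured dimension and is deterministic", {
  mdl <- tiny_model(alpha = 120)
  set.seed(2); m <- matrix(rpois(6 * 120, 3), 6, 120)
  x1 <- encodeSegments(mdl, m)
  x2 <- encodeSegments(mdl, m)
  expect_equal(dim(x1), c(6, 12))
  expect_identical(x1, x2)
  expect_true(all(is.finite(x1)))
  expect_error(encodeSegments(mdl, m[, 1:100]), "alpha")

  # default embedding dimension is 50
  expect_equal(modelConfig(peakModel())$embed_dim, 50)
})

test_that("zeroed parameters map any input to the zero embedding", {
  mdl <- tiny_model(alpha = 120)
  mdl@params <- lapply(mdl@params, function(p) { p[] <- 0; p })
  set.seed(3); m <- matrix(rpois(3 * 120, 5), 3, 120)
  expect_true(all(encodeSegments(mdl, m) == 0))
  expect_equal(unname(classifyEmbeddings(mdl, matrix(0, 1, 12))[1, ]),
               c(0.5, 0.5)) # zero logits -> uniform
})

test_that("classification head is a softmax on the 2-simplex", {
  mdl <- tiny_model(alpha = 120)
  set.seed(4)
  x <- matrix(rnorm(20 * 12), 20, 12)
  q <- classifyEmbeddings(mdl, x)
  expect_true(all(q >= 0))
  expect_equal(rowSums(q), rep(1, 20), tolerance = 1e-6)

  # closed-form softmax: logits (ln 3, 0) -> (0.75, 0.25); drive the head
  # directly by zeroing the hidden layer and setting the output bias
  mdl@params$mlp_h_W[] <- 0; mdl@params$mlp_h_b[] <- 0
  mdl@params$mlp_o_W[] <- 0
  mdl@params$mlp_o_b[, 1] <- c(log(3), 0)
  q2 <- classifyEmbeddings(mdl, matrix(0, 1, 12))
  expect_equal(unname(q2[1, ]), c(0.75, 0.25), tolerance = 1e-6)

  # the compiled forward pass and the R head agree
  mdl2 <- tiny_model(alpha = 120, seed = 9)
  m <- matrix(rpois(5 * 120, 3), 5, 120)
  fw <- contrastPeaks:::.cp_forward(mdl2@params, mdl2@config, m, FALSE)
  expect_equal(fw$q, unname(classifyEmbeddings(mdl2, fw$x)), tolerance = 1e-5)
})

test_that("decoder reconstructs to the input length deterministically", {
  mdl <- tiny_model(alpha = 120)
  set.seed(5)
  x <- matrix(rnorm(4 * 12), 4, 12)
  mh <- decodeEmbeddings(mdl, x)
  expect_equal(dim(mh), c(4, 120))
  expect_identical(mh, decodeEmbeddings(mdl, x))
  # encode -> decode equals the full forward reconstruction
  m <- matrix(rpois(4 * 120, 3), 4, 120)
  fw <- contrastPeaks:::.cp_forward(mdl@params, mdl@config, m, TRUE)
  expect_equal(decodeEmbeddings(mdl, fw$x), fw$mhat, tolerance = 1e-5)
})

test_that("modelForward reports losses consistent with the R loss functions", {
  mdl <- tiny_model(alpha = 120)
  set.seed(6)
  arr <- array(rpois(8 * 2 * 120, 2), c(8, 2, 120))
  fw <- modelForward(mdl, arr)
  expect_equal(fw$losses$l1, lossReplicate(fw$x, 0.5), tolerance = 1e-10)
  expect_equal(fw$losses$l2, lossClass(fw$q, 0.5), tolerance = 1e-10)
  expect_equal(fw$losses$l3, lossAutoencoder(arr, fw$mhat), tolerance = 1e-10)
  expect_equal(fw$losses$L, fw$losses$l1 + fw$losses$l2 + fw$losses$l3)
  # q rows on the simplex after a forward pass
  expect_equal(apply(fw$q, c(1, 2), sum), matrix(1, 8, 2), tolerance = 1e-6)
})

test_that("checkpoints round-trip through write/read", {
  tmp <- withr::local_tempdir()
  mdl <- tiny_model(alpha = 120)
  p <- file.path(tmp, "m.rds")
  writeModel(mdl, p)
  back <- readModel(p)
  expect_identical(back@params, mdl@params)
  expect_identical(back@config, mdl@config)
  set.seed(8); m <- matrix(rpois(2 * 120, 3), 2, 120)
  expect_identical(encodeSegments(back, m), encodeSegments(mdl, m))
})
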