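# Construction of the network and thin R wrappers around the compiled
# forward pass. The MLP head is small enough that classification from an
# embedding is done directly in R.

.default_config <- function(alpha = 1000L, channels = 16L, kernel_size = 31L,
                            dilation = 8L, n_modules = 5L, pool_out = 16L,
                            embed_dim = 50L, tau1 = 0.5, tau2 = 0.5,
                            loss_weights = c(1, 1, 1), log1p = FALSE,
                            batch_norm = FALSE) {
  list(alpha = as.integer(alpha), channels = as.integer(channels),
       kernel_size = as.integer(kernel_size), dilation = as.integer(dilation),
       n_modules = as.integer(n_modules), pool_out = as.integer(pool_out),
       embed_dim = as.integer(embed_dim), tau1 = tau1, tau2 = tau2,
       loss_weights = as.numeric(loss_weights), log1p = isTRUE(log1p),
       batch_norm = isTRUE(batch_norm))
}

#' Create an untrained peak model
#'
#' Initialises the encoder/MLP/decoder network. The encoder stacks
#' \code{n_modules} residual modules, each three dilated 1-D convolutions with
#' ReLU followed by a residual convolution block; the first convolution of
#' each module halves the sequence length. Adaptive average pooling and a
#' linear layer produce the \code{embed_dim}-dimensional embedding. The MLP
#' head has one hidden layer of the embedding dimension and a 2-class softmax;
#' the decoder mirrors the encoder with nearest-neighbour upsampling.
#' Convolution weights use Kaiming-uniform initialisation, seeded.
#'
#' @param alpha input segment length (bp).
#' @param channels convolutional channels in every block.
#' @param kernel_size convolution kernel size (odd).
#' @param dilation convolution dilation.
#' @param n_modules number of residual modules in the encoder (and decoder).
#' @param pool_out positions kept by the adaptive average pooling.
#' @param embed_dim embedding dimension.
#' @param tau1,tau2 temperatures of the contrastive and class losses.
#' @param loss_weights length-3 multipliers for the three losses.
#' @param log1p transform coverage by \code{log1p} before encoding.
#' @param batch_norm use batch normalisation in the convolutional blocks
#'   (default \code{FALSE}: on compact segment sets the normalised geometry
#'   can steer the class-similarity loss into a degenerate near-one-class
#'   partition; see the methods vignette).
#' @param seed integer seed for parameter initialisation.
#' @return An untrained [PeakModel-class].
#' @export
peakModel <- function(alpha = 1000L, channels = 16L, kernel_size = 31L,
                      dilation = 8L, n_modules = 5L, pool_out = 16L,
                      embed_dim = 50L, tau1 = 0.5, tau2 = 0.5,
                      loss_weights = c(1, 1, 1), log1p = FALSE,
                      batch_norm = FALSE, seed = 1L) {
  cfg <- .default_config(alpha, channels, kernel_size, dilation, n_modules,
                         pool_out, embed_dim, tau1, tau2, loss_weights, log1p,
                         batch_norm)
  params <- .cp_init_params(cfg, as.integer(seed))
  new("PeakModel", config = cfg, params = params, orientation = 1L,
      history = data.frame(), trained = FALSE)
}

.prep_input <- function(model, m) {
  if (is.vector(m)) m <- matrix(m, nrow = 1L)
  if (ncol(m) != model@config$alpha)
    stop(sprintf("input length %d does not match model alpha %d",
                 ncol(m), model@config$alpha))
  if (any(m < 0)) stop("coverage values must be nonnegative")
  if (model@config$log1p) m <- log1p(m)
  m
}

# flatten S x R x alpha array to (S*R) x alpha with row (r-1)*S + i
.flatten_svd <- function(arr) {
  d <- dim(arr)
  m <- matrix(0, nrow = d[1L] * d[2L], ncol = d[3L])
  for (r in seq_len(d[2L]))
    m[(r - 1L) * d[1L] + seq_len(d[1L]), ] <- arr[, r, ]
  m
}

#' Encode coverage segments
#'
#' Maps per-base coverage vectors through the encoder to their embeddings.
#' Deterministic for fixed parameters.
#'
#' @param model a [PeakModel-class].
#' @param m numeric matrix (segments x alpha) or a single coverage vector.
#' @return Matrix of embeddings (segments x embed_dim).
#' @export
encodeSegments <- function(model, m) {
  m <- .prep_input(model, m)
  .cp_forward(model@params, model@config, m, FALSE)$x
}

.relu <- function(x) pmax(x, 0)

#' Classify embeddings into peak/nonpeak probabilities
#'
#' Applies the MLP head (one hidden layer of the embedding dimension, ReLU,
#' linear output, softmax) to embeddings. Rows of the result lie on the
#' 2-simplex. Columns are in the network's internal class order; use
#' [scoreSegments()] for oriented peak probabilities.
#'
#' @param model a [PeakModel-class].
#' @param x matrix of embeddings (segments x embed_dim) or a single embedding.
#' @return Matrix (segments x 2) of class probabilities.
#' @export
classifyEmbeddings <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model@config$embed_dim)
    stop("embedding dimension does not match the model")
  p <- model@params
  h <- .relu(x %*% t(p$mlp_h_W) + rep(p$mlp_h_b[, 1L], each = nrow(x)))
  z <- h %*% t(p$mlp_o_W) + rep(p$mlp_o_b[, 1L], each = nrow(x))
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Decode embeddings back to coverage space
#'
#' Runs the decoder (linear projection, nearest-neighbour upsampling and the
#' mirrored convolutional modules) to reconstruct per-base coverage.
#'
#' @param model a [PeakModel-class].
#' @param x matrix of embeddings (segments x embed_dim).
#' @return Matrix (segments x alpha) of reconstructions.
#' @export
decodeEmbeddings <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model@config$embed_dim)
    stop("embedding dimension does not match the model")
  .cp_decode(model@params, model@config, x)
}

#' Full forward pass with loss breakdown
#'
#' Encodes, classifies and decodes a segment array, and reports the three
#' losses and their weighted total on that input.
#'
#' @param model a [PeakModel-class].
#' @param arr numeric array \code{S x R x alpha} from [segmentMatrix()].
#' @return List: \code{x} (array S x R x D), \code{q} (array S x R x 2),
#'   \code{mhat} (array S x R x alpha), and \code{losses} from [totalLoss()].
#' @export
modelForward <- function(model, arr) {
  d <- dim(arr)
  S <- d[1L]; R <- d[2L]
  m <- .prep_input(model, .flatten_svd(arr))
  fw <- .cp_forward(model@params, model@config, m, TRUE)
  D <- model@config$embed_dim
  x <- array(0, c(S, R, D)); q <- array(0, c(S, R, 2L))
  mhat <- array(0, c(S, R, d[3L]))
  for (r in seq_len(R)) {
    idx <- (r - 1L) * S + seq_len(S)
    x[, r, ] <- fw$x[idx, , drop = FALSE]
    q[, r, ] <- fw$q[idx, , drop = FALSE]
    mhat[, r, ] <- fw$mhat[idx, , drop = FALSE]
  }
  marr <- arr
  if (model@config$log1p) marr <- log1p(marr)
  l1 <- if (S >= 2 && R >= 2) lossReplicate(x, model@config$tau1) else NA_real_
  l2 <- if (R >= 2) lossClass(q, model@config$tau2) else NA_real_
  l3 <- lossAutoencoder(marr, mhat)
  list(x = x, q = q, mhat = mhat,
       losses = totalLoss(l1, l2, l3, model@config$loss_weights))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the architecture
#' configuration, all parameters, the class orientation and the training
#' history.
#'
#' @param model a [PeakModel-class].
#' @param path checkpoint path.
#' @return \code{writeModel}: invisibly, \code{path}; \code{readModel}: the
#'   restored [PeakModel-class].
#' @export
writeModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               orientation = model@orientation, history = model@history,
               trained = model@trained), path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  ck <- readRDS(path)
  new("PeakModel", config = ck$config, params = ck$params,
      orientation = ck$orientation, history = ck$history, trained = ck$trained)
}
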