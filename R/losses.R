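# The three training losses, in double precision on plain arrays. These are
# the reference implementations used for reporting and testing; the compiled
# training loop computes the same quantities (with gradients) in single
# precision.

.cosine <- function(u, v, floor = 1e-12) {
  sum(u * v) / (max(sqrt(sum(u * u)), floor) * max(sqrt(sum(v * v)), floor))
}

.check_svd <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected an array of dimension S x R x D")
  d
}

#' Replicate contrastive loss
#'
#' The SimCLR-style loss contrasting the same segment across replicates
#' (positive pairs) against different segments (negatives). For every
#' unordered replicate pair (r, r') and segment i the term is
#' \deqn{-\log \frac{\exp(\cos(x_{ri}, x_{r'i})/\tau_1)}
#'                  {\sum_{j \ne i} \exp(\cos(x_{ri}, x_{r'j})/\tau_1)},}
#' averaged over all segments and replicate pairs, and symmetrised by
#' averaging over both anchor directions of each pair (so the loss is
#' invariant under replicate permutation). The denominator runs over
#' negatives only (it excludes the positive term j = i); set
#' \code{ntXent = TRUE} to include it, as in standard NT-Xent.
#'
#' @param x numeric array \code{S x R x D} of embeddings.
#' @param tau1 temperature (default 0.5).
#' @param ntXent include the positive pair in the denominator (default
#'   \code{FALSE}).
#' @return Scalar loss.
#' @export
lossReplicate <- function(x, tau1 = 0.5, ntXent = FALSE) {
  d <- .check_svd(x)
  S <- d[1L]; R <- d[2L]
  if (S < 2L) stop("the replicate contrastive loss needs at least 2 segments")
  if (R < 2L) stop("the replicate contrastive loss needs at least 2 replicates")
  nrm <- sqrt(apply(x^2, c(1, 2), sum))
  if (any(nrm == 0)) stop("zero-norm embedding: cosine similarity undefined")
  total <- 0
  for (r in seq_len(R)) for (rp in seq_len(R)) {
    if (r == rp) next # each unordered pair enters once per anchor direction
    xr <- matrix(x[, r, ], nrow = S); xrp <- matrix(x[, rp, ], nrow = S)
    xr <- xr / sqrt(rowSums(xr^2)); xrp <- xrp / sqrt(rowSums(xrp^2))
    cs <- xr %*% t(xrp) # cs[i, j] = cos(x_ri, x_r'j); anchor is replicate r
    for (i in seq_len(S)) {
      neg <- cs[i, -i] / tau1
      if (ntXent) neg <- c(neg, cs[i, i] / tau1)
      m <- max(neg)
      total <- total - (cs[i, i] / tau1 - (m + log(sum(exp(neg - m)))))
    }
  }
  total / (2 * S * choose(R, 2))
}

#' Class-similarity loss
#'
#' Pushes the per-replicate vectors of class probabilities across segments,
#' \eqn{p_{rk} = (q_{r1k}, ..., q_{rSk})}, to agree between replicates and to
#' oppose their element-wise complements:
#' \deqn{-\frac{1}{2\binom{R}{2}} \sum_{k=1}^{2} \sum_{r' < r}
#'   \frac{\cos(p_{rk}, p_{r'k}) - \cos(p_{rk}, 1 - p_{r'k})}{\tau_2}.}
#' Zero-norm probability vectors are guarded by a small norm floor.
#'
#' @param q numeric array \code{S x R x 2} of class probabilities (rows on the
#'   2-simplex).
#' @param tau2 temperature (default 0.5).
#' @return Scalar loss.
#' @export
lossClass <- function(q, tau2 = 0.5) {
  d <- .check_svd(q)
  R <- d[2L]
  if (d[3L] != 2L) stop("q must have 2 classes in the third dimension")
  if (R < 2L) stop("the class-similarity loss needs at least 2 replicates")
  total <- 0
  for (k in 1:2) for (r in 2:R) for (rp in seq_len(r - 1L)) {
    prk <- q[, r, k]; prpk <- q[, rp, k]
    total <- total - (.cosine(prk, prpk) - .cosine(prk, 1 - prpk)) / tau2
  }
  total / (2 * choose(R, 2))
}

#' Autoencoder reconstruction loss
#'
#' Mean over segments and replicates of the per-segment mean squared error
#' between original and reconstructed coverage.
#'
#' @param m,mhat numeric arrays \code{S x R x alpha} of original and
#'   reconstructed coverage (matching shapes).
#' @return Scalar loss, \code{>= 0}.
#' @export
lossAutoencoder <- function(m, mhat) {
  if (!identical(dim(m), dim(mhat)))
    stop("m and mhat must have identical dimensions")
  mean((m - mhat)^2)
}

#' Total training loss
#'
#' Weighted sum of the three components; the default weights are all one.
#'
#' @param l1,l2,l3 the replicate contrastive, class-similarity and
#'   autoencoder losses.
#' @param weights numeric length-3 multipliers.
#' @return List with the components and the total \code{L}.
#' @export
totalLoss <- function(l1, l2, l3, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L)
  list(l1 = l1, l2 = l2, l3 = l3,
       L = weights[1] * l1 + weights[2] * l2 + weights[3] * l3,
       weights = weights)
}
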