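#' Train the peak model
#'
#' Jointly minimises the replicate contrastive, class-similarity and
#' autoencoder losses over the segment set with Adam. Segments are shuffled
#' every epoch; the replicate rows of a segment always travel together, as
#' both contrastive losses require. A trailing batch of a single segment is
#' dropped with a warning (the contrastive denominators need at least two
#' segments). After the final epoch the peak class is oriented: the softmax
#' column positively associated with mean segment coverage becomes the peak
#' class, fixing the arbitrary class identity of the unsupervised learner.
#' Training is deterministic given the seed (single device).
#'
#' @param model an untrained (or pre-trained) [PeakModel-class].
#' @param arr numeric array \code{S x R x alpha} from [segmentMatrix()].
#' @param epochs training epochs (default 25; 0 returns the model unchanged
#'   apart from orientation).
#' @param batchSize segments per minibatch (default 256; the contrastive
#'   losses are computed within the minibatch).
#' @param lr Adam learning rate (default 1e-4).
#' @param seed integer seed for shuffling (parameter initialisation is seeded
#'   in [peakModel()]).
#' @return The trained [PeakModel-class] with per-epoch loss history.
#' @export
trainModel <- function(model, arr, epochs = 25L, batchSize = 256L,
                       lr = 1e-4, seed = 1L) {
  d <- dim(arr)
  if (length(d) != 3L) stop("expected an S x R x alpha array")
  S <- d[1L]; R <- d[2L]
  if (S < 2L) stop("need at least 2 segments to train")
  if (R < 2L) stop("need at least 2 replicates to train")
  if (epochs < 0L) stop("epochs must be >= 0")
  if (batchSize < 2L) stop("batchSize must be >= 2")
  m <- .prep_input(model, .flatten_svd(arr))
  if (epochs > 0L) {
    res <- .cp_train(model@params, model@config, m, S, R,
                     as.integer(epochs), as.integer(batchSize), lr,
                     as.integer(seed), model@config$loss_weights,
                     model@config$tau1, model@config$tau2)
    if (res$dropped_batches > 0L)
      warning(sprintf("dropped %d single-segment batch(es)", res$dropped_batches))
    if (nrow(res$history) && !all(is.finite(as.matrix(res$history[-1L]))))
      warning("non-finite loss encountered during training")
    model@params <- res$params
    model@history <- res$history
  }
  model@orientation <- .orient_classes(model, m)
  model@trained <- TRUE
  model
}

# peak class = softmax column positively associated with segment coverage
.orient_classes <- function(model, m) {
  q1 <- .cp_forward(model@params, model@config, m, FALSE)$q[, 1L]
  cov_mean <- rowMeans(m)
  if (stats::sd(q1) == 0 || stats::sd(cov_mean) == 0) return(1L)
  if (stats::cor(q1, cov_mean) >= 0) 1L else 2L
}

#' Write the per-epoch training log
#'
#' @param model a trained [PeakModel-class].
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTrainingLog <- function(model, path) {
  utils::write.table(model@history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
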