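#' Per-segment, per-replicate peak scores
#'
#' The peak prediction score of segment i in replicate r is its oriented
#' peak-class probability \eqn{\xi_{ri}}. Deterministic in inference mode.
#'
#' @param model a trained [PeakModel-class].
#' @param arr numeric array \code{S x R x alpha} from [segmentMatrix()].
#' @return Matrix \code{S x R} of scores in \code{[0, 1]}.
#' @export
scoreSegments <- function(model, arr) {
  d <- dim(arr)
  if (length(d) != 3L) stop("expected an S x R x alpha array")
  S <- d[1L]; R <- d[2L]
  m <- .prep_input(model, .flatten_svd(arr))
  q <- .cp_forward(model@params, model@config, m, FALSE)$q
  xi <- matrix(q[, model@orientation], nrow = S, ncol = R)
  dimnames(xi) <- list(NULL, paste0("rep", seq_len(R)))
  xi
}

#' Aggregate segment scores into scored region calls
#'
#' Each candidate region's score is the unweighted mean of \eqn{\xi_{ri}} over
#' all replicates r and all segments i extracted from the region; the region
#' is called a peak when the score strictly exceeds the cutoff. Regions whose
#' segments were all removed (e.g. blacklisted) are dropped with a warning.
#' The full scored list is returned, enabling post hoc thresholding and
#' precision-recall curves.
#'
#' @param xi matrix \code{S x R} of segment scores from [scoreSegments()].
#' @param regionSet the [RegionSet-class] the segments came from.
#' @param cutoff peak-call cutoff on the region score (default 0.5, strict).
#' @return \code{GRanges} of candidate regions with metadata columns
#'   \code{score}, \code{is_peak}, \code{n_segments} and \code{region_id}.
#' @export
aggregateAndCall <- function(xi, regionSet, cutoff = 0.5) {
  segs <- segments(regionSet)
  regions <- candidateRegions(regionSet)
  if (nrow(xi) != length(segs))
    stop("xi rows must match the number of segments in the RegionSet")
  rid <- segs$region_id
  seg_mean <- rowMeans(xi) # mean over replicates for each segment
  score <- vapply(split(seg_mean, rid), mean, 0)
  keep <- as.integer(names(score))
  if (length(keep) < length(regions))
    warning(sprintf("%d region(s) had no scored segments and were dropped",
                    length(regions) - length(keep)))
  out <- regions[keep]
  out$score <- unname(score)
  out$is_peak <- out$score > cutoff
  out$n_segments <- unname(lengths(split(seg_mean, rid)))
  sort(out)
}

#' Call peaks from coverage
#'
#' Convenience wrapper: extracts the segment coverage array, scores segments
#' with the trained model and aggregates to scored region calls.
#'
#' @param model a trained [PeakModel-class].
#' @param cov a [CoverageSet-class].
#' @param regionSet a [RegionSet-class] from [selectRegions()].
#' @param cutoff peak-call cutoff (default 0.5, strict).
#' @return Scored calls as from [aggregateAndCall()].
#' @export
callPeaks <- function(model, cov, regionSet, cutoff = 0.5) {
  arr <- segmentMatrix(cov, segments(regionSet))
  xi <- scoreSegments(model, arr)
  aggregateAndCall(xi, regionSet, cutoff = cutoff)
}
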