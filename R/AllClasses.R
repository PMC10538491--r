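#' CoverageSet: per-base fragment coverage for a replicated experiment
#'
#' Holds one integer-valued [IRanges::RleList] of per-base fragment coverage
#' per replicate, all on the same set of chromosomes. Fragment coverage counts
#' the full span of each properly paired fragment, not individual reads.
#'
#' @slot coverage list of \code{RleList}, one per replicate; each element has
#'   one \code{Rle} per chromosome whose length equals the chromosome size.
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with the chromosome sizes.
#'
#' @aliases CoverageSet
#' @exportClass CoverageSet
setClass("CoverageSet",
  representation(coverage = "list", seqinfo = "Seqinfo"))

setValidity("CoverageSet", function(object) {
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (length(object@coverage) < 1L)
    return("at least one replicate is required")
  for (r in seq_along(object@coverage)) {
    cv <- object@coverage[[r]]
    if (!is(cv, "RleList"))
      return(sprintf("replicate %d coverage is not an RleList", r))
    if (!setequal(names(cv), names(sl)))
      return(sprintf("replicate %d chromosomes do not match seqinfo", r))
    for (chr in names(sl)) {
      if (length(cv[[chr]]) != sl[[chr]])
        return(sprintf("replicate %d, %s: track length %d != chromosome size %d",
                       r, chr, length(cv[[chr]]), sl[[chr]]))
      if (any(S4Vectors::runValue(cv[[chr]]) < 0))
        return(sprintf("replicate %d, %s: negative coverage", r, chr))
    }
  }
  TRUE
})

#' Construct a CoverageSet
#'
#' @param coverage list of \code{RleList} per-replicate coverage tracks.
#' @param seqinfo a \code{Seqinfo} (or named integer vector of chromosome
#'   sizes) describing the genome.
#' @return A [CoverageSet-class] object.
#' @examples
#' sizes <- c(chr1 = 100L)
#' trk <- IRanges::RleList(chr1 = S4Vectors::Rle(0L, 100L))
#' CoverageSet(list(trk, trk), sizes)
#' @export
CoverageSet <- function(coverage, seqinfo) {
  if (!is(seqinfo, "Seqinfo"))
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(seqinfo),
                                     seqlengths = as.integer(seqinfo))
  if (is.null(names(coverage)))
    names(coverage) <- paste0("rep", seq_along(coverage))
  new("CoverageSet", coverage = coverage, seqinfo = seqinfo)
}

#' @describeIn CoverageSet-class number of replicates
#' @param x,object a \code{CoverageSet}
#' @export
nReplicates <- function(x) length(x@coverage)

#' @describeIn CoverageSet-class coverage track (RleList) of one replicate
#' @param r replicate index
#' @export
replicateCoverage <- function(x, r) x@coverage[[r]]

#' @describeIn CoverageSet-class element-wise sum of the replicate tracks,
#'   equivalent to the coverage of pooled fragments
#' @export
mergedCoverage <- function(x) Reduce(`+`, x@coverage)

setMethod("show", "CoverageSet", function(object) {
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  cat(sprintf("CoverageSet: %d replicate(s), %d chromosome(s), %g bp\n",
              length(object@coverage), length(sl), sum(as.numeric(sl))))
  mns <- vapply(object@coverage, function(cv)
    sum(vapply(cv, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                     S4Vectors::runLength(x)), 0)) /
      sum(as.numeric(sl)), 0)
  cat("  mean coverage per replicate:", paste(signif(mns, 3), collapse = ", "), "\n")
})

#' RegionSet: candidate peak regions and their fixed-length segments
#'
#' The output of [selectRegions()]: the variable-length candidate regions
#' (set A) surviving thresholding, merging and length filtering, together with
#' the alpha-length segments extracted from them (which may extend beyond
#' their region) and the resolved per-chromosome coverage thresholds.
#'
#' @slot regions \code{GRanges} of candidate regions; metadata column
#'   \code{region_id}.
#' @slot segments \code{GRanges} of alpha-length segments; metadata column
#'   \code{region_id} links each segment to its region.
#' @slot alpha integer segment length.
#' @slot threshold named numeric vector, resolved coverage threshold per
#'   chromosome.
#'
#' @aliases RegionSet
#' @exportClass RegionSet
setClass("RegionSet",
  representation(regions = "GRanges", segments = "GRanges",
                 alpha = "integer", threshold = "numeric"))

setValidity("RegionSet", function(object) {
  if (length(object@segments) &&
      !all(IRanges::width(object@segments) == object@alpha))
    return("all segments must have width alpha")
  if (length(object@segments) && is.null(object@segments$region_id))
    return("segments need a region_id metadata column")
  TRUE
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf(
    "RegionSet: %d candidate region(s), %d segment(s) of %d bp\n",
    length(object@regions), length(object@segments), object@alpha))
  cat("  thresholds:",
      paste(names(object@threshold), signif(object@threshold, 3),
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn RegionSet-class the candidate regions (set A)
#' @param x,object a \code{RegionSet}
#' @export
candidateRegions <- function(x) x@regions

#' @describeIn RegionSet-class the alpha-length segments
#' @export
segments <- function(x) x@segments

#' @describeIn RegionSet-class the resolved per-chromosome thresholds
#' @export
thresholds <- function(x) x@threshold

#' PeakModel: the replicate-contrastive network
#'
#' A trained (or freshly initialised) encoder/MLP/decoder network. Parameters
#' are plain numeric matrices so the object is self-describing and
#' serialisable; \code{orientation} records which softmax column is the peak
#' class (fixed after training by association with segment coverage).
#'
#' @slot config list of architecture and loss hyperparameters (alpha,
#'   channels, kernel_size, dilation, n_modules, pool_out, embed_dim, tau1,
#'   tau2, loss_weights, log1p).
#' @slot params named list of parameter matrices.
#' @slot orientation integer, 1 or 2: softmax column used as the peak class.
#' @slot history data.frame of per-epoch batch-averaged losses
#'   (l1, l2, l3, L).
#' @slot trained logical.
#'
#' @aliases PeakModel
#' @exportClass PeakModel
setClass("PeakModel",
  representation(config = "list", params = "list", orientation = "integer",
                 history = "data.frame", trained = "logical"))

setMethod("show", "PeakModel", function(object) {
  cf <- object@config
  cat(sprintf(
    "PeakModel: alpha=%d, %d modules x %d channels, kernel %d (dilation %d), embed dim %d\n",
    cf$alpha, cf$n_modules, cf$channels, cf$kernel_size, cf$dilation, cf$embed_dim))
  if (object@trained)
    cat(sprintf("  trained: %d epoch(s), final total loss %.4f (peak class: column %d)\n",
                nrow(object@history), utils::tail(object@history$L, 1),
                object@orientation))
  else cat("  untrained (random initialisation)\n")
})

#' @describeIn PeakModel-class per-epoch loss history
#' @param x,object a \code{PeakModel}
#' @export
lossHistory <- function(x) x@history

#' @describeIn PeakModel-class model configuration list
#' @export
modelConfig <- function(x) x@config
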