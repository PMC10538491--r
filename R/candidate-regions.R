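# Candidate-region selection: threshold covered positions in every replicate,
# aggregate and merge nearby runs, keep regions longer than a minimum, then
# extract fixed-length segments centred on regions (or on their coverage
# summits for long regions).

.weighted_median_rle <- function(x, nonzero = TRUE) {
  v <- as.numeric(S4Vectors::runValue(x))
  w <- as.numeric(S4Vectors::runLength(x))
  if (nonzero) { w <- w[v > 0]; v <- v[v > 0] }
  if (!length(v)) return(NA_real_)
  o <- order(v); v <- v[o]; w <- w[o]
  n <- sum(w)
  cw <- cumsum(w)
  if (n %% 2 == 1) {
    v[which(cw >= (n + 1) / 2)[1L]]
  } else {
    lo <- v[which(cw >= n / 2)[1L]]
    hi <- v[which(cw >= n / 2 + 1)[1L]]
    (lo + hi) / 2
  }
}

#' Resolve the coverage threshold
#'
#' Resolves the coverage threshold \code{t} used to retain genome positions.
#' With \code{mode = "median"}, for every chromosome each replicate's median
#' coverage over its nonzero positions is computed, and the minimum of those
#' medians across replicates is the chromosome's threshold. With an integer
#' \code{mode}, that value is used for every chromosome. Chromosomes where any
#' replicate has all-zero coverage get \code{t = 1} with a warning.
#'
#' @param cov a [CoverageSet-class].
#' @param mode \code{"median"} or a single positive number.
#' @return Named numeric vector: threshold per chromosome, all \code{>= 1};
#'   attribute \code{mode} records the request.
#' @export
resolveThreshold <- function(cov, mode = "median") {
  chroms <- names(GenomeInfoDb::seqlengths(cov@seqinfo))
  if (nReplicates(cov) < 2L)
    warning("fewer than 2 replicates: thresholds resolved from a single track")
  if (is.numeric(mode)) {
    if (length(mode) != 1L || is.na(mode) || mode <= 0)
      stop("fixed threshold must be a single positive number")
    tt <- stats::setNames(rep(as.numeric(mode), length(chroms)), chroms)
  } else if (identical(mode, "median")) {
    tt <- vapply(chroms, function(chr) {
      med <- vapply(cov@coverage,
                    function(cv) .weighted_median_rle(cv[[chr]]), 0)
      if (anyNA(med)) {
        warning(sprintf("%s: all-zero coverage in some replicate; threshold set to 1", chr))
        1
      } else min(med)
    }, 0)
  } else stop("mode must be \"median\" or a positive number")
  attr(tt, "mode") <- mode
  tt
}

#' Select positions covered above threshold in every replicate
#'
#' Returns the maximal runs of genome positions whose coverage is strictly
#' greater than the chromosome's threshold in all replicates.
#'
#' @param cov a [CoverageSet-class].
#' @param threshold named per-chromosome numeric vector from
#'   [resolveThreshold()], or a single number.
#' @return \code{GRanges} of covered runs (possibly empty).
#' @export
selectCoveredIntervals <- function(cov, threshold) {
  chroms <- names(GenomeInfoDb::seqlengths(cov@seqinfo))
  if (length(threshold) == 1L && is.null(names(threshold)))
    threshold <- stats::setNames(rep(threshold, length(chroms)), chroms)
  grl <- lapply(chroms, function(chr) {
    mask <- Reduce(`&`, lapply(cov@coverage,
                               function(cv) cv[[chr]] > threshold[[chr]]))
    ir <- methods::as(mask, "IRanges") # runs of TRUE
    GenomicRanges::GRanges(rep(chr, length(ir)), ir)
  })
  gr <- do.call(c, grl)
  GenomeInfoDb::seqlevels(gr) <- chroms
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- cov@seqinfo)
  gr
}

#' Merge nearby intervals and drop short regions
#'
#' Merges intervals separated by at most \code{mergeGap} bp (transitively) and
#' retains merged regions strictly longer than \code{minLen} bp. The defaults
#' reflect DNA linker lengths (8-90 bp) and a minimal region of interest of
#' just over 100 bp.
#'
#' @param intervals \code{GRanges} of covered runs.
#' @param mergeGap maximum gap (bp) across which intervals are merged.
#' @param minLen regions must be strictly longer than this many bp.
#' @return \code{GRanges}: the candidate regions (set A), sorted.
#' @export
mergeAndFilter <- function(intervals, mergeGap = 90L, minLen = 100L) {
  merged <- GenomicRanges::reduce(sort(intervals), min.gapwidth = mergeGap + 1L)
  merged[width(merged) > minLen]
}

# segment of length alpha centred on 0-based midpoint mid0, clipped into
# [0, chromLen); returns 1-based start
.centered_segment_start <- function(mid0, alpha, chromLen) {
  s0 <- mid0 - alpha %/% 2L
  s0 <- pmax(0, pmin(s0, chromLen - alpha))
  s0 + 1
}

#' Extract fixed-length segments from candidate regions
#'
#' For a region shorter than \code{alpha}, one segment of length \code{alpha}
#' is centred at the region midpoint (extending \code{floor(alpha/2)} bp
#' upstream). For longer regions, positions whose across-replicate summed
#' coverage reaches the 0.95 quantile of that coverage over the region are
#' clustered (positions within \code{alpha} bp of each other are merged) and
#' one segment is centred at each cluster midpoint. Segments may extend beyond
#' their region; segments extending past a chromosome end are shifted inward.
#'
#' @param regions \code{GRanges} of candidate regions (set A).
#' @param mergedCov \code{RleList}: across-replicate summed coverage, e.g.
#'   \code{mergedCoverage(cov)}.
#' @param alpha segment length in bp (must not exceed any used chromosome).
#' @return \code{GRanges} of segments with a \code{region_id} metadata column
#'   (index into \code{regions}).
#' @export
extractSegments <- function(regions, mergedCov, alpha = 1000L) {
  alpha <- as.integer(alpha)
  if (!length(regions)) {
    out <- GenomicRanges::GRanges()
    out$region_id <- integer()
    return(out)
  }
  segs <- vector("list", length(regions))
  chromLens <- vapply(mergedCov, length, 0L)
  for (i in seq_along(regions)) {
    chr <- as.character(GenomeInfoDb::seqnames(regions)[i])
    cl <- chromLens[[chr]]
    if (alpha > cl)
      stop(sprintf("alpha (%d) exceeds the length of %s (%d)", alpha, chr, cl))
    s1 <- start(regions)[i]; e1 <- end(regions)[i]
    if (width(regions)[i] < alpha) {
      mid0 <- (s1 - 1 + e1) %/% 2
      st <- .centered_segment_start(mid0, alpha, cl)
    } else {
      vals <- as.numeric(S4Vectors::window(mergedCov[[chr]], s1, e1))
      q95 <- stats::quantile(vals, 0.95, type = 7, names = FALSE)
      pos <- which(vals >= q95) + s1 - 1L # 1-based genome positions
      brk <- c(0L, which(diff(pos) > alpha), length(pos))
      mid0 <- vapply(seq_len(length(brk) - 1L), function(k) {
        p <- pos[(brk[k] + 1L):brk[k + 1L]]
        (min(p) - 1 + max(p)) %/% 2
      }, 0)
      st <- .centered_segment_start(mid0, alpha, cl)
    }
    segs[[i]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = st, width = alpha),
                                        region_id = i)
  }
  out <- do.call(c, segs)
  GenomeInfoDb::seqlevels(out) <- names(chromLens)
  out
}

#' Remove blacklisted segments
#'
#' Drops every segment that overlaps a blacklist interval by at least 1 bp.
#'
#' @param segs \code{GRanges} of segments.
#' @param blacklist \code{GRanges} of blacklist intervals (or \code{NULL}).
#' @return The retained segments.
#' @export
removeBlacklisted <- function(segs, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0L || length(segs) == 0L)
    return(segs)
  bl <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(blacklist)),
                               IRanges::ranges(blacklist))
  sq <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(segs)),
                               IRanges::ranges(segs))
  hits <- GenomicRanges::findOverlaps(sq, bl, minoverlap = 1L)
  keep <- setdiff(seq_along(segs), S4Vectors::queryHits(hits))
  segs[keep]
}

#' Select candidate regions and segments
#'
#' Runs the full region-selection procedure: resolve the coverage threshold,
#' retain positions covered above it in every replicate, merge nearby runs and
#' keep regions longer than \code{minLen} (set A), extract \code{alpha}-length
#' segments, and remove blacklisted segments.
#'
#' @param cov a [CoverageSet-class].
#' @param threshold \code{"median"} or a positive number.
#' @param mergeGap,minLen see [mergeAndFilter()].
#' @param alpha segment length in bp.
#' @param blacklist optional \code{GRanges} of blacklist intervals.
#' @return A [RegionSet-class].
#' @export
selectRegions <- function(cov, threshold = "median", mergeGap = 90L,
                          minLen = 100L, alpha = 1000L, blacklist = NULL) {
  tt <- resolveThreshold(cov, threshold)
  covered <- selectCoveredIntervals(cov, tt)
  regions <- mergeAndFilter(covered, mergeGap = mergeGap, minLen = minLen)
  regions$region_id <- seq_along(regions)
  segs <- extractSegments(regions, mergedCoverage(cov), alpha = alpha)
  segs <- removeBlacklisted(segs, blacklist)
  new("RegionSet", regions = regions, segments = segs,
      alpha = as.integer(alpha), threshold = tt)
}

#' Per-segment coverage matrix
#'
#' Extracts the per-base coverage of every segment in every replicate as the
#' network input array.
#'
#' @param cov a [CoverageSet-class].
#' @param segs \code{GRanges} of alpha-length segments (e.g.
#'   \code{segments(regionSet)}).
#' @return Numeric array of dimension \code{S x R x alpha} (segments x
#'   replicates x positions).
#' @export
segmentMatrix <- function(cov, segs) {
  S <- length(segs); R <- nReplicates(cov)
  if (S == 0L) stop("no segments to extract")
  alpha <- unique(width(segs))
  if (length(alpha) != 1L) stop("segments must share one length")
  arr <- array(0, dim = c(S, R, alpha))
  chr <- as.character(GenomeInfoDb::seqnames(segs))
  for (r in seq_len(R)) {
    cv <- cov@coverage[[r]]
    for (i in seq_len(S))
      arr[i, r, ] <- as.numeric(S4Vectors::window(cv[[chr[i]]],
                                                  start(segs)[i], end(segs)[i]))
  }
  arr
}
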