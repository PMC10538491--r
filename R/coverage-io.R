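#' Read chromosome sizes
#'
#' Reads a two-column text file (chromosome name, length in bp) as produced by
#' \code{samtools faidx} / UCSC \code{chrom.sizes}.
#'
#' @param path path to a two-column whitespace-separated file.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom.sizes file needs two columns: name, length")
  sizes <- as.integer(tab[[2L]])
  if (any(is.na(sizes)) || any(sizes <= 0L))
    stop("chrom.sizes lengths must be positive integers")
  stats::setNames(sizes, as.character(tab[[1L]]))
}

.rle_from_bedgraph <- function(gr, sizes) {
  unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))), names(sizes))
  if (length(unknown))
    stop("BedGraph contains chromosome(s) not in chrom.sizes: ",
         paste(unknown, collapse = ", "))
  out <- IRanges::RleList(lapply(names(sizes), function(chr) {
    g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chr]
    v <- S4Vectors::Rle(0, sizes[[chr]])
    if (length(g)) {
      if (max(end(g)) > sizes[[chr]])
        stop(sprintf("BedGraph interval ends beyond %s (%d bp)", chr, sizes[[chr]]))
      g <- sort(g)
      v[IRanges::ranges(g)] <- S4Vectors::Rle(g$score, width(g))
    }
    v
  }), compress = FALSE)
  names(out) <- names(sizes)
  out
}

.fragments_from_bam <- function(path, sizes) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("flag", "rname", "pos", "isize"))
  rec <- Rsamtools::scanBam(path, param = param)[[1L]]
  n_total <- length(rec$pos)
  flag <- rec$flag
  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  if (n_total > 0L && !any(paired))
    stop("no paired reads in ", path,
         ": single-end input is not supported (fragment coverage needs mate pairs)")
  # keep the leftmost mate of each properly paired fragment (isize > 0)
  keep <- paired & proper & !is.na(rec$isize) & rec$isize > 0L
  n_skipped <- n_total - 2L * sum(keep) # mates of kept reads are not skipped
  if (n_skipped > 0L)
    message(sprintf("%s: skipped %d unpaired/improper/secondary record(s)",
                    basename(path), n_skipped))
  chrom <- as.character(rec$rname[keep])
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown))
    stop("BAM contains chromosome(s) not in chrom.sizes: ",
         paste(unknown, collapse = ", "))
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = rec$pos[keep], width = rec$isize[keep]),
    seqinfo = GenomeInfoDb::Seqinfo(names(sizes), sizes))
}

.rle_from_fragments <- function(frags, sizes) {
  if (length(frags) &&
      any(end(frags) > sizes[as.character(GenomeInfoDb::seqnames(frags))]))
    stop("fragment extends beyond chromosome end")
  cov <- GenomicRanges::coverage(frags)
  out <- IRanges::RleList(lapply(names(sizes), function(chr) cov[[chr]]),
                            compress = FALSE)
  names(out) <- names(sizes)
  out
}

#' Read per-replicate fragment coverage
#'
#' Builds per-base fragment-coverage tracks for each replicate from
#' coordinate-sorted paired-end BAM files or from BedGraph tracks. For BAM
#' input, each properly paired fragment increments coverage by one over its
#' full insert span (both mates and the gap between them), matching
#' \code{bedtools genomecov -pc}; unpaired, improperly paired, secondary and
#' unmapped records are skipped with a reported count. Single-end BAMs are
#' rejected. BedGraph input is expanded to per-base values, with bases not
#' covered by any interval set to zero.
#'
#' @param files character vector of input paths, one per replicate.
#' @param chromSizes named integer vector of chromosome sizes, or path to a
#'   two-column chrom.sizes file.
#' @param format \code{"auto"} (by extension), \code{"bam"} or
#'   \code{"bedgraph"}.
#' @return A [CoverageSet-class].
#' @export
readCoverage <- function(files, chromSizes, format = c("auto", "bam", "bedgraph")) {
  format <- match.arg(format)
  if (is.character(chromSizes) && length(chromSizes) == 1L && file.exists(chromSizes))
    chromSizes <- readChromSizes(chromSizes)
  sizes <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  tracks <- lapply(files, function(f) {
    fmt <- format
    if (fmt == "auto")
      fmt <- if (grepl("\\.bam$", f, ignore.case = TRUE)) "bam" else "bedgraph"
    if (fmt == "bam") {
      .rle_from_fragments(.fragments_from_bam(f, sizes), sizes)
    } else {
      gr <- rtracklayer::import(f, format = "bedGraph")
      .rle_from_bedgraph(gr, sizes)
    }
  })
  CoverageSet(tracks, sizes)
}

#' Write per-replicate coverage as BedGraph
#'
#' @param cov a [CoverageSet-class].
#' @param paths character vector of output paths, one per replicate.
#' @return Invisibly, \code{paths}.
#' @export
writeCoverageBedGraph <- function(cov, paths) {
  stopifnot(length(paths) == nReplicates(cov))
  sl <- GenomeInfoDb::seqlengths(cov@seqinfo)
  for (r in seq_along(paths)) {
    cv <- cov@coverage[[r]]
    grl <- lapply(names(cv), function(chr) {
      x <- cv[[chr]]
      GenomicRanges::GRanges(chr,
        IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(x)))[
          seq_along(S4Vectors::runLength(x))],
          width = S4Vectors::runLength(x)),
        score = as.numeric(S4Vectors::runValue(x)))
    })
    gr <- do.call(c, grl)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- cov@seqinfo)
    rtracklayer::export(gr, paths[r], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a BED interval file
#'
#' Parses a BED3+ file into a \code{GRanges}, preserving file order. BED is
#' 0-based half-open; coordinates are converted to the 1-based closed
#' convention of \code{GRanges}. Malformed lines raise an error that reports
#' the offending line number.
#'
#' @param path path to a BED file (3 or more tab/space separated columns).
#' @return \code{GRanges} in file order; a \code{name} metadata column is kept
#'   when a fourth column is present, a numeric \code{score} when a fifth is.
#' @export
readIntervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad))
    stop("malformed BED line ", bad[1L],
         ": need numeric 0 <= start < end, got '", lines[bad[1L]], "'")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0))
  if (all(nf >= 4L)) gr$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  gr
}

#' Write scored calls as BED6
#'
#' Writes intervals with scores as six-column BED (chrom, start, end, name,
#' score, strand \code{"."}). Scores are serialised with six decimal places;
#' output is sorted by chromosome then start; names are \code{peak_1},
#' \code{peak_2}, ... in output order.
#'
#' @param calls \code{GRanges} with a numeric \code{score} metadata column in
#'   \code{[0, 1]}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeScoredBed <- function(calls, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(calls) == 0L) return(invisible(path))
  score <- calls$score
  if (is.null(score)) stop("calls need a 'score' metadata column")
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  o <- order(as.character(GenomeInfoDb::seqnames(calls)), start(calls))
  calls <- calls[o]
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%.6f\t.",
                   as.character(GenomeInfoDb::seqnames(calls)),
                   start(calls) - 1L, end(calls),
                   seq_along(calls), calls$score)
  writeLines(lines, con)
  invisible(path)
}
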