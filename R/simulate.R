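# Fragment-level ATAC-seq simulator with planted peaks. Coverage is produced
# by placing discrete paired-end fragments and computing their pileup, so
# fragment-coverage semantics, BedGraph round trips and within-peak summit
# structure are all exercised realistically.

#' Simulation configuration
#'
#' Defaults describe a small but realistic multi-replicate ATAC-seq
#' experiment: a 2 Mb genome with 200 planted accessible regions of 200-600
#' bp, background fragment coverage 1x, eightfold enrichment at peaks with a
#' triangular within-peak profile (summit at the center), three replicates at
#' moderately unequal depths, and nucleosome-free fragment lengths around
#' 120 bp.
#'
#' @param genome_length chromosome length in bp (per chromosome).
#' @param n_chroms number of chromosomes (named chr1, chr2, ...).
#' @param n_peaks planted peaks per chromosome.
#' @param peak_width_range min/max peak width (bp).
#' @param background_rate mean background fragment coverage per base.
#' @param enrichment mean fold-increase of coverage inside peaks (>= 1).
#' @param replicate_depths per-replicate depth scaling factors (length R).
#' @param fragment_length_mean,fragment_length_sd fragment length
#'   distribution (Gaussian, truncated below at 20 bp).
#' @param seed integer seed; simulation is deterministic given the seed.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(genome_length = 2e6, n_chroms = 1L, n_peaks = 200L,
                      peak_width_range = c(200L, 600L), background_rate = 1,
                      enrichment = 8, replicate_depths = c(1, 0.8, 1.2),
                      fragment_length_mean = 120, fragment_length_sd = 40,
                      seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_chroms = as.integer(n_chroms), n_peaks = as.integer(n_peaks),
              peak_width_range = as.integer(peak_width_range),
              background_rate = background_rate, enrichment = enrichment,
              replicate_depths = as.numeric(replicate_depths),
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd, seed = as.integer(seed))
  if (cfg$background_rate <= 0) stop("background_rate must be positive")
  if (cfg$enrichment < 1) stop("enrichment must be >= 1")
  if (length(cfg$peak_width_range) != 2L ||
      cfg$peak_width_range[1L] > cfg$peak_width_range[2L])
    stop("peak_width_range must be an increasing pair")
  if (any(cfg$replicate_depths <= 0)) stop("replicate depths must be positive")
  if (cfg$n_peaks * cfg$peak_width_range[2L] >= cfg$genome_length)
    stop("peaks cannot be placed without overlap: genome too small")
  class(cfg) <- "SimConfig"
  cfg
}

# n non-overlapping intervals with the given widths on [1, L], uniform gaps
.place_nonoverlapping <- function(n, widths, L) {
  free <- L - sum(widths)
  if (free < n) stop("peaks cannot be placed without overlap")
  cuts <- sort(runif(n, 0, free))
  starts <- floor(cuts) + cumsum(c(0, widths[-n])) + 1
  IRanges::IRanges(start = as.integer(starts), width = widths)
}

.trunc_frag_lengths <- function(n, mean, sd, lo = 20L) {
  len <- round(rnorm(n, mean, sd))
  bad <- len < lo
  while (any(bad)) {
    len[bad] <- round(rnorm(sum(bad), mean, sd))
    bad <- len < lo
  }
  as.integer(len)
}

#' Simulate replicated ATAC-seq fragment coverage with planted peaks
#'
#' Peaks are placed uniformly without overlap, identically across replicates.
#' Background fragments are placed uniformly at a rate giving expected
#' per-base coverage \code{depth_r * background_rate}; inside peaks, extra
#' fragments with triangular-density midpoints raise expected coverage to
#' \code{depth_r * background_rate * enrichment} on average over the peak,
#' peaking at the region center. Fragment lengths are Gaussian, truncated
#' below. Deterministic given \code{config$seed}.
#'
#' @param config a [simConfig()] list.
#' @return List: \code{coverage} (a [CoverageSet-class]), \code{truth}
#'   (\code{GRanges} of planted peaks), \code{config}.
#' @export
simulateAtac <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  L <- config$genome_length
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(L, config$n_chroms), chroms)
  R <- length(config$replicate_depths)
  flen <- config$fragment_length_mean

  truth_list <- lapply(chroms, function(chr) {
    w <- as.integer(round(runif(config$n_peaks, config$peak_width_range[1L],
                                config$peak_width_range[2L])))
    GenomicRanges::GRanges(chr, .place_nonoverlapping(config$n_peaks, w, L))
  })
  truth <- sort(do.call(c, truth_list))
  GenomeInfoDb::seqlevels(truth) <- chroms

  tracks <- lapply(seq_len(R), function(r) {
    depth <- config$replicate_depths[r]
    per_chrom <- lapply(chroms, function(chr) {
      pk <- IRanges::ranges(truth[as.character(GenomeInfoDb::seqnames(truth)) == chr])
      # background fragments: rate chosen so E[coverage] = depth * background
      n_bg <- rpois(1L, depth * config$background_rate * L / flen)
      bg_start <- as.integer(floor(runif(n_bg, 1, L + 1)))
      bg_len <- .trunc_frag_lengths(n_bg, flen, config$fragment_length_sd)
      # peak fragments: triangular midpoint density, mean excess (e-1)*bg
      starts <- IRanges::start(pk); widths <- IRanges::width(pk)
      n_pk <- rpois(length(pk), depth * config$background_rate *
                      (config$enrichment - 1) * widths / flen)
      pk_mid <- unlist(lapply(seq_along(pk), function(k) {
        if (n_pk[k] == 0L) return(integer())
        u <- (runif(n_pk[k]) + runif(n_pk[k])) / 2
        as.integer(floor(starts[k] + u * (widths[k] - 1)))
      }))
      n_all <- n_bg + length(pk_mid)
      len <- c(bg_len, .trunc_frag_lengths(length(pk_mid), flen,
                                           config$fragment_length_sd))
      st <- c(bg_start, as.integer(pk_mid - len[(n_bg + 1L):n_all] %/% 2L))
      en <- pmin.int(st + len - 1L, L)
      st <- pmax.int(st, 1L)
      frags <- IRanges::IRanges(start = st, end = en)
      cv <- IRanges::coverage(frags, width = L)
      cv
    })
    names(per_chrom) <- chroms
    IRanges::RleList(per_chrom, compress = FALSE)
  })

  list(coverage = CoverageSet(tracks, sizes), truth = truth, config = config)
}

#' Write simulation outputs to disk
#'
#' Writes one BedGraph per replicate, the truth BED and a chrom.sizes file.
#'
#' @param sim result of [simulateAtac()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  R <- nReplicates(sim$coverage)
  bg <- file.path(dir, sprintf("rep%d.bedgraph", seq_len(R)))
  writeCoverageBedGraph(sim$coverage, bg)
  truth_bed <- file.path(dir, "truth_peaks.bed")
  tr <- sim$truth
  lines <- sprintf("%s\t%d\t%d\tpeak_%d",
                   as.character(GenomeInfoDb::seqnames(tr)),
                   start(tr) - 1L, end(tr), seq_along(tr))
  writeLines(lines, truth_bed)
  sizes_file <- file.path(dir, "chrom.sizes")
  sl <- GenomeInfoDb::seqlengths(sim$coverage@seqinfo)
  writeLines(sprintf("%s\t%d", names(sl), sl), sizes_file)
  invisible(c(bg, truth_bed, sizes_file))
}
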