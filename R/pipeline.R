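# End-to-end orchestration: selection -> training -> calling, with per-stage
# seeds derived from one master seed, structured one-line-per-stage logging
# and a JSON run manifest recording every resolved parameter.

.derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage) %% 2147483647)
}

#' Pipeline configuration
#'
#' Collects all inputs and resolved parameters of a full run. Either
#' \code{input_files} (BAM or BedGraph, one per replicate, with
#' \code{chrom_sizes}) or a \code{sim} configuration must be given.
#'
#' @param input_files character vector of per-replicate BAM/BedGraph paths
#'   (or \code{NULL} to simulate).
#' @param chrom_sizes named integer vector or path to a chrom.sizes file.
#' @param blacklist optional BED path (or \code{GRanges}) of blacklist
#'   regions.
#' @param sim optional [simConfig()] list used when \code{input_files} is
#'   \code{NULL}.
#' @param out_dir output directory.
#' @param threshold \code{"median"} or a positive number (coverage threshold
#'   t).
#' @param alpha segment length in bp (must exceed \code{min_len}).
#' @param merge_gap,min_len region merging gap and minimum length (bp).
#' @param epochs,batch_size,lr training parameters.
#' @param cutoff peak-call cutoff on the region score.
#' @param model_args list of extra arguments to [peakModel()].
#' @param seed master seed; stage seeds are derived from it.
#' @param dump_regions also write candidate regions and segments as BED.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(input_files = NULL, chrom_sizes = NULL,
                           blacklist = NULL, sim = NULL, out_dir = "peakcall_out",
                           threshold = "median", alpha = 1000L,
                           merge_gap = 90L, min_len = 100L, epochs = 25L,
                           batch_size = 256L, lr = 1e-4, cutoff = 0.5,
                           model_args = list(), seed = 1L,
                           dump_regions = FALSE) {
  if (is.null(input_files) && is.null(sim))
    stop("either input_files or a sim configuration is required")
  if (!is.null(input_files) && is.null(chrom_sizes))
    stop("chrom_sizes is required with input_files")
  alpha <- as.integer(alpha)
  if (alpha <= min_len)
    stop("alpha must exceed min_len for segments to cover whole regions")
  cfg <- list(input_files = input_files, chrom_sizes = chrom_sizes,
              blacklist = blacklist, sim = sim, out_dir = out_dir,
              threshold = threshold, alpha = alpha,
              merge_gap = as.integer(merge_gap), min_len = as.integer(min_len),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, cutoff = cutoff, model_args = model_args,
              seed = as.integer(seed), dump_regions = isTRUE(dump_regions))
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  res
}

#' Run the full peak-calling pipeline
#'
#' Executes (optionally) simulation, region selection, model training and
#' peak calling; persists every stage's artifacts under \code{out_dir}
#' (scored BED of all candidate regions, filtered peak BED, training log,
#' model checkpoint and a JSON manifest with all resolved parameters, derived
#' seeds and stage counts). With fewer than two replicates a loud warning is
#' emitted; contrastive training then cannot proceed.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with \code{calls} (scored \code{GRanges}),
#'   \code{regions} (the [RegionSet-class]), \code{model}, \code{manifest},
#'   and \code{truth} when simulated.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- do.call(pipelineConfig, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(sim = .derive_seed(config$seed, 1L),
                init = .derive_seed(config$seed, 2L),
                train = .derive_seed(config$seed, 3L))
  truth <- NULL

  if (is.null(config$input_files)) {
    simcfg <- config$sim
    if (!inherits(simcfg, "SimConfig")) {
      simcfg$seed <- seeds$sim
      simcfg <- do.call(simConfig, simcfg)
    }
    sim <- .stage("simulate", simulateAtac(simcfg))
    cov <- sim$coverage; truth <- sim$truth
    message(sprintf("[simulate] %d replicate(s), %d planted peak(s)",
                    nReplicates(cov), length(truth)))
  } else {
    cov <- .stage("read", readCoverage(config$input_files, config$chrom_sizes))
    message(sprintf("[read] %d replicate(s) from %d file(s)",
                    nReplicates(cov), length(config$input_files)))
  }
  if (nReplicates(cov) < 2L)
    warning("only one replicate: replicate-contrastive learning is not possible; ",
            "results will be unreliable", immediate. = TRUE)

  blacklist <- config$blacklist
  if (is.character(blacklist)) blacklist <- readIntervals(blacklist)

  rs <- .stage("select",
               selectRegions(cov, threshold = config$threshold,
                             mergeGap = config$merge_gap, minLen = config$min_len,
                             alpha = config$alpha, blacklist = blacklist))
  message(sprintf("[select] %d candidate region(s), %d segment(s), thresholds: %s",
                  length(candidateRegions(rs)), length(segments(rs)),
                  paste(signif(thresholds(rs), 3), collapse = ",")))

  arr <- .stage("extract", segmentMatrix(cov, segments(rs)))
  model <- .stage("train", {
    margs <- c(list(alpha = config$alpha, seed = seeds$init), config$model_args)
    mdl <- do.call(peakModel, margs)
    trainModel(mdl, arr, epochs = config$epochs,
               batchSize = config$batch_size, lr = config$lr,
               seed = seeds$train)
  })
  message(sprintf("[train] %d epoch(s), final loss %s", config$epochs,
                  if (nrow(model@history)) sprintf("%.4f", utils::tail(model@history$L, 1))
                  else "NA"))

  calls <- .stage("call", {
    xi <- scoreSegments(model, arr)
    aggregateAndCall(xi, rs, cutoff = config$cutoff)
  })
  peaks <- calls[calls$is_peak]
  message(sprintf("[call] %d scored region(s), %d peak(s) at cutoff %g",
                  length(calls), length(peaks), config$cutoff))

  scored_bed <- file.path(config$out_dir, "scored_regions.bed")
  peaks_bed <- file.path(config$out_dir, "peaks.bed")
  writeScoredBed(calls, scored_bed)
  writeScoredBed(peaks, peaks_bed)
  writeTrainingLog(model, file.path(config$out_dir, "training_log.tsv"))
  writeModel(model, file.path(config$out_dir, "model.rds"))
  if (config$dump_regions) {
    rtracklayer::export(candidateRegions(rs),
                        file.path(config$out_dir, "candidate_regions.bed"))
    rtracklayer::export(segments(rs), file.path(config$out_dir, "segments.bed"))
  }
  if (!is.null(truth)) {
    tr <- truth
    writeLines(sprintf("%s\t%d\t%d", as.character(GenomeInfoDb::seqnames(tr)),
                       start(tr) - 1L, end(tr)),
               file.path(config$out_dir, "truth_peaks.bed"))
  }

  par <- config[setdiff(names(config), c("model_args", "sim"))]
  if (!is.null(par$blacklist) && !is.character(par$blacklist))
    par$blacklist <- sprintf("<%d interval(s)>", length(par$blacklist))
  if (!is.null(par$chrom_sizes) && !is.character(par$chrom_sizes))
    par$chrom_sizes <- as.list(par$chrom_sizes)
  manifest <- list(
    parameters = par,
    model_config = model@config, seeds = seeds,
    counts = list(replicates = nReplicates(cov),
                  candidate_regions = length(candidateRegions(rs)),
                  segments = length(segments(rs)),
                  scored_regions = length(calls), peaks = length(peaks)),
    thresholds = as.list(thresholds(rs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(calls = calls, regions = rs, model = model,
                 manifest = manifest, truth = truth))
}
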