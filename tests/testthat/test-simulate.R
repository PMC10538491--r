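test_that("simulation is deterministic per seed and writes consistent truth", {
  cfg <- simConfig(genome_length = 5e4, n_peaks = 8, seed = 3)
  a <- simulateAtac(cfg); b <- simulateAtac(cfg)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  for (r in 1:3)
    expect_identical(as.numeric(replicateCoverage(a$coverage, r)[["chr1"]]),
                     as.numeric(replicateCoverage(b$coverage, r)[["chr1"]]))
  expect_length(a$truth, 8)
  expect_true(all(width(a$truth) >= 200 & width(a$truth) <= 600))
  # planted peaks do not overlap
  expect_true(all(width(GenomicRanges::reduce(a$truth)) == width(sort(a$truth))))
})

test_that("mean coverage tracks depth x background rate", {
  cfg <- simConfig(genome_length = 4e5, n_peaks = 10, background_rate = 1,
                   replicate_depths = c(1, 0.8, 1.2), seed = 5)
  sim <- simulateAtac(cfg)
  # peak mass correction: (enrichment-1) x (peak bp)/L extra on average
  peak_frac <- sum(width(sim$truth)) / cfg$genome_length
  expected <- cfg$replicate_depths * cfg$background_rate *
    (1 + (cfg$enrichment - 1) * peak_frac)
  for (r in 1:3) {
    v <- replicateCoverage(sim$coverage, r)[["chr1"]]
    mn <- sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v)) /
      cfg$genome_length
    expect_equal(mn, expected[r], tolerance = 0.05)
  }
})

test_that("enrichment = 1 plants no detectable coverage difference", {
  cfg <- simConfig(genome_length = 4e5, n_peaks = 20, enrichment = 1,
                   replicate_depths = c(1, 1), seed = 9)
  sim <- simulateAtac(cfg)
  v <- as.numeric(replicateCoverage(sim$coverage, 1)[["chr1"]])
  inpk <- logical(length(v))
  for (i in seq_along(sim$truth))
    inpk[start(sim$truth)[i]:end(sim$truth)[i]] <- TRUE
  # difference of means within ~3 standard errors (correlated bases: use a
  # generous effective sample size of n / fragment length)
  neff_in <- sum(inpk) / 120; neff_out <- sum(!inpk) / 120
  se <- sqrt(var(v[inpk]) / neff_in + var(v[!inpk]) / neff_out)
  expect_lt(abs(mean(v[inpk]) - mean(v[!inpk])), 3 * se)
})

test_that("enriched peaks have a summit-shaped (centre-heavy) profile", {
  cfg <- simConfig(genome_length = 2e5, n_peaks = 10, enrichment = 10, seed = 21)
  sim <- simulateAtac(cfg)
  v <- as.numeric(replicateCoverage(sim$coverage, 1)[["chr1"]])
  centre <- edge <- 0
  for (i in seq_along(sim$truth)) {
    s <- start(sim$truth)[i]; e <- end(sim$truth)[i]; w <- e - s + 1
    mid <- (s + e) %/% 2
    centre <- centre + mean(v[(mid - w %/% 8):(mid + w %/% 8)])
    edge <- edge + mean(c(v[s:(s + w %/% 8)], v[(e - w %/% 8):e]))
  }
  expect_gt(centre, edge) # triangular profile peaks at the centre
})

test_that("candidate-region selection recovers planted peaks at high enrichment", {
  cfg <- simConfig(genome_length = 5e5, n_peaks = 50, enrichment = 8,
                   background_rate = 1, seed = 33)
  sim <- simulateAtac(cfg)
  rs <- selectRegions(sim$coverage, threshold = "median", alpha = 1000)
  st <- peakRecoveryStats(candidateRegions(rs), sim$truth)
  expect_gte(st$recall, 0.9)
})

test_that("impossible peak placement is rejected", {
  expect_error(simConfig(genome_length = 1e4, n_peaks = 50,
                         peak_width_range = c(200, 600)), "overlap")
  expect_error(simConfig(enrichment = 0.5), "enrichment")
  expect_error(simConfig(background_rate = 0), "background_rate")
})

test_that("simulation outputs round-trip through BedGraph files", {
  tmp <- withr::local_tempdir()
  sim <- demo_sim(seed = 11, genome_length = 2e4, n_peaks = 3)
  paths <- writeSimulation(sim, tmp)
  sizes <- readChromSizes(file.path(tmp, "chrom.sizes"))
  back <- readCoverage(file.path(tmp, paste0("rep", 1:3, ".bedgraph")), sizes)
  for (r in 1:3)
    expect_identical(as.numeric(replicateCoverage(back, r)[["chr1"]]),
                     as.numeric(replicateCoverage(sim$coverage, r)[["chr1"]]))
  truth <- readIntervals(file.path(tmp, "truth_peaks.bed"))
  expect_equal(start(truth), start(sort(sim$truth)))
})
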