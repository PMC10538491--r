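test_that("threshold resolution follows the min-of-medians rule", {
  # replicate A nonzero {1,2,3,4,5}, replicate B nonzero {2,2,2}:
  # medians 3 and 2 -> t = 2
  a <- c(1, 2, 3, 4, 5, rep(0, 20))
  b <- c(2, 2, 2, rep(0, 22))
  cs <- covset_from_vectors(list(a, b))
  tt <- resolveThreshold(cs, "median")
  expect_equal(unname(tt[["chr1"]]), 2)

  # fixed integer mode applies everywhere
  tt2 <- resolveThreshold(cs, 2)
  expect_equal(unname(tt2[["chr1"]]), 2)
  expect_error(resolveThreshold(cs, 0), "positive")
  expect_error(resolveThreshold(cs, -3), "positive")

  # single replicate, constant coverage 5 over 10 bp -> t = 5, with a warning
  cs1 <- covset_from_vectors(list(c(rep(5, 10), rep(0, 10))))
  expect_warning(t1 <- resolveThreshold(cs1, "median"), "replicate")
  expect_equal(unname(t1[["chr1"]]), 5)

  # all-zero replicate -> t = 1 with a warning
  cs0 <- covset_from_vectors(list(rep(0, 10), c(1, 1, rep(0, 8))))
  expect_warning(t0 <- resolveThreshold(cs0, "median"), "all-zero")
  expect_equal(unname(t0[["chr1"]]), 1)
})

test_that("covered-interval selection uses strict intersection across replicates", {
  L <- 400
  a <- numeric(L); b <- numeric(L)
  a[101:250] <- 3; a[261:290] <- 2
  b[101:250] <- 3; b[261:290] <- 2
  cs <- covset_from_vectors(list(a, b))
  iv <- selectCoveredIntervals(cs, c(chr1 = 1))
  expect_equal(start(iv), c(101, 261))
  expect_equal(end(iv), c(250, 290))

  # one replicate below threshold anywhere -> empty
  cs2 <- covset_from_vectors(list(a, numeric(L)))
  expect_length(selectCoveredIntervals(cs2, c(chr1 = 1)), 0)
  # all-zero tracks -> empty
  cs3 <- covset_from_vectors(list(numeric(L), numeric(L)))
  expect_length(selectCoveredIntervals(cs3, c(chr1 = 1)), 0)
})

test_that("merging and length filtering follow the gap/length rules", {
  # [100,250) and [260,290) 0-based: gap 10 -> merged [100,290), kept
  iv <- c(gr0("chr1", 100, 250), gr0("chr1", 260, 290))
  m <- mergeAndFilter(iv)
  expect_equal(start(m), 101); expect_equal(end(m), 290)

  # short interval discarded (50 <= 100)
  expect_length(mergeAndFilter(gr0("chr1", 0, 50)), 0)

  # boundary: gap exactly 91 does NOT merge; gap 90 does
  iv91 <- c(gr0("chr1", 0, 120), gr0("chr1", 211, 400))
  expect_length(mergeAndFilter(iv91), 2)
  iv90 <- c(gr0("chr1", 0, 120), gr0("chr1", 210, 400))
  expect_length(mergeAndFilter(iv90), 1)

  # exactly 100 bp after merge is discarded (strictly longer required)
  expect_length(mergeAndFilter(gr0("chr1", 0, 100)), 0)
  expect_length(mergeAndFilter(gr0("chr1", 0, 101)), 1)
})

test_that("selection + merging matches the per-base boolean-scan oracle on random genomes", {
  set.seed(301)
  for (trial in 1:1000) {
    L <- sample(200:10000, 1)
    R <- sample(2:3, 1)
    lam <- runif(1, 0.3, 3)
    tracks <- lapply(seq_len(R), function(r) {
      v <- rpois(L, lam)
      # add some coherent enriched stretches so runs exist
      nseg <- sample(0:3, 1)
      for (s in seq_len(nseg)) {
        a <- sample(1:L, 1); b <- min(L, a + sample(20:400, 1))
        v[a:b] <- v[a:b] + rpois(b - a + 1, 4)
      }
      v
    })
    t <- sample(1:3, 1)
    cs <- covset_from_vectors(tracks)
    got <- mergeAndFilter(selectCoveredIntervals(cs, c(chr1 = t)))
    exp <- naive_merge_filter(naive_covered(tracks, t))
    expect_equal(length(got), nrow(exp))
    if (nrow(exp)) {
      expect_equal(start(got), exp$start)
      expect_equal(end(got), exp$end)
    }
  }
})

test_that("short regions get one centred alpha-length segment", {
  # region [100,290) 0-based, alpha 200 -> midpoint 195 -> segment [95,295)
  mc <- IRanges::RleList(chr1 = S4Vectors::Rle(1, 1000), compress = FALSE)
  region <- gr0("chr1", 100, 290)
  seg <- extractSegments(region, mc, alpha = 200)
  expect_equal(start(seg), 96) # 0-based 95
  expect_equal(end(seg), 295)
  expect_equal(seg$region_id, 1L)

  # region of length exactly alpha keeps its span (length < alpha rule is
  # strict, so this goes through the summit path but spans the whole region)
  v <- numeric(1000); v[401:600] <- 5
  mc2 <- IRanges::RleList(chr1 = S4Vectors::Rle(v), compress = FALSE)
  region2 <- gr0("chr1", 400, 600)
  seg2 <- extractSegments(region2, mc2, alpha = 200)
  expect_true(all(width(seg2) == 200))
})

test_that("summit clustering on long regions gives one centred segment per summit", {
  # region [0,3000), alpha 1000: two 81 bp summit plateaus centred at 0-based
  # 500 and 2500 carry the top 5% of coverage, 2000 bp apart (> alpha), so
  # two clusters emerge with segments [0,1000) and [2000,3000)
  v <- rep(0, 3000)
  v[461:541] <- 100; v[2461:2541] <- 100
  mc <- IRanges::RleList(chr1 = S4Vectors::Rle(v), compress = FALSE)
  region <- gr0("chr1", 0, 3000)
  seg <- extractSegments(region, mc, alpha = 1000)
  expect_equal(start(seg), c(1, 2001))   # 0-based [0,1000) and [2000,3000)
  expect_equal(end(seg), c(1000, 3000))
  # summits closer than alpha merge into a single cluster
  v2 <- rep(0, 3000); v2[1311:1391] <- 100; v2[1611:1691] <- 100
  mc2 <- IRanges::RleList(chr1 = S4Vectors::Rle(v2), compress = FALSE)
  seg2 <- extractSegments(region, mc2, alpha = 1000)
  expect_length(seg2, 1)
})

test_that("segment extraction matches a brute-force quantile/cluster oracle", {
  set.seed(77)
  for (trial in 1:200) {
    L <- 6000
    alpha <- sample(c(150, 200, 333, 500), 1)
    v <- rpois(L, 2)
    # a few sharp summits
    for (s in seq_len(sample(1:4, 1))) {
      a <- sample(1:(L - 50), 1)
      v[a:(a + 49)] <- v[a:(a + 49)] + sample(10:60, 1)
    }
    s1 <- sample(1:(L - 2000), 1)
    e1 <- s1 + sample((alpha - 50):1800, 1) # mixes short and long regions
    e1 <- min(e1, L)
    mc <- IRanges::RleList(chr1 = S4Vectors::Rle(as.numeric(v)), compress = FALSE)
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1))
    seg <- extractSegments(region, mc, alpha = alpha)
    exp_starts <- naive_segments(s1, e1, v, alpha, L)
    expect_equal(start(seg), exp_starts)
    expect_true(all(width(seg) == alpha))
    expect_true(length(seg) >= 1)
  }
})

test_that("segments near chromosome ends are shifted inward, never truncated", {
  mc <- IRanges::RleList(chr1 = S4Vectors::Rle(1, 300), compress = FALSE)
  seg <- extractSegments(gr0("chr1", 0, 120), mc, alpha = 200)
  expect_equal(start(seg), 1); expect_equal(width(seg), 200)
  seg2 <- extractSegments(gr0("chr1", 170, 300), mc, alpha = 200)
  expect_equal(end(seg2), 300); expect_equal(width(seg2), 200)
  expect_error(extractSegments(gr0("chr1", 0, 120), mc, alpha = 400), "alpha")
})

test_that("blacklist removal uses 1 bp half-open overlap", {
  segs <- gr0("chr1", 95, 295, region_id = 1L)
  expect_length(removeBlacklisted(segs, gr0("chr1", 294, 400)), 0) # 1 bp overlap
  expect_length(removeBlacklisted(segs, gr0("chr1", 295, 400)), 1) # adjacent
  expect_length(removeBlacklisted(segs, NULL), 1)
  expect_length(removeBlacklisted(segs, GenomicRanges::GRanges()), 1)
})

test_that("full region selection is invariant under replicate reordering", {
  sim <- demo_sim(seed = 5, genome_length = 5e4, n_peaks = 6)
  cov <- sim$coverage
  rs1 <- selectRegions(cov, alpha = 300)
  cov2 <- CoverageSet(rev(cov@coverage), GenomeInfoDb::seqlengths(cov@seqinfo))
  rs2 <- selectRegions(cov2, alpha = 300)
  expect_identical(as.data.frame(candidateRegions(rs1)),
                   as.data.frame(candidateRegions(rs2)))
  expect_identical(as.data.frame(segments(rs1)), as.data.frame(segments(rs2)))
  # every region in A maps to at least one segment (no blacklist)
  expect_setequal(unique(segments(rs1)$region_id),
                  seq_along(candidateRegions(rs1)))
})
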