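test_that("score transfer follows the overlap-weighted formula", {
  # label of length 100 overlapped by (o=60, c=0.9) and (o=40, c=0.5)
  labels <- gr0("chr1", 100, 200)
  calls <- c(gr0("chr1", 40, 160, score = 0.9),  # overlaps [100,160) = 60 bp
             gr0("chr1", 160, 260, score = 0.5)) # overlaps [160,200) = 40 bp
  out <- transferScores(labels, calls)
  expect_equal(out$transferred_score, (60 * 0.9 + 40 * 0.5) / 100)
  expect_equal(out$n_overlaps, 2L)

  # label fully inside one call inherits its score
  out2 <- transferScores(gr0("chr1", 120, 140), gr0("chr1", 100, 200, score = 0.37))
  expect_equal(out2$transferred_score, 0.37)

  # fallback: unoverlapped label gets the observed minimum
  labels3 <- c(gr0("chr1", 0, 100), gr0("chr1", 5000, 5100))
  out3 <- transferScores(labels3, gr0("chr1", 0, 100, score = 0.8))
  expect_equal(out3$transferred_score, c(0.8, 0.8))
  expect_equal(out3$n_overlaps, c(1L, 0L))

  # no overlaps anywhere: all zero with a warning
  expect_warning(out4 <- transferScores(labels3, gr0("chr1", 9000, 9100, score = 1)),
                 "no call overlaps")
  expect_equal(out4$transferred_score, c(0, 0))
})

test_that("score transfer matches a per-base oracle on random interval sets", {
  set.seed(500)
  for (trial in 1:500) {
    nl <- sample(1:8, 1); nc <- sample(0:8, 1)
    labels <- data.frame(start = sample(1:900, nl))
    labels$end <- labels$start + sample(10:120, nl, replace = TRUE)
    calls <- data.frame(start = sample(1:900, nc))
    if (nc) {
      calls$end <- calls$start + sample(10:120, nc, replace = TRUE)
      calls$score <- round(runif(nc), 3)
    } else { calls$end <- integer(0); calls$score <- numeric(0) }
    lgr <- GenomicRanges::GRanges(rep("chr1", nl),
                                  IRanges::IRanges(labels$start, labels$end))
    cgr <- GenomicRanges::GRanges(rep("chr1", nc),
                                  IRanges::IRanges(calls$start, calls$end))
    cgr$score <- calls$score
    got <- suppressWarnings(transferScores(lgr, cgr))$transferred_score
    expect_equal(got, naive_transfer(labels, calls), tolerance = 1e-12)
  }
})

test_that("precision/recall/F1 follow the confusion table with strict thresholding", {
  lab <- c(TRUE, TRUE, FALSE)
  sc <- c(0.9, 0.2, 0.8)
  pm <- prMetrics(lab, sc, 0.5)
  expect_equal(pm$precision, 0.5)
  expect_equal(pm$recall, 0.5)
  expect_equal(pm$f1, 0.5)

  # perfect scorer
  pm2 <- prMetrics(c(TRUE, TRUE, FALSE, FALSE), c(1, 1, 0, 0), 0.5)
  expect_equal(c(pm2$precision, pm2$recall, pm2$f1), c(1, 1, 1))

  # threshold above all scores -> recall 0, flagged
  pm3 <- prMetrics(lab, sc, 0.95)
  expect_equal(pm3$recall, 0)
  expect_true(pm3$degenerate)

  expect_error(prMetrics(c(FALSE, FALSE), c(0.1, 0.2)), "positive")
})

test_that("PR curve groups ties, matches prMetrics, and integrates correctly", {
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  sc <- c(0.9, 0.8, 0.8, 0.3, 0.1)
  cv <- prCurve(lab, sc)
  # curve points use >= threshold; prMetrics uses > t: at t just below each
  # distinct score the two coincide
  for (i in seq_len(nrow(cv))) {
    pm <- prMetrics(lab, sc, cv$threshold[i] - 1e-9)
    expect_equal(cv$precision[i], pm$precision)
    expect_equal(cv$recall[i], pm$recall)
  }
  # duplicating every (score, label) pair leaves the curve unchanged
  cv2 <- prCurve(c(lab, lab), c(sc, sc))
  expect_equal(cv$precision, cv2$precision)
  expect_equal(cv$recall, cv2$recall)

  # perfect separation -> area 1; all-ties -> precision x full recall
  expect_equal(prAUC(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1)), 1)
  expect_equal(prAUC(c(TRUE, FALSE, FALSE, TRUE), rep(0.5, 4)), 0.5)
  expect_gte(prAUC(lab, sc), 0); expect_lte(prAUC(lab, sc), 1)
})

test_that("random scores give PRAUC near the positive fraction", {
  set.seed(606)
  n <- 4000; pi0 <- 0.3
  lab <- runif(n) < pi0
  sc <- runif(n)
  auc <- prAUC(lab, sc)
  expect_equal(auc, mean(lab), tolerance = 0.05)
  expect_equal(prAUC(lab, sc, estimator = "step"), mean(lab), tolerance = 0.05)
})

test_that("region-level recovery statistics count 1 bp overlaps", {
  truth <- c(gr0("chr1", 100, 200), gr0("chr1", 500, 600))
  calls <- c(gr0("chr1", 150, 250), gr0("chr1", 900, 950))
  st <- peakRecoveryStats(calls, truth)
  expect_equal(st$precision, 0.5)
  expect_equal(st$recall, 0.5)
  expect_equal(st$f1, 0.5)
  st0 <- peakRecoveryStats(GenomicRanges::GRanges(), truth)
  expect_equal(st0$f1, 0)
})

test_that("chromatin-state translation config maps annotations to labels", {
  states <- chromhmmStateLabels()
  expect_true(all(c("TssA", "Tx") %in% states$positive))
  expect_true(all(c("Quies", "ZNF/Rpts") %in% states$negative))
  ann <- c(gr0("chr1", 0, 100, name = "TssA"),
           gr0("chr1", 200, 300, name = "Quies"),
           gr0("chr1", 400, 500, name = "EnhBiv")) # unlisted state dropped
  lab <- labelAnnotations(ann, states)
  expect_length(lab, 2)
  expect_equal(lab$label, c(TRUE, FALSE))
  expect_error(labelAnnotations(GenomicRanges::GRanges("chr1:1-10")), "name")
})
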