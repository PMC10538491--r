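# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (literal loops over the definitions) and independent of
# the package implementation paths they check.

# literal evaluation of the replicate contrastive loss (both anchor
# directions of every replicate pair)
naive_l1 <- function(x, tau) {
  S <- dim(x)[1]; R <- dim(x)[2]
  cosv <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  total <- 0
  for (r in 1:R) for (rp in 1:R) {
    if (r == rp) next
    for (i in 1:S) {
      num <- exp(cosv(x[i, r, ], x[i, rp, ]) / tau)
      den <- 0
      for (j in setdiff(1:S, i)) den <- den + exp(cosv(x[i, r, ], x[j, rp, ]) / tau)
      total <- total - log(num / den)
    }
  }
  total / (2 * S * choose(R, 2))
}

# literal evaluation of the class-similarity loss
naive_l2 <- function(q, tau) {
  R <- dim(q)[2]
  cosv <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  total <- 0
  for (k in 1:2) for (r in 2:R) for (rp in 1:(r - 1)) {
    prk <- q[, r, k]; prpk <- q[, rp, k]
    total <- total - (cosv(prk, prpk) - cosv(prk, 1 - prpk)) / tau
  }
  total / (2 * choose(R, 2))
}

# per-base boolean scan: positions (1-based) covered > t in every track,
# returned as a data.frame of 1-based closed intervals
naive_covered <- function(tracks, t) {
  mask <- Reduce(`&`, lapply(tracks, function(v) v > t))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# transitive merging of sorted disjoint intervals with gap <= gap, then
# keep strictly longer than minlen
naive_merge_filter <- function(iv, gap = 90L, minlen = 100L) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv$start[i] - out$end[nrow(out)] - 1L <= gap)
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out[(out$end - out$start + 1L) > minlen, , drop = FALSE]
}

# brute-force segment extraction for one region (1-based [s, e]) on a
# merged-coverage vector; returns 1-based segment starts
naive_segments <- function(s, e, mergedcov, alpha, chromLen) {
  clip <- function(st0) { # 0-based start -> clipped 1-based start
    st0 <- max(0, min(st0, chromLen - alpha))
    st0 + 1
  }
  w <- e - s + 1
  if (w < alpha) {
    mid0 <- (s - 1 + e) %/% 2
    return(clip(mid0 - alpha %/% 2))
  }
  vals <- mergedcov[s:e]
  q95 <- as.numeric(quantile(vals, 0.95, type = 7))
  pos <- which(vals >= q95) + s - 1L
  starts <- integer(0)
  cl_start <- pos[1]; cl_end <- pos[1]
  flush <- function(a, b) {
    mid0 <- (a - 1 + b) %/% 2
    clip(mid0 - alpha %/% 2)
  }
  if (length(pos) > 1L) for (p in pos[-1]) {
    if (p - cl_end > alpha) { starts <- c(starts, flush(cl_start, cl_end)); cl_start <- p }
    cl_end <- p
  }
  c(starts, flush(cl_start, cl_end))
}

# per-base overlap-weighted score transfer
naive_transfer <- function(labels, calls) {
  # labels, calls: data.frames with start, end (1-based closed), calls$score
  out <- rep(NA_real_, nrow(labels))
  for (i in seq_len(nrow(labels))) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(calls))) {
      ov <- max(0, min(labels$end[i], calls$end[j]) -
                   max(labels$start[i], calls$start[j]) + 1)
      if (ov > 0) { num <- num + ov * calls$score[j]; den <- den + ov }
    }
    if (den > 0) out[i] <- num / den
  }
  if (all(is.na(out))) out[] <- 0 else out[is.na(out)] <- min(out, na.rm = TRUE)
  out
}

# literal dilated "same" 1-D convolution; x: Cin x L, W: Cout x (Cin*K) with
# column k*Cin + ci; stride 2 keeps even output positions (0-based)
naive_conv1d <- function(x, W, b, dil, stride = 1L) {
  Cin <- nrow(x); L <- ncol(x); Cout <- nrow(W)
  K <- ncol(W) / Cin; K2 <- (K - 1) / 2
  y <- matrix(0, Cout, L)
  for (t0 in 0:(L - 1)) {
    for (k in 0:(K - 1)) {
      pos <- t0 + dil * (k - K2)
      if (pos < 0 || pos >= L) next
      for (co in 1:Cout) for (ci in 1:Cin)
        y[co, t0 + 1] <- y[co, t0 + 1] + W[co, k * Cin + ci] * x[ci, pos + 1]
    }
  }
  y <- y + b
  if (stride == 2L) y <- y[, seq(1, L, by = 2), drop = FALSE]
  y
}

# build a CoverageSet from plain per-replicate numeric vectors (one chrom)
covset_from_vectors <- function(tracks, chrom = "chr1") {
  L <- length(tracks[[1]])
  rl <- lapply(tracks, function(v) {
    x <- IRanges::RleList(S4Vectors::Rle(as.numeric(v)), compress = FALSE)
    names(x) <- chrom
    x
  })
  CoverageSet(rl, stats::setNames(L, chrom))
}

# GRanges helper for 0-based half-open spec coordinates
gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0), ...)
}

# small trainable model for fast tests
tiny_model <- function(alpha = 200L, seed = 1L, ...) {
  peakModel(alpha = alpha, channels = 4L, kernel_size = 7L, dilation = 2L,
            n_modules = 2L, pool_out = 8L, embed_dim = 12L, seed = seed, ...)
}

# deterministic coverage with two replicates and one obvious peak
demo_sim <- function(seed = 42L, genome_length = 1e5, n_peaks = 10L, ...) {
  simulateAtac(simConfig(genome_length = genome_length, n_peaks = n_peaks,
                         seed = seed, ...))
}

# write a tiny coordinate-sorted paired-end SAM/BAM with the given fragments
# (0-based half-open) and return the BAM path
write_test_bam <- function(frags0, chromLen = 30L, chrom = "chr1",
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "test.sam")
  rl <- 5L # read length
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen))
  recs <- character(0)
  if (nrow(frags0)) {
    recs <- unlist(lapply(seq_len(nrow(frags0)), function(i) {
      s0 <- frags0$start[i]; e0 <- frags0$end[i]
      isize <- e0 - s0
      p1 <- s0 + 1L; p2 <- e0 - rl + 1L
      c(sprintf("frag%d\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                i, chrom, p1, rl, p2, isize, strrep("A", rl)),
        sprintf("frag%d\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                i, chrom, p2, rl, p1, -isize, strrep("A", rl)))
    }))
    # records must be coordinate sorted; sort lines by POS field
    pos <- as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 4L))
    recs <- recs[order(pos)]
  }
  writeLines(c(hdr, recs), sam)
  Rsamtools::asBam(sam, file.path(dir, "test"), overwrite = TRUE,
                   indexDestination = TRUE)
}
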