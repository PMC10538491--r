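# Label-transfer evaluation: called regions rarely coincide with annotated
# regions, so call scores are transferred onto labels by overlap-weighted
# averaging before computing precision/recall/F1 and PR curves.

#' Transfer call scores onto labeled regions
#'
#' For the i-th labeled region overlapped by n_i calls with scores c_j and
#' overlap widths o_j, the transferred score is
#' \eqn{\sum_j o_j c_j / \sum_j o_j}. Labels overlapped by no call receive the
#' minimum transferred score observed among labels with at least one overlap;
#' if no label overlaps any call, all labels get 0 with a warning.
#'
#' @param labels \code{GRanges} of labeled regions.
#' @param calls \code{GRanges} of scored calls (numeric \code{score} column).
#' @return \code{labels} with metadata columns \code{transferred_score} and
#'   \code{n_overlaps} added.
#' @export
transferScores <- function(labels, calls) {
  if (is.null(calls$score)) stop("calls need a 'score' metadata column")
  score <- rep(NA_real_, length(labels))
  n_ov <- integer(length(labels))
  hits <- GenomicRanges::findOverlaps(labels, calls, minoverlap = 1L)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ow <- width(IRanges::pintersect(IRanges::ranges(labels)[qh],
                                    IRanges::ranges(calls)[sh]))
    num <- vapply(split(ow * calls$score[sh], qh), sum, 0)
    den <- vapply(split(ow, qh), sum, 0)
    idx <- as.integer(names(num))
    score[idx] <- unname(num / den)
    n_ov[idx] <- unname(lengths(split(ow, qh)))
  }
  if (all(is.na(score))) {
    warning("no call overlaps any label; all transferred scores set to 0")
    score[] <- 0
  } else {
    score[is.na(score)] <- min(score, na.rm = TRUE)
  }
  labels$transferred_score <- score
  labels$n_overlaps <- n_ov
  labels
}

.check_labels <- function(label) {
  if (is.character(label)) label <- label == "positive"
  label <- as.logical(label)
  if (anyNA(label)) stop("labels must be positive/negative (or logical)")
  if (!any(label)) stop("no positive labels: precision/recall undefined")
  label
}

#' Precision, recall and F1 at a threshold
#'
#' Labels with \code{score > threshold} (strict) are predicted positive. Zero
#' denominators yield 0, flagged in the \code{degenerate} field.
#'
#' @param label logical vector (or \code{"positive"}/\code{"negative"}):
#'   true labels.
#' @param score numeric vector of (transferred) prediction scores.
#' @param threshold decision threshold (default 0.5).
#' @return List: \code{precision}, \code{recall}, \code{f1}, counts
#'   \code{tp}/\code{fp}/\code{fn}, and \code{degenerate}.
#' @export
prMetrics <- function(label, score, threshold = 0.5) {
  label <- .check_labels(label)
  stopifnot(length(label) == length(score))
  pred <- score > threshold
  tp <- sum(pred & label); fp <- sum(pred & !label); fn <- sum(!pred & label)
  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L || tp == 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, degenerate = degenerate)
}

#' Precision-recall curve and its area
#'
#' One curve point per distinct score, sorted by descending score: at each
#' distinct score s, labels with score >= s are predicted positive (ties are
#' grouped, so duplicating every (score, label) pair leaves the curve
#' unchanged). Labels sharing the minimum (fallback) score form the terminal
#' point, the linear extension to full recall. The area is computed by
#' trapezoidal integration over the achieved recall range, anchored at
#' (recall 0, precision of the highest-score point); the \code{"step"}
#' estimator instead uses the average-precision step sum.
#'
#' @param label logical vector (or \code{"positive"}/\code{"negative"}).
#' @param score numeric prediction scores.
#' @param estimator \code{"trapezoid"} (default) or \code{"step"}.
#' @return data.frame with columns \code{threshold}, \code{precision},
#'   \code{recall}; the area is in attribute \code{prauc}.
#' @export
prCurve <- function(label, score, estimator = c("trapezoid", "step")) {
  estimator <- match.arg(estimator)
  label <- .check_labels(label)
  stopifnot(length(label) == length(score))
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  npos <- sum(y)
  ctp <- cumsum(y); cn <- seq_along(y)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie group
  prec <- ctp[last] / cn[last]
  rec <- ctp[last] / npos
  thr <- s[last]
  if (estimator == "trapezoid") {
    r <- c(0, rec); p <- c(prec[1L], prec)
    prauc <- sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
  } else {
    r <- c(0, rec)
    prauc <- sum(diff(r) * prec)
  }
  out <- data.frame(threshold = thr, precision = prec, recall = rec)
  attr(out, "prauc") <- prauc
  out
}

#' Area under the precision-recall curve
#'
#' @inheritParams prCurve
#' @return Scalar in \code{[0, 1]}.
#' @export
prAUC <- function(label, score, estimator = c("trapezoid", "step")) {
  attr(prCurve(label, score, estimator), "prauc")
}

#' Region-level recovery of planted peaks
#'
#' Compares called peak regions with a truth set by 1-bp overlap: precision is
#' the fraction of called peaks overlapping any truth interval, recall the
#' fraction of truth intervals overlapped by any called peak.
#'
#' @param calls \code{GRanges} of called peaks (already thresholded).
#' @param truth \code{GRanges} of true intervals.
#' @return List: \code{precision}, \code{recall}, \code{f1}, \code{n_calls},
#'   \code{n_truth}.
#' @export
peakRecoveryStats <- function(calls, truth) {
  if (length(calls) == 0L)
    return(list(precision = 0, recall = 0, f1 = 0,
                n_calls = 0L, n_truth = length(truth)))
  precision <- mean(IRanges::overlapsAny(calls, truth, minoverlap = 1L))
  recall <- mean(IRanges::overlapsAny(truth, calls, minoverlap = 1L))
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_calls = length(calls), n_truth = length(truth))
}

#' Chromatin-state label translation
#'
#' Annotation-based evaluation labels chromatin states as positive
#' (accessible/active) or negative (inaccessible/repressed). The translation
#' is configuration data, not code: the default table shipped with the
#' package covers the ENCODE full-stack state names, and any YAML file with
#' \code{positive:} and \code{negative:} lists can replace it.
#'
#' @param path YAML file with \code{positive} and \code{negative} state-name
#'   lists; default: the table shipped in \code{extdata}.
#' @return \code{chromhmmStateLabels}: list with character vectors
#'   \code{positive} and \code{negative}.
#' @export
chromhmmStateLabels <- function(path = system.file("extdata",
                                                   "chromhmm_states.yaml",
                                                   package = "contrastPeaks")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$positive) || is.null(cfg$negative))
    stop("state config needs 'positive' and 'negative' lists")
  list(positive = as.character(cfg$positive),
       negative = as.character(cfg$negative))
}

#' @describeIn chromhmmStateLabels translate state-annotated intervals into
#'   labeled regions: intervals whose \code{name} matches a positive state
#'   get \code{label = TRUE}, negative states \code{FALSE}; intervals with
#'   unlisted states are dropped.
#' @param annotations \code{GRanges} with a \code{name} metadata column of
#'   state names (e.g. from [readIntervals()] on a ChromHMM BED).
#' @param states translation list from \code{chromhmmStateLabels()}.
#' @return \code{labelAnnotations}: the retained \code{GRanges} with a
#'   logical \code{label} metadata column.
#' @export
labelAnnotations <- function(annotations, states = chromhmmStateLabels()) {
  if (is.null(annotations$name))
    stop("annotations need a 'name' metadata column of state names")
  keep <- annotations$name %in% c(states$positive, states$negative)
  out <- annotations[keep]
  out$label <- out$name %in% states$positive
  out
}
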