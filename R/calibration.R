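#' Histogram of pairwise antibody distance scores
#'
#' Draws a seeded uniform subsample of records without replacement, scores
#' every pair, and bins the scores at fixed width over the full observed
#' range. Cross-family sentinel scores are excluded before binning — they
#' carry no information about the related/unrelated score boundary and
#' would otherwise dominate the upper tail. On repertoires with clonal
#' structure the histogram is bimodal: a low mode of clonally related
#' pairs and a broad high mode of unrelated pairs, separated by a
#' low-frequency trough.
#'
#' @param records rearrangement data.frame.
#' @param nSample subsample size (default 1000, giving 499,500 pairwise
#'   scores); capped at `nrow(records)`.
#' @param binWidth histogram bin width on the normalized-score axis
#'   (default 0.05).
#' @param seed optional integer seed for the subsample.
#' @param params a [ScoreParams-class] object.
#' @return A [ScoreHistogram-class] object.
#' @export
scoreHistogram <- function(records, nSample = 1000, binWidth = 0.05,
                           seed = NULL, params = scoreParams()) {
  if (nSample < 2) stop("nSample must be at least 2")
  n <- nrow(records)
  if (nSample > n) nSample <- n
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, nSample)
  d <- as.numeric(condensedDistances(records[idx, , drop = FALSE],
                                     params))
  d <- d[d < params@sentinelDistance]
  if (!length(d)) stop("no non-sentinel pairwise scores to bin")
  edges <- seq(0, max(d) + binWidth, by = binWidth)
  counts <- as.numeric(table(cut(d, breaks = edges, right = FALSE,
                                 include.lowest = TRUE)))
  new("ScoreHistogram", binEdges = edges, counts = counts,
      nPairs = length(d))
}

# Moving-average smoothing with edge shrinkage (window must be odd).
.smoothCounts <- function(counts, window) {
  if (window <= 1L) return(counts)
  half <- window %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Locate the trough of a bimodal score histogram
#'
#' Implements the data-driven threshold choice: smooth the bin counts with
#' a centered moving average, identify the two largest smoothed modes, and
#' return the center of the lowest bin strictly between them (leftmost on
#' ties). The returned value is the clustering threshold separating the
#' clonally-related score mode from the unrelated mode.
#'
#' The second mode is required to be a genuine separate peak, not a noise
#' wiggle on the flank of the first: among local maxima, only those whose
#' valley against the global maximum drops below `prominenceRatio` times
#' the lower of the two peak heights qualify, and of those the one with
#' the deepest relative valley wins (ties break to the tallest). Sampling
#' noise on a broad unrelated-score mass produces many shallow local
#' maxima; the prominence requirement ignores them, and the deep — often
#' empty — valley between the related-pair spike and the unrelated mass
#' always dominates even when the spike itself is small.
#'
#' @param histogram a [ScoreHistogram-class].
#' @param smoothingWindow moving-average window in bins (odd; default 5;
#'   1 disables smoothing).
#' @param prominenceRatio maximum ratio of the between-modes valley to the
#'   lower mode height for the second mode to count as separate
#'   (default 0.5).
#' @return The trough position (bin center), a single number strictly
#'   between the two mode locations.
#' @export
findTrough <- function(histogram, smoothingWindow = 5,
                       prominenceRatio = 0.5) {
  validObject(histogram)
  counts <- histogram@counts
  centers <- (histogram@binEdges[-1] +
              histogram@binEdges[-length(histogram@binEdges)]) / 2
  s <- .smoothCounts(counts, as.integer(smoothingWindow))
  n <- length(s)
  if (n < 3L)
    stop("histogram too coarse for trough detection; ",
         "choose the clustering threshold manually")
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  is_max <- s >= left & s >= right & (s > left | s > right)
  maxima <- which(is_max)
  mode1 <- which.max(s)
  # candidate second modes: separated from mode1 by a prominent valley
  cand <- maxima[maxima != mode1]
  valleyRatio <- vapply(cand, function(m) {
    if (abs(m - mode1) < 2L) return(Inf)
    between <- s[(min(m, mode1) + 1L):(max(m, mode1) - 1L)]
    min(between) / min(s[m], s[mode1])
  }, numeric(1))
  keep <- valleyRatio <= prominenceRatio
  cand <- cand[keep]
  valleyRatio <- valleyRatio[keep]
  if (!length(cand))
    stop("score histogram is unimodal after smoothing; ",
         "choose the clustering threshold manually")
  # most cleanly separated candidate: deepest valley relative to the lower
  # peak; ties (e.g. several candidates with an empty valley) break to the
  # tallest
  best <- which(valleyRatio <= min(valleyRatio) + 1e-12)
  mode2 <- cand[best][which.max(s[cand[best]])]
  lo <- min(mode1, mode2); hi <- max(mode1, mode2)
  between <- (lo + 1L):(hi - 1L)
  trough <- between[which.min(s[between])]
  centers[trough]
}

#' Calibrate the clustering threshold from the data
#'
#' Convenience wrapper: [scoreHistogram()] then [findTrough()].
#'
#' @inheritParams scoreHistogram
#' @inheritParams findTrough
#' @return The calibrated threshold (a single number).
#' @export
calibrateThreshold <- function(records, nSample = 1000, binWidth = 0.05,
                               seed = NULL, params = scoreParams(),
                               smoothingWindow = 5) {
  findTrough(scoreHistogram(records, nSample = nSample,
                            binWidth = binWidth, seed = seed,
                            params = params),
             smoothingWindow = smoothingWindow)
}
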