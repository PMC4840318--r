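#' Weighted Levenshtein edit distance
#'
#' Minimum-cost edit distance in which insertions and deletions are, by
#' default, penalized twice as heavily as substitutions — reflecting the
#' relative infrequency of indel mutations during antibody affinity
#' maturation. Computed by the standard dynamic programme over all
#' alignments; symmetric, and zero exactly when the strings are equal.
#'
#' @param s1,s2 character strings (any alphabet).
#' @param subCost substitution cost (default 1).
#' @param indelCost insertion/deletion cost (default `2 * subCost`).
#' @return A single non-negative number.
#' @examples
#' weightedLevenshtein("CARDYW", "CARDGYW") # one insertion: 2
#' weightedLevenshtein("CARDYW", "CARDFW")  # one substitution: 1
#' @export
weightedLevenshtein <- function(s1, s2, subCost = 1,
                                indelCost = 2 * subCost) {
  stopifnot(length(s1) == 1L, length(s2) == 1L,
            !is.na(s1), !is.na(s2))
  .wlev_cpp(s1, s2, subCost, indelCost)
}

#' Gapless distance for equal-length CDR3 sequences
#'
#' For CDR3 sequences of the same length the gapped edit distance can
#' introduce alignment gaps that produce deceptively low scores between
#' unrelated sequences; the metric therefore forces a gapless,
#' position-wise comparison whenever the two lengths are equal.
#'
#' @param s1,s2 equal-length character strings.
#' @param subCost per-mismatch cost (default 1).
#' @return `subCost` times the number of mismatching positions.
#' @examples
#' gaplessDistance("ABCDEF", "BCDEFA") # 6; the gapped distance would be 4
#' @export
gaplessDistance <- function(s1, s2, subCost = 1) {
  stopifnot(length(s1) == 1L, length(s2) == 1L)
  if (nchar(s1) != nchar(s2))
    stop("gaplessDistance() requires equal-length strings")
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  subCost * sum(a != b)
}

#' Count shared somatic mutations
#'
#' A shared mutation is the same substitution event — identical position,
#' germline base and observed base — found in both sequences' mutation
#' lists. Duplicated entries count once.
#'
#' @param mut1,mut2 data.frames with columns `pos`, `ref`, `alt` (as
#'   returned by [deriveMutations()]).
#' @return Integer intersection size.
#' @examples
#' m1 <- data.frame(pos = c(45, 120), ref = c("G", "C"), alt = c("A", "T"))
#' m2 <- data.frame(pos = 45, ref = "G", alt = "A")
#' sharedMutationCount(m1, m2) # 1
#' @export
sharedMutationCount <- function(mut1, mut2) {
  length(intersect(.mutationKeys(mut1), .mutationKeys(mut2)))
}

# Normalize a rearrangement data.frame into the parallel vectors the
# scoring kernel consumes. Errors if a scored field is missing.
.prepareRecords <- function(records, params) {
  stopifnot(is.data.frame(records))
  cdr3 <- if (params@cdr3Mode == "amino_acid") {
    if (!is.null(records$cdr3_aa)) records$cdr3_aa
    else if (!is.null(records$junction_aa))
      substr(records$junction_aa, 2L, nchar(records$junction_aa) - 1L)
    else stop("records lack cdr3_aa/junction_aa")
  } else {
    if (!is.null(records$cdr3)) records$cdr3
    else if (!is.null(records$junction))
      substr(records$junction, 4L, nchar(records$junction) - 3L)
    else stop("records lack cdr3/junction")
  }
  if (is.null(records$v_call) || is.null(records$j_call))
    stop("records lack v_call/j_call")
  if (any(is.na(cdr3)) || any(!nzchar(cdr3)))
    stop("every scored record needs a non-empty CDR3")
  vgene <- geneName(records$v_call)
  jgene <- geneName(records$j_call)
  vfam <- geneFamily(records$v_call)
  ids <- if (!is.null(records$sequence_id)) records$sequence_id
         else as.character(seq_len(nrow(records)))
  list(ids = ids, cdr3 = cdr3,
       v_family = as.integer(factor(vfam)),
       v_gene = as.integer(factor(vgene)),
       j_gene = as.integer(factor(jgene)),
       mut_keys = .recordMutationKeys(records))
}

#' Antibody-specific pairwise distance between two rearrangements
#'
#' Scores one pair of annotated antibody sequences. If the family
#' pre-screen is on and the two V-gene families differ, the sentinel
#' distance is returned without further computation. Otherwise the CDR3
#' edit distance (gapless when lengths are equal, weighted Levenshtein
#' otherwise) is adjusted by the V- and J-gene penalties and the shared
#' somatic-mutation bonus, clamped at the floor, and normalized by the
#' length of the shorter CDR3.
#'
#' @param rec1,rec2 single rearrangement records: 1-row data.frames (or
#'   lists) with `v_call`, `j_call`, a CDR3 in the active mode, and
#'   optionally alignment columns or a `mutations` entry.
#' @param params a [ScoreParams-class] object.
#' @return A single non-negative distance.
#' @examples
#' r1 <- data.frame(sequence_id = "a", v_call = "IGHV3-23*01",
#'                  j_call = "IGHJ4*02", cdr3_aa = "ARDYW")
#' r2 <- data.frame(sequence_id = "b", v_call = "IGHV3-23*01",
#'                  j_call = "IGHJ4*02", cdr3_aa = "ARDFW")
#' pairwiseScore(r1, r2) # 1 mismatch / length 5
#' @export
pairwiseScore <- function(rec1, rec2, params = scoreParams()) {
  rec <- rbind(as.data.frame(rec1, stringsAsFactors = FALSE)[
                 , , drop = FALSE],
               as.data.frame(rec2, stringsAsFactors = FALSE))
  if (!is.null(rec1$mutations) || !is.null(rec2$mutations)) {
    rec$mutations <- list(
      if (is.null(rec1$mutations)) data.frame() else
        if (is.data.frame(rec1$mutations)) rec1$mutations else
          rec1$mutations[[1]],
      if (is.null(rec2$mutations)) data.frame() else
        if (is.data.frame(rec2$mutations)) rec2$mutations else
          rec2$mutations[[1]])
  }
  p <- .prepareRecords(rec, params)
  if (params@familyPrescreen && p$v_family[1] != p$v_family[2])
    return(params@sentinelDistance)
  d <- if (nchar(p$cdr3[1]) == nchar(p$cdr3[2]))
    gaplessDistance(p$cdr3[1], p$cdr3[2], params@subCost)
  else
    weightedLevenshtein(p$cdr3[1], p$cdr3[2], params@subCost,
                        params@indelCost)
  if (p$v_gene[1] != p$v_gene[2]) d <- d + params@vPenalty
  if (p$j_gene[1] != p$j_gene[2]) d <- d + params@jPenalty
  d <- d - params@sharedMutBonus *
    length(intersect(p$mut_keys[[1]], p$mut_keys[[2]]))
  d <- max(d, params@clampFloor)
  d / min(nchar(p$cdr3))
}

#' All pairwise antibody-specific distances, condensed
#'
#' Computes the antibody-specific distance for every unordered pair of
#' records and returns them as a `"dist"` object (lower-triangle,
#' column-major order, `n*(n-1)/2` values) ready for [stats::hclust()].
#' For 1000 records this is 499,500 pairwise scores.
#'
#' @param records rearrangement data.frame (one row per sequence).
#' @param params a [ScoreParams-class] object.
#' @return A `"dist"` object labeled by `sequence_id`.
#' @export
condensedDistances <- function(records, params = scoreParams()) {
  if (nrow(records) < 2L)
    stop("need at least 2 records to compute pairwise distances")
  p <- .prepareRecords(records, params)
  d <- .condensed_scores_cpp(p$cdr3, p$v_family, p$v_gene, p$j_gene,
                             p$mut_keys,
                             params@subCost, params@indelCost,
                             params@vPenalty, params@jPenalty,
                             params@sharedMutBonus, params@clampFloor,
                             params@familyPrescreen,
                             params@sentinelDistance)
  attr(d, "Size") <- nrow(records)
  attr(d, "Labels") <- p$ids
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  attr(d, "method") <- "antibody"
  class(d) <- "dist"
  d
}
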