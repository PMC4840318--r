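#' @import methods
#' @importFrom stats hclust cutree as.dist setNames rbinom rlnorm runif
#' @importFrom utils read.delim write.table head
#' @useDynLib AbLineage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scoring parameters for the antibody-specific pairwise distance
#'
#' Holds every constant of the pairwise distance: edit costs on the CDR3
#' (indels cost twice as much as substitutions by default, reflecting the
#' rarity of indel mutations in affinity maturation), the penalties added
#' when two sequences are annotated with different V or J genes, the bonus
#' subtracted per shared somatic mutation, the clamp floor applied before
#' length normalization, and the pre-screen sentinel returned for pairs
#' from different V-gene families.
#'
#' @slot subCost substitution cost on the CDR3 (default 1).
#' @slot indelCost insertion/deletion cost (default 2, i.e. twice `subCost`).
#' @slot vPenalty penalty added when V genes (allele-stripped) differ
#'   (default 10).
#' @slot jPenalty penalty added when J genes differ (default 8).
#' @slot sharedMutBonus bonus subtracted per shared somatic substitution,
#'   identical (position, germline base, observed base) in both sequences
#'   (default 0.35).
#' @slot clampFloor lower clamp applied to the adjusted score before length
#'   normalization (default 0).
#' @slot familyPrescreen skip the full computation for pairs whose V-gene
#'   families differ, returning `sentinelDistance` instead (default TRUE).
#' @slot sentinelDistance the distance reported for cross-family pairs; a
#'   finite constant larger than any attainable normalized score
#'   (default 100).
#' @slot cdr3Mode `"amino_acid"` (scores `cdr3_aa`) or `"nucleotide"`
#'   (scores the nucleotide CDR3); normalization uses the length in the
#'   active mode.
#' @export
setClass("ScoreParams",
  slots = c(
    subCost = "numeric",
    indelCost = "numeric",
    vPenalty = "numeric",
    jPenalty = "numeric",
    sharedMutBonus = "numeric",
    clampFloor = "numeric",
    familyPrescreen = "logical",
    sentinelDistance = "numeric",
    cdr3Mode = "character"
  )
)

setValidity("ScoreParams", function(object) {
  msg <- character()
  num <- c(object@subCost, object@indelCost, object@vPenalty,
           object@jPenalty, object@sharedMutBonus, object@clampFloor)
  if (any(!is.finite(num)) || any(num < 0))
    msg <- c(msg, "all costs, penalties and bonuses must be finite and >= 0")
  if (!object@cdr3Mode %in% c("amino_acid", "nucleotide"))
    msg <- c(msg, "cdr3Mode must be 'amino_acid' or 'nucleotide'")
  if (length(object@sentinelDistance) != 1 ||
      object@sentinelDistance <= max(object@vPenalty, object@jPenalty))
    msg <- c(msg, "sentinelDistance must exceed any attainable score")
  if (length(msg)) msg else TRUE
})

#' Construct scoring parameters
#'
#' Defaults follow the published antibody-specific metric: substitution
#' cost 1, indel cost 2, V-gene penalty 10, J-gene penalty 8, shared
#' mutation bonus 0.35, adjusted score clamped at 0 and normalized by the
#' shorter CDR3 length, with a same-V-family pre-screen.
#'
#' @param subCost,indelCost CDR3 edit costs.
#' @param vPenalty,jPenalty penalties for differing V / J gene calls.
#' @param sharedMutBonus bonus per shared somatic substitution.
#' @param clampFloor lower clamp before normalization.
#' @param familyPrescreen logical; short-circuit cross-family pairs.
#' @param sentinelDistance score assigned to cross-family pairs.
#' @param cdr3Mode `"amino_acid"` or `"nucleotide"`.
#' @return A [ScoreParams-class] object.
#' @examples
#' scoreParams()
#' scoreParams(cdr3Mode = "nucleotide")
#' @export
scoreParams <- function(subCost = 1, indelCost = 2 * subCost,
                        vPenalty = 10, jPenalty = 8,
                        sharedMutBonus = 0.35, clampFloor = 0,
                        familyPrescreen = TRUE, sentinelDistance = 100,
                        cdr3Mode = c("amino_acid", "nucleotide")) {
  new("ScoreParams", subCost = subCost, indelCost = indelCost,
      vPenalty = vPenalty, jPenalty = jPenalty,
      sharedMutBonus = sharedMutBonus, clampFloor = clampFloor,
      familyPrescreen = familyPrescreen,
      sentinelDistance = sentinelDistance,
      cdr3Mode = match.arg(cdr3Mode))
}

#' Clustering parameters
#'
#' @slot threshold positive cut height on the normalized-score dendrogram;
#'   all merges at height <= threshold are applied.
#' @slot linkage agglomeration criterion: `"average"`, `"single"` or
#'   `"complete"`.
#' @slot precluster `"none"`, `"v_family"` or `"v_gene"`: optionally split
#'   records by V annotation and cluster each group separately (a speed
#'   device; with the family pre-screen on and sentinel above the
#'   threshold it yields the same partition as a global run).
#' @export
setClass("ClusterParams",
  slots = c(threshold = "numeric", linkage = "character",
            precluster = "character")
)

setValidity("ClusterParams", function(object) {
  msg <- character()
  if (length(object@threshold) != 1 || !is.finite(object@threshold) ||
      object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive number")
  if (!object@linkage %in% c("average", "single", "complete"))
    msg <- c(msg, "linkage must be 'average', 'single' or 'complete'")
  if (!object@precluster %in% c("none", "v_family", "v_gene"))
    msg <- c(msg, "precluster must be 'none', 'v_family' or 'v_gene'")
  if (length(msg)) msg else TRUE
})

#' Construct clustering parameters
#'
#' The shipped default threshold (0.35) is an implementation default for
#' convenience; the recommended practice is to calibrate the threshold on
#' the data with [scoreHistogram()] and [findTrough()].
#'
#' @param threshold cut height (> 0).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param precluster `"none"` (default), `"v_family"` or `"v_gene"`.
#' @return A [ClusterParams-class] object.
#' @examples
#' clusterParams(threshold = 0.35)
#' @export
clusterParams <- function(threshold = 0.35,
                          linkage = c("average", "single", "complete"),
                          precluster = c("none", "v_family", "v_gene")) {
  new("ClusterParams", threshold = threshold,
      linkage = match.arg(linkage), precluster = match.arg(precluster))
}

#' Partition of a repertoire into clonal lineages
#'
#' @slot assignments named character vector mapping every scored
#'   `sequence_id` to its lineage id.
#' @slot lineages data.frame with one row per lineage: `lineage_id`,
#'   `size`, `representative_junction` (modal CDR3), modal `v_family`,
#'   `v_gene`, `j_gene`, `mean_nt_mutations`, `mean_aa_mutations`,
#'   `mean_cdr3_len`, and a list-column `member_ids`.
#' @slot dropped character vector of sequence ids excluded before scoring
#'   (missing junction or V/J call).
#' @export
setClass("LineagePartition",
  slots = c(assignments = "character", lineages = "data.frame",
            dropped = "character")
)

setValidity("LineagePartition", function(object) {
  msg <- character()
  if (length(object@assignments) &&
      is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by sequence_id")
  if (nrow(object@lineages) &&
      sum(object@lineages$size) != length(object@assignments))
    msg <- c(msg, "lineage sizes must sum to the number of assignments")
  if (anyDuplicated(names(object@assignments)))
    msg <- c(msg, "every sequence appears in exactly one lineage")
  if (length(msg)) msg else TRUE
})

#' @describeIn LineagePartition-class number of lineages.
#' @param object,x a `LineagePartition`.
#' @export
setGeneric("nLineages", function(object) standardGeneric("nLineages"))

#' @export
setMethod("nLineages", "LineagePartition",
          function(object) nrow(object@lineages))

#' @describeIn LineagePartition-class named map sequence_id -> lineage_id.
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @export
setMethod("assignments", "LineagePartition",
          function(object) object@assignments)

#' @describeIn LineagePartition-class per-lineage summary table.
#' @export
setGeneric("lineages", function(object) standardGeneric("lineages"))

#' @export
setMethod("lineages", "LineagePartition", function(object) object@lineages)

#' @describeIn LineagePartition-class named vector of lineage sizes.
#' @export
setGeneric("lineageSizes", function(object) standardGeneric("lineageSizes"))

#' @export
setMethod("lineageSizes", "LineagePartition", function(object)
  stats::setNames(object@lineages$size, object@lineages$lineage_id))

setMethod("show", "LineagePartition", function(object) {
  n <- length(object@assignments)
  k <- nrow(object@lineages)
  cat("LineagePartition:", n, "sequences in", k, "lineages\n")
  if (k) {
    sz <- object@lineages$size
    cat(sprintf("  singletons: %d (%.1f%% of lineages)\n",
                sum(sz == 1), 100 * mean(sz == 1)))
    cat(sprintf("  largest lineage: %d members\n", max(sz)))
    cat(sprintf("  clonality fraction: %.3f\n",
                sum(sz[sz >= 2]) / n))
  }
  if (length(object@dropped))
    cat("  dropped before scoring:", length(object@dropped), "\n")
  invisible(object)
})

#' Histogram of pairwise distance scores
#'
#' @slot binEdges increasing numeric vector of bin edges.
#' @slot counts non-negative integer counts, one per bin.
#' @slot nPairs total number of scores binned (sentinel-distance scores
#'   from the cross-family pre-screen are excluded before binning).
#' @export
setClass("ScoreHistogram",
  slots = c(binEdges = "numeric", counts = "numeric", nPairs = "numeric")
)

setValidity("ScoreHistogram", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@binEdges) - 1L)
    msg <- c(msg, "counts must have length(binEdges) - 1")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (abs(sum(object@counts) - object@nPairs) > 0.5)
    msg <- c(msg, "sum(counts) must equal nPairs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoreHistogram", function(object) {
  cat("ScoreHistogram:", object@nPairs, "pairwise scores in",
      length(object@counts), "bins over [",
      min(object@binEdges), ",", max(object@binEdges), "]\n")
  invisible(object)
})

#' Nearest-neighbor network of a single clonal lineage
#'
#' Identical sequences are collapsed into one node whose weight is the
#' number of sequences it represents; each node is joined by an edge to
#' every node at its minimum pairwise distance (ties produce multiple
#' edges). The graph need not be connected.
#'
#' @slot nodes data.frame: `node_id`, `sequence`, `weight`, and
#'   list-column `member_ids`.
#' @slot edges data.frame: `from`, `to`, `distance` (undirected,
#'   deduplicated).
#' @export
setClass("LineageGraph",
  slots = c(nodes = "data.frame", edges = "data.frame")
)

setMethod("show", "LineageGraph", function(object) {
  cat("LineageGraph:", nrow(object@nodes), "nodes (",
      sum(object@nodes$weight), "sequences ),",
      nrow(object@edges), "edges\n")
  invisible(object)
})

#' @describeIn LineageGraph-class node table.
#' @param object a `LineageGraph`.
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @export
setMethod("graphNodes", "LineageGraph", function(object) object@nodes)

#' @describeIn LineageGraph-class edge table.
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @export
setMethod("graphEdges", "LineageGraph", function(object) object@edges)
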