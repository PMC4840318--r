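# Lineage summary rows for one group of records given integer cluster
# labels. Modal values break ties lexicographically (deterministic).
.modal <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- table(x)
  names(tab)[which.max(tab)]  # which.max takes the first = smallest name
}

.summarizeLineages <- function(records, labels, cdr3, mutKeys) {
  groups <- split(seq_len(nrow(records)), labels)
  aa_counts <- if (all(c("sequence_alignment", "germline_alignment") %in%
                       names(records))) {
    vapply(seq_len(nrow(records)), function(i)
      .aaMutationCount(records$sequence_alignment[i],
                       records$germline_alignment[i]), numeric(1))
  } else rep(NA_real_, nrow(records))
  do.call(rbind, lapply(groups, function(idx) {
    data.frame(
      size = length(idx),
      representative_junction = .modal(cdr3[idx]),
      v_family = .modal(geneFamily(records$v_call[idx])),
      v_gene = .modal(geneName(records$v_call[idx])),
      j_gene = .modal(geneName(records$j_call[idx])),
      mean_nt_mutations = mean(lengths(mutKeys[idx])),
      mean_aa_mutations = mean(aa_counts[idx]),
      mean_cdr3_len = mean(nchar(cdr3[idx])),
      stringsAsFactors = FALSE)
  }))
}

#' Cut a condensed distance matrix into lineages
#'
#' Agglomerative hierarchical clustering of a condensed antibody distance
#' matrix with the configured linkage, cutting the dendrogram so that all
#' merges at height at or below the threshold are applied. Deterministic
#' for a given input order.
#'
#' @param d a `"dist"` object (e.g. from [condensedDistances()]).
#' @param params a [ClusterParams-class] object.
#' @param ids optional sequence ids (defaults to the `dist` labels).
#' @return Integer cluster labels named by sequence id.
#' @export
clusterLineages <- function(d, params = clusterParams(), ids = NULL) {
  stopifnot(inherits(d, "dist"))
  validObject(params)
  n <- attr(d, "Size")
  if (is.null(ids)) ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) return(stats::setNames(1L, ids))
  tree <- stats::hclust(d, method = params@linkage)
  # the configured linkages are monotone; any decreasing step in the merge
  # heights is floating-point noise, which cutree() refuses to tolerate
  viol <- -min(0, diff(tree$height))
  if (viol > 1e-6 * max(abs(tree$height), 1))
    stop("non-monotone merge heights from hclust")
  tree$height <- cummax(tree$height)
  stats::setNames(stats::cutree(tree, h = params@threshold), ids)
}

#' Assign a repertoire to clonal lineages
#'
#' The end-to-end unseeded assignment: records missing a junction or a V/J
#' call are excluded (with a message), pairwise antibody-specific
#' distances are computed, and the sequences are hierarchically clustered
#' into lineages at the configured threshold. With
#' `precluster = "v_family"` or `"v_gene"` the records are first split by
#' V annotation and each group is clustered against its own (much smaller)
#' distance matrix; because the family pre-screen already assigns the
#' sentinel distance to cross-family pairs, pre-clustering by family
#' yields the same partition as a global run whenever the sentinel exceeds
#' the threshold.
#'
#' @param records rearrangement data.frame.
#' @param params a [ScoreParams-class] object.
#' @param clusterParams a [ClusterParams-class] object.
#' @return A [LineagePartition-class]: lineage ids are globally unique,
#'   zero-padded, ordered by decreasing lineage size (ties by first
#'   appearance), with per-lineage summaries.
#' @export
assignLineages <- function(records, params = scoreParams(),
                           clusterParams = AbLineage::clusterParams()) {
  if (is.null(records$sequence_id))
    records$sequence_id <- as.character(seq_len(nrow(records)))
  usable <- rep(TRUE, nrow(records))
  for (col in c("v_call", "j_call"))
    usable <- usable & !is.na(records[[col]]) & nzchar(records[[col]])
  cdr3col <- if (params@cdr3Mode == "amino_acid") {
    if (!is.null(records$cdr3_aa)) "cdr3_aa" else "junction_aa"
  } else {
    if (!is.null(records$cdr3)) "cdr3" else "junction"
  }
  if (is.null(records[[cdr3col]]))
    stop("records lack a CDR3/junction column for cdr3Mode '",
         params@cdr3Mode, "'")
  usable <- usable & !is.na(records[[cdr3col]]) &
    nchar(records[[cdr3col]]) > 0
  dropped <- records$sequence_id[!usable]
  if (length(dropped))
    message("excluded ", length(dropped),
            " record(s) missing junction or V/J call")
  records <- records[usable, , drop = FALSE]
  if (nrow(records) == 0L)
    return(new("LineagePartition",
               assignments = stats::setNames(character(0), character(0)),
               lineages = data.frame(), dropped = dropped))

  groups <- switch(clusterParams@precluster,
    none = list(seq_len(nrow(records))),
    v_family = split(seq_len(nrow(records)),
                     geneFamily(records$v_call)),
    v_gene = split(seq_len(nrow(records)), geneName(records$v_call)))

  labels <- integer(nrow(records))
  offset <- 0L
  for (idx in groups) {
    grp <- records[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      labels[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    d <- condensedDistances(grp, params)
    cl <- clusterLineages(d, clusterParams, ids = grp$sequence_id)
    labels[idx] <- offset + as.integer(cl)
    offset <- offset + max(cl)
  }

  # relabel lineages by decreasing size, ties by first appearance
  tab <- table(labels)
  ord <- order(-as.integer(tab),
               match(names(tab), unique(as.character(labels))))
  width <- max(4L, nchar(as.character(length(tab))))
  newid <- stats::setNames(sprintf(paste0("L%0", width, "d"),
                                   seq_along(ord)), names(tab)[ord])
  lineage_ids <- newid[as.character(labels)]

  p <- .prepareRecords(records, params)
  summ <- .summarizeLineages(records, lineage_ids, p$cdr3, p$mut_keys)
  summ$lineage_id <- rownames(summ)
  summ <- summ[order(summ$lineage_id), ]
  summ$member_ids <- lapply(split(records$sequence_id, lineage_ids),
                            identity)[summ$lineage_id]
  rownames(summ) <- NULL
  summ <- summ[, c("lineage_id", "size", "representative_junction",
                   "v_family", "v_gene", "j_gene", "mean_nt_mutations",
                   "mean_aa_mutations", "mean_cdr3_len", "member_ids")]
  new("LineagePartition",
      assignments = stats::setNames(unname(lineage_ids),
                                    records$sequence_id),
      lineages = summ, dropped = as.character(dropped))
}

#' Append lineage assignments to a rearrangement table
#'
#' @param records rearrangement data.frame.
#' @param partition a [LineagePartition-class].
#' @return `records` with a `clone_id` column (NA for records that were
#'   excluded before scoring).
#' @export
exportClones <- function(records, partition) {
  records$clone_id <- unname(assignments(partition)[records$sequence_id])
  records
}

#' Write a lineage partition as JSON
#'
#' One JSON object per lineage with its id, size, representative junction,
#' modal V/J calls and member sequence ids.
#'
#' @param partition a [LineagePartition-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLineages <- function(partition, path) {
  lin <- lineages(partition)
  out <- lapply(seq_len(nrow(lin)), function(i) list(
    lineage_id = lin$lineage_id[i],
    size = lin$size[i],
    representative_junction = lin$representative_junction[i],
    v_family = lin$v_family[i],
    v_gene = lin$v_gene[i],
    j_gene = lin$j_gene[i],
    member_ids = lin$member_ids[[i]]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
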