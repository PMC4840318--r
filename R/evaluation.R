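#' Clonality fraction of a partition
#'
#' The fraction of sequences belonging to a lineage with at least two
#' members — the standard depth-dependent summary of repertoire
#' clonality.
#'
#' @param partition a [LineagePartition-class].
#' @return A number in `[0, 1]`.
#' @examples
#' ## two sequences in one lineage plus a singleton -> 2/3
#' @export
clonalityFraction <- function(partition) {
  a <- assignments(partition)
  if (!length(a)) stop("empty partition")
  sizes <- table(a)
  sum(sizes[sizes >= 2]) / length(a)
}

# Modal donor of each lineage; ties broken by lexicographically smallest
# donor so contamination is deterministic.
.modalDonor <- function(donors) {
  tab <- table(donors)
  names(tab)[which.max(tab)]
}

#' Cross-donor contamination of a partition
#'
#' True clonal lineages descend from a single naive B cell and therefore
#' cannot span donors, so sequences placed in a lineage dominated by
#' another donor's sequences are incorrect assignments. Under the default
#' `"modal"` rule each lineage's modal donor is determined (ties to the
#' lexicographically smallest donor) and contamination is the fraction of
#' sequences whose donor differs from their lineage's modal donor. The
#' stricter `"strict"` rule counts every member of any multi-donor lineage
#' as incorrect.
#'
#' @param partition a [LineagePartition-class].
#' @param donors named character vector: `sequence_id -> donor`.
#' @param rule `"modal"` (default) or `"strict"`.
#' @return Fraction of incorrectly assigned sequences in `[0, 1]`.
#' @export
crossDonorContamination <- function(partition, donors,
                                    rule = c("modal", "strict")) {
  rule <- match.arg(rule)
  a <- assignments(partition)
  if (any(!names(a) %in% names(donors)))
    stop("every assigned sequence needs a donor label")
  d <- donors[names(a)]
  mean(.incorrectFlags(a, d, rule))
}

.incorrectFlags <- function(assignments, donors, rule) {
  if (rule == "modal") {
    modal <- vapply(split(donors, assignments), .modalDonor, character(1))
    donors != modal[assignments]
  } else {
    mixed <- vapply(split(donors, assignments),
                    function(x) length(unique(x)) > 1, logical(1))
    mixed[assignments]
  }
}

#' Build leave-one-out cross-validation pools
#'
#' For each donor, builds a pool omitting that donor and containing a
#' seeded random draw of `nPerDonor` records from every other donor —
#' the construction used to test whether pooling across donors inflates
#' apparent clonality.
#'
#' @param donorDatasets named list of rearrangement data.frames, one per
#'   donor.
#' @param nPerDonor records drawn from each included donor.
#' @param seed optional integer seed.
#' @return Named list of pooled data.frames (name = the omitted donor).
#' @export
loocvPools <- function(donorDatasets, nPerDonor, seed = NULL) {
  if (length(donorDatasets) < 2) stop("need at least 2 donors")
  short <- vapply(donorDatasets, nrow, integer(1)) < nPerDonor
  if (any(short))
    stop("donor(s) with fewer than nPerDonor records: ",
         paste(names(donorDatasets)[short], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  samples <- lapply(donorDatasets, function(df)
    df[sample.int(nrow(df), nPerDonor), , drop = FALSE])
  pools <- lapply(names(donorDatasets), function(left_out) {
    pool <- do.call(rbind, samples[setdiff(names(donorDatasets),
                                           left_out)])
    rownames(pool) <- NULL
    pool
  })
  stats::setNames(pools, names(donorDatasets))
}

#' Short-HCDR3 enrichment among incorrectly assigned sequences
#'
#' Short HCDR3s carry little junctional diversity, so unrelated donors are
#' more likely to coincidentally express near-identical short-HCDR3
#' antibodies. This compares the frequency of CDR3s shorter than `cutoff`
#' amino acids among incorrectly vs correctly assigned sequences (by the
#' cross-donor rule).
#'
#' @param records rearrangement data.frame with `sequence_id` and
#'   `cdr3_aa`.
#' @param partition a [LineagePartition-class].
#' @param donors named character vector `sequence_id -> donor`.
#' @param cutoff length threshold in amino acids (default 15; "short"
#'   means strictly below the cutoff).
#' @param rule incorrect-assignment rule, see
#'   [crossDonorContamination()].
#' @return A list: `fracShortIncorrect`, `fracShortCorrect` (either is
#'   `NA` when its group is empty — a 0/0 ratio is reported as undefined,
#'   never as 0 or 1), `nIncorrect`, `nCorrect`.
#' @export
shortHcdr3Enrichment <- function(records, partition, donors, cutoff = 15,
                                 rule = c("modal", "strict")) {
  rule <- match.arg(rule)
  a <- assignments(partition)
  d <- donors[names(a)]
  bad <- .incorrectFlags(a, d, rule)
  len <- stats::setNames(nchar(records$cdr3_aa), records$sequence_id)
  short <- len[names(a)] < cutoff
  list(
    fracShortIncorrect = if (any(bad)) mean(short[bad]) else NA_real_,
    fracShortCorrect = if (any(!bad)) mean(short[!bad]) else NA_real_,
    nIncorrect = sum(bad), nCorrect = sum(!bad))
}

#' Germline gene usage at the sequence or lineage level
#'
#' Sequence-level usage counts every record; lineage-level usage counts
#' each lineage once — via its modal gene — regardless of lineage size,
#' removing the influence of clonal expansion on apparent germline usage.
#' Frequencies sum to 1 within each gene class. Classes reported: V family,
#' J gene, and D family when a `d_call` column is present.
#'
#' @param records rearrangement data.frame.
#' @param partition a [LineagePartition-class]; required for
#'   `level = "lineage"`.
#' @param level `"sequence"` or `"lineage"`.
#' @return data.frame with columns `class`, `gene`, `count`, `freq`.
#' @export
germlineUsage <- function(records, partition = NULL,
                          level = c("sequence", "lineage")) {
  level <- match.arg(level)
  classes <- list(v_family = geneFamily(records$v_call),
                  j_gene = geneName(records$j_call))
  if (!is.null(records$d_call)) {
    has_d <- !is.na(records$d_call) & nzchar(records$d_call)
    if (any(has_d)) {
      dfam <- rep(NA_character_, nrow(records))
      dfam[has_d] <- geneFamily(records$d_call[has_d])
      classes$d_family <- dfam
    }
  }
  if (level == "lineage") {
    if (is.null(partition))
      stop("lineage-level usage needs a partition")
    a <- assignments(partition)
    idx <- match(names(a), records$sequence_id)
    classes <- lapply(classes, function(x) {
      vapply(split(x[idx], a), .modal, character(1))
    })
  }
  out <- lapply(names(classes), function(cl) {
    x <- classes[[cl]]
    x <- x[!is.na(x)]
    tab <- table(x)
    data.frame(class = cl, gene = names(tab),
               count = as.integer(tab),
               freq = as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise precision and recall of a partition against truth
#'
#' Standard pair-counting accuracy: over all unordered sequence pairs, a
#' true positive is a pair co-clustered in both the partition and the
#' truth; precision = TP/(TP+FP), recall = TP/(TP+FN). Computed from the
#' contingency table, so no pair enumeration is needed.
#'
#' @param partition a [LineagePartition-class].
#' @param truth named character vector `sequence_id -> true lineage`.
#' @return A list (`precision`, `recall`); an undefined ratio (no
#'   predicted or no true pairs) is `NA`.
#' @export
pairwisePrecisionRecall <- function(partition, truth) {
  a <- assignments(partition)
  if (any(!names(a) %in% names(truth)))
    stop("truth must cover every assigned sequence")
  t <- truth[names(a)]
  choose2 <- function(x) sum(x * (x - 1) / 2)
  tp <- choose2(table(a, t))
  pred_pairs <- choose2(table(a))
  true_pairs <- choose2(table(t))
  list(precision = if (pred_pairs > 0) tp / pred_pairs else NA_real_,
       recall = if (true_pairs > 0) tp / true_pairs else NA_real_)
}

#' Nearest-neighbor network graph of one clonal lineage
#'
#' Collapses identical sequences into nodes weighted by multiplicity, then
#' joins each node to every node at its minimum pairwise antibody distance
#' (a tie produces one edge per tied nearest neighbor). Edges are
#' undirected and deduplicated; the graph need not be connected.
#'
#' @param records rearrangement data.frame of one lineage's members.
#' @param params a [ScoreParams-class].
#' @param collapseOn column defining sequence identity
#'   (default `sequence_alignment`, falling back to `junction`).
#' @return A [LineageGraph-class].
#' @export
buildLineageGraph <- function(records, params = scoreParams(),
                              collapseOn = NULL) {
  if (is.null(collapseOn))
    collapseOn <- if (!is.null(records$sequence_alignment))
      "sequence_alignment" else "junction"
  key <- records[[collapseOn]]
  groups <- split(seq_len(nrow(records)), key)
  reps <- vapply(groups, `[`, integer(1), 1L)
  nodes <- data.frame(
    node_id = paste0("N", seq_along(groups)),
    sequence = names(groups),
    weight = lengths(groups),
    stringsAsFactors = FALSE)
  nodes$member_ids <- lapply(groups, function(i) records$sequence_id[i])
  rownames(nodes) <- NULL
  k <- nrow(nodes)
  if (k < 2L)
    return(new("LineageGraph", nodes = nodes,
               edges = data.frame(from = character(0), to = character(0),
                                  distance = numeric(0))))
  d <- as.matrix(condensedDistances(records[reps, , drop = FALSE],
                                    params))
  eps <- 1e-12
  edges <- list()
  for (i in seq_len(k)) {
    di <- d[i, -i]
    nn <- which(d[i, ] <= min(di) + eps)
    nn <- nn[nn != i]
    for (j in nn) {
      a <- min(i, j); b <- max(i, j)
      edges[[paste(a, b)]] <- c(a, b, d[a, b])
    }
  }
  em <- do.call(rbind, edges)
  edges_df <- data.frame(from = nodes$node_id[em[, 1]],
                         to = nodes$node_id[em[, 2]],
                         distance = em[, 3], stringsAsFactors = FALSE)
  rownames(edges_df) <- NULL
  new("LineageGraph", nodes = nodes, edges = edges_df)
}

#' Export a lineage graph
#'
#' Writes the nearest-neighbor network as GraphML (via igraph) or as a
#' plain edge-list TSV.
#'
#' @param graph a [LineageGraph-class].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
writeLineageGraph <- function(graph, path,
                              format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  if (format == "edgelist") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = nodes[, c("node_id", "weight")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Full evaluation report for a partitioned repertoire
#'
#' Bundles the repertoire-level summaries: clonality fraction, cross-donor
#' contamination (when donors are available), pairwise precision/recall
#' (when truth is available), the lineage-size histogram, sequence- and
#' lineage-level germline usage, and the per-lineage feature table.
#'
#' @param records rearrangement data.frame.
#' @param partition a [LineagePartition-class].
#' @param donors optional named donor vector.
#' @param truth optional named truth vector.
#' @return A list with the report components.
#' @export
evaluationReport <- function(records, partition, donors = NULL,
                             truth = NULL) {
  sizes <- lineageSizes(partition)
  size_hist <- as.data.frame(table(size = sizes),
                             stringsAsFactors = FALSE)
  names(size_hist) <- c("size", "n_lineages")
  size_hist$size <- as.integer(size_hist$size)
  rep <- list(
    n_sequences = length(assignments(partition)),
    n_lineages = nLineages(partition),
    clonality_fraction = clonalityFraction(partition),
    size_histogram = size_hist,
    germline_usage_sequence = germlineUsage(records, level = "sequence"),
    germline_usage_lineage = germlineUsage(records, partition,
                                           level = "lineage"),
    feature_table = lineages(partition)[
      , c("lineage_id", "size", "mean_nt_mutations",
          "mean_aa_mutations", "mean_cdr3_len")])
  if (!is.null(donors)) {
    rep$contamination_fraction <-
      crossDonorContamination(partition, donors)
    rep$short_hcdr3 <- shortHcdr3Enrichment(records, partition, donors)
  }
  if (!is.null(truth)) {
    pr <- pairwisePrecisionRecall(partition, truth)
    rep$pairwise_precision <- pr$precision
    rep$pairwise_recall <- pr$recall
  }
  rep
}
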