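# Hand-built rearrangement records for metric and partition tests.
makeRecord <- function(id, v = "IGHV3-23*01", j = "IGHJ4*02",
                       cdr3 = "ARDYW", mutations = NULL,
                       donor = NA_character_) {
  rec <- data.frame(sequence_id = id, donor_id = donor, v_call = v,
                    j_call = j, cdr3_aa = cdr3,
                    junction_aa = paste0("C", cdr3, "W"),
                    junction = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(mutations)) rec$mutations <- list(mutations)
  rec
}

makeRecords <- function(...) do.call(rbind, list(...))

# Random annotated records (no lineage structure) for property tests.
randomRecords <- function(n, withMutations = TRUE) {
  cat <- germlineCatalog()
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  recs <- lapply(seq_len(n), function(i) {
    mut <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    if (withMutations && stats::runif(1) < 0.7) {
      k <- sample(0:6, 1)
      mut <- data.frame(pos = sample(300, k),
                        ref = sample(c("A","C","G","T"), k, TRUE),
                        alt = sample(c("A","C","G","T"), k, TRUE),
                        stringsAsFactors = FALSE)
      mut <- mut[mut$ref != mut$alt, , drop = FALSE]
    }
    makeRecord(paste0("rr", i),
               v = paste0(sample(cat$v$gene, 1), "*01"),
               j = paste0(sample(cat$j$gene, 1), "*01"),
               cdr3 = randomString(sample(6:18, 1), aa),
               mutations = mut)
  })
  do.call(rbind, recs)
}

# A LineagePartition built directly from a list of member-id vectors.
makePartition <- function(groups) {
  ids <- unlist(groups)
  lineage_ids <- sprintf("L%04d", seq_along(groups))
  a <- stats::setNames(rep(lineage_ids, lengths(groups)), ids)
  new("LineagePartition", assignments = a,
      lineages = data.frame(lineage_id = lineage_ids,
                            size = lengths(groups),
                            stringsAsFactors = FALSE),
      dropped = character(0))
}
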