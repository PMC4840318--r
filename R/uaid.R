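#' Extract 5'-embedded UAIDs from reads
#'
#' Each transcript is labeled before amplification with a random barcode
#' (unique antibody identifier, UAID) embedded at the 5' end of the read.
#' This splits every read into its barcode prefix and the remaining
#' transcript sequence. Reads not longer than the barcode are skipped with
#' a warning.
#'
#' @param reads a [Biostrings::DNAStringSet] or named character vector.
#' @param uaidLength barcode length in nucleotides (default 20).
#' @return A list with `uaid` (character vector), `reads` (trimmed
#'   character vector, same names) and `skipped` (ids of reads too short
#'   to carry a barcode).
#' @export
extractUAID <- function(reads, uaidLength = 20) {
  seqs <- as.character(reads)
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  ok <- nchar(seqs) > uaidLength
  if (any(!ok))
    warning(sum(!ok), " read(s) shorter than uaidLength + 1 skipped")
  seqs <- seqs[ok]
  list(uaid = unname(substr(seqs, 1L, uaidLength)),
       reads = stats::setNames(substring(seqs, uaidLength + 1L),
                               names(seqs)),
       skipped = names(reads)[!ok])
}

#' Group UAID-extracted reads into barcode bins
#'
#' @param uaids character vector of barcodes, parallel to `reads`.
#' @param reads character vector of trimmed read sequences.
#' @return Named list (names = UAIDs) of character vectors of reads; the
#'   bin sizes sum to the number of input reads.
#' @export
binByUAID <- function(uaids, reads) {
  stopifnot(length(uaids) == length(reads))
  split(reads, uaids)
}

#' Discard small UAID bins
#'
#' Bins containing fewer reads than `minBinSize` (by default singleton
#' bins) are discarded: a single read gives no opportunity for consensus
#' error correction, and singleton barcodes are enriched for barcode
#' sequencing errors.
#'
#' @param bins named list of read vectors from [binByUAID()].
#' @param minBinSize minimum retained bin size (default 2).
#' @return The retained bins; the number discarded is reported with a
#'   message.
#' @export
filterBins <- function(bins, minBinSize = 2) {
  keep <- lengths(bins) >= minBinSize
  if (any(!keep))
    message("discarded ", sum(!keep), " bin(s) below size ", minBinSize)
  bins[keep]
}

# Column-wise plurality vote over reads anchored at the modal read length.
# Reads shorter than the modal length are right-padded with N (no vote);
# longer reads are truncated. Vote ties go to the germline base when the
# germline covers the column and carries a tied base, else to the
# lexicographically smallest tied base. The germline contributes no votes.
.consensusVote <- function(seqs, germline = NULL) {
  lens <- nchar(seqs)
  ltab <- table(lens)
  modal_len <- as.integer(names(ltab)[which.max(ltab)])  # ties: smallest
  padded <- vapply(seqs, function(s) {
    if (nchar(s) >= modal_len) substr(s, 1L, modal_len)
    else paste0(s, strrep("N", modal_len - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
  mat <- matrix(unlist(strsplit(toupper(padded), "")), ncol = modal_len,
                byrow = TRUE)
  germ <- if (!is.null(germline))
    strsplit(toupper(germline), "")[[1]] else character(0)
  bases <- c("A", "C", "G", "T")
  cons <- vapply(seq_len(modal_len), function(j) {
    col <- mat[, j]
    col <- col[col %in% bases]
    if (!length(col)) return("N")
    tab <- table(col)
    tied <- names(tab)[tab == max(tab)]
    if (length(tied) == 1L) return(tied)
    if (j <= length(germ) && germ[j] %in% tied) return(germ[j])
    min(tied)
  }, character(1))
  paste(cons, collapse = "")
}

#' Build the consensus sequence of one UAID bin
#'
#' All reads in a bin are amplified copies of a single transcript, so a
#' per-column plurality vote recovers the true base wherever fewer than
#' half the reads carry an error at that column. On an exact vote tie the
#' germline variable-gene sequence acts as tiebreaker — it is added to the
#' comparison only to break ties, never as a counted vote; if the germline
#' does not cover the column (or does not carry a tied base) the
#' lexicographically smallest tied base is chosen.
#'
#' @param bin character vector of reads sharing one UAID.
#' @param germlineVSeq optional germline V-region nucleotide sequence
#'   aligned from the first read position.
#' @param uaid optional barcode (recorded in the result).
#' @return A list (`uaid`, `seq`, `support`): the consensus record.
#' @export
buildConsensus <- function(bin, germlineVSeq = NULL, uaid = NA_character_) {
  if (length(bin) == 0L) stop("cannot build a consensus of an empty bin")
  list(uaid = uaid, seq = .consensusVote(bin, germlineVSeq),
       support = length(bin))
}

#' UAID consensus correction of a barcoded read library
#'
#' End-to-end error and bias correction: extract barcodes, bin reads by
#' UAID, discard bins below the minimum size, and collapse each surviving
#' bin to its consensus transcript. Amplification bias is removed because
#' each original transcript contributes one consensus sequence regardless
#' of its copy number, and sequencing errors are suppressed by the
#' per-column vote.
#'
#' @param reads a [Biostrings::DNAStringSet] or named character vector of
#'   raw barcoded reads.
#' @param uaidLength barcode length (default 20).
#' @param minBinSize minimum bin size retained (default 2).
#' @param germline optional consensus tiebreaker: a single germline
#'   sequence applied to every bin, or a function `(uaid, binReads) ->`
#'   germline sequence (or NULL).
#' @param maxMismatchFrac bins whose mean per-read mismatch fraction
#'   against their consensus exceeds this value are flagged (column
#'   `flagged`), a guard against rare barcode collisions; no bin is split.
#' @return data.frame with one row per surviving bin: `uaid`, `sequence`,
#'   `support`, `flagged`.
#' @export
correctRepertoire <- function(reads, uaidLength = 20, minBinSize = 2,
                              germline = NULL, maxMismatchFrac = 0.1) {
  ex <- extractUAID(reads, uaidLength)
  bins <- binByUAID(ex$uaid, ex$reads)
  bins <- filterBins(bins, minBinSize)
  if (!length(bins))
    return(data.frame(uaid = character(0), sequence = character(0),
                      support = integer(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  out <- lapply(names(bins), function(u) {
    g <- if (is.function(germline)) germline(u, bins[[u]]) else germline
    cons <- buildConsensus(bins[[u]], germlineVSeq = g, uaid = u)
    mm <- vapply(bins[[u]], function(s) {
      n <- min(nchar(s), nchar(cons$seq))
      if (n == 0) return(0)
      a <- strsplit(substr(s, 1, n), "")[[1]]
      b <- strsplit(substr(cons$seq, 1, n), "")[[1]]
      mean(a != b)
    }, numeric(1))
    data.frame(uaid = u, sequence = cons$seq, support = cons$support,
               flagged = mean(mm) > maxMismatchFrac,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin-size report for a barcoded library
#'
#' @param reads raw barcoded reads.
#' @param uaidLength barcode length.
#' @param minBinSize size below which a bin is marked discarded.
#' @return data.frame (`uaid`, `size`, `kept`) sorted by decreasing size.
#' @export
binReport <- function(reads, uaidLength = 20, minBinSize = 2) {
  ex <- extractUAID(reads, uaidLength)
  tab <- table(ex$uaid)
  df <- data.frame(uaid = names(tab), size = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$kept <- df$size >= minBinSize
  df[order(-df$size, df$uaid), , drop = FALSE]
}
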