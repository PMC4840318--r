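#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that rejects empty
#' records, so downstream barcode extraction never sees a zero-length read.
#'
#' @param path file path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return A [Biostrings::DNAStringSet] named by record id (text up to the
#'   first whitespace of the header).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGTA"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  if (length(x) == 0L)
    stop("no sequence records found in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence entry in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param x a [Biostrings::DNAStringSet] or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.REQUIRED_REARR_COLS <- c("sequence_id", "v_call", "j_call",
                          "junction", "junction_aa")

#' Read annotated rearrangement records (AIRR-style TSV)
#'
#' Reads a tab-separated table of annotated antibody rearrangements using
#' AIRR Rearrangement column names. Required columns: `sequence_id`,
#' `v_call`, `j_call`, `junction`, `junction_aa`. Optional columns that
#' are used when present: `cdr3_aa`, `sequence_alignment`,
#' `germline_alignment`, `d_call`, `donor_id`, `uaid`, `clone_id`. Rows
#' missing a V call, J call or junction amino-acid sequence are dropped
#' with a message giving the count.
#'
#' @param path TSV file path.
#' @return data.frame of rearrangements, one row per retained record. If
#'   `cdr3_aa` is absent it is derived from `junction_aa` by stripping the
#'   two anchor residues.
#' @export
readRearrangements <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"),
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(.REQUIRED_REARR_COLS, names(df))
  if (length(missing_cols))
    stop("rearrangement table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- !is.na(df$v_call) & !is.na(df$j_call) & !is.na(df$junction_aa)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("dropped ", n_drop,
            " record(s) missing v_call, j_call or junction_aa")
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  if (!"cdr3_aa" %in% names(df) && nrow(df))
    df$cdr3_aa <- substr(df$junction_aa, 2L,
                         nchar(df$junction_aa) - 1L)
  df
}

#' Write rearrangement records to TSV
#'
#' List columns (e.g. mutation lists) are dropped; all other columns are
#' written as a plain AIRR-style tab-separated table readable by
#' [readRearrangements()].
#'
#' @param df data.frame of rearrangements.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRearrangements <- function(df, path) {
  keep <- !vapply(df, is.list, logical(1))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive somatic substitution list from an alignment pair
#'
#' Compares an aligned observed sequence to its aligned germline and
#' returns every position where both strings hold an unambiguous base and
#' the bases differ. Gap columns (`-` or `.`) and `N` bases yield no
#' mutation: the mutation list holds substitution events only, which is
#' what the shared-mutation bonus counts. Positions are 1-based indices in
#' the gapped alignment coordinate system, so the triple
#' (pos, ref, alt) identifies the same substitution event across sequences
#' aligned to the same germline.
#'
#' @param sequenceAlignment aligned observed nucleotide string.
#' @param germlineAlignment aligned germline nucleotide string of the same
#'   length.
#' @return data.frame with columns `pos` (integer), `ref`, `alt`.
#' @examples
#' deriveMutations("ACTT", "ACGT")  # one substitution G3T
#' deriveMutations("AC-T", "ACGT") # gap column: no mutation
#' @export
deriveMutations <- function(sequenceAlignment, germlineAlignment) {
  if (length(sequenceAlignment) != 1L || length(germlineAlignment) != 1L)
    stop("deriveMutations() takes single strings")
  if (nchar(sequenceAlignment) != nchar(germlineAlignment))
    stop("sequence and germline alignments must have equal length")
  s <- strsplit(toupper(sequenceAlignment), "")[[1]]
  g <- strsplit(toupper(germlineAlignment), "")[[1]]
  bases <- c("A", "C", "G", "T")
  hit <- s != g & s %in% bases & g %in% bases
  data.frame(pos = which(hit), ref = g[hit], alt = s[hit],
             stringsAsFactors = FALSE)
}

#' Parse a gene call to its family token
#'
#' Strips the allele suffix (`*01` etc.) and returns the text before the
#' first hyphen, e.g. `"IGHV3-23*01"` -> `"IGHV3"`. Genes without a hyphen
#' (J genes) are their own family. Names that do not look like an
#' IMGT-style gene (letters followed by digits) are an error.
#'
#' @param geneCall character vector of gene names.
#' @return character vector of family tokens.
#' @examples
#' geneFamily(c("IGHV3-23*01", "IGHJ6*02"))
#' @export
geneFamily <- function(geneCall) {
  fam <- sub("-.*$", "", sub("\\*.*$", "", geneCall))
  bad <- !grepl("^[A-Za-z]+[0-9]+$", fam) | is.na(fam)
  if (any(bad))
    stop("unparseable gene call(s): ",
         paste(unique(geneCall[bad]), collapse = ", "))
  fam
}

#' Parse a gene call to gene level (allele stripped)
#'
#' @param geneCall character vector of gene names.
#' @return character vector with allele suffixes removed.
#' @examples
#' geneName("IGHV3-23*01")
#' @export
geneName <- function(geneCall) {
  sub("\\*.*$", "", geneCall)
}

# Integer encoding of a substitution event for fast set intersection:
# pos * 16 + ref * 4 + alt with bases coded A=0, C=1, G=2, T=3.
.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.mutationKeys <- function(mut) {
  if (is.null(mut) || nrow(mut) == 0L) return(integer(0))
  sort(unique(as.integer(mut$pos) * 16L +
              .BASE_CODE[mut$ref] * 4L + .BASE_CODE[mut$alt]))
}

# Per-record sorted mutation-key lists for a rearrangement data.frame.
# Uses a `mutations` list-column when present (each element a data.frame
# of pos/ref/alt), otherwise derives substitutions from the alignment
# columns; records without alignments get an empty list.
.recordMutationKeys <- function(records) {
  n <- nrow(records)
  if (!is.null(records$mutations)) {
    return(lapply(records$mutations, .mutationKeys))
  }
  if (all(c("sequence_alignment", "germline_alignment") %in%
          names(records))) {
    ok <- !is.na(records$sequence_alignment) &
      !is.na(records$germline_alignment)
    keys <- vector("list", n)
    keys[!ok] <- list(integer(0))
    keys[ok] <- lapply(which(ok), function(i) {
      .mutationKeys(deriveMutations(records$sequence_alignment[i],
                                    records$germline_alignment[i]))
    })
    return(keys)
  }
  rep(list(integer(0)), n)
}

# Frame-1 translation via a plain codon lookup (standard genetic code);
# incomplete or ambiguous codons translate to X. Used on hot paths where
# per-record S4 dispatch would dominate.
.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translateNT <- function(nt) {
  n3 <- (nchar(nt) %/% 3L) * 3L
  if (n3 < 3L) return("")
  cods <- substring(toupper(nt), seq(1L, n3, 3L), seq(3L, n3, 3L))
  aa <- unname(.GENETIC_CODE[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Amino-acid substitution count from an alignment pair: gap columns are
# removed, both strings are translated in frame 1 and residue mismatches
# counted (ambiguous codons excluded). Approximate when indels are present.
.aaMutationCount <- function(sequenceAlignment, germlineAlignment) {
  if (is.na(sequenceAlignment) || is.na(germlineAlignment)) return(NA_real_)
  s <- strsplit(toupper(sequenceAlignment), "")[[1]]
  g <- strsplit(toupper(germlineAlignment), "")[[1]]
  keep <- !(s %in% c("-", ".")) & !(g %in% c("-", "."))
  s <- s[keep]; g <- g[keep]
  n <- (length(s) %/% 3L) * 3L
  if (n < 3L) return(0)
  saa <- strsplit(.translateNT(paste(s[1:n], collapse = "")), "")[[1]]
  gaa <- strsplit(.translateNT(paste(g[1:n], collapse = "")), "")[[1]]
  ok <- saa != "X" & gaa != "X"
  sum(saa[ok] != gaa[ok])
}
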