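# Independent oracle for the weighted edit distance: memoised top-down
# recursion over prefixes, sharing no code with the package's bottom-up
# dynamic-programming kernel.
oracleWlev <- function(a, b, sub = 1, indel = 2) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j * indel)
    if (j == 0L) return(i * indel)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(
      rec(i - 1L, j - 1L) +
        if (substr(a, i, i) == substr(b, j, j)) 0 else sub,
      rec(i - 1L, j) + indel,
      rec(i, j - 1L) + indel)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

randomString <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# All strings over `alphabet` of length 0..maxLen.
allStrings <- function(maxLen, alphabet = c("A", "C", "G", "T")) {
  out <- ""
  level <- ""
  for (l in seq_len(maxLen)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}
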