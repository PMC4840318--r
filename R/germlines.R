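# Built-in toy germline catalog used by the repertoire simulator.
#
# The sequences are fixed synthetic stand-ins, not IMGT germline alleles:
# they carry realistic gene names (10 V genes spanning 6 families, 6 J
# genes) so that family parsing, gene-use penalties and the pre-screen
# behave as on real annotations, but the nucleotide strings themselves are
# arbitrary. Gene weights approximate the skewed usage of human heavy
# chain repertoires (IGHV3/IGHV4 families and IGHJ4 dominate).

.V_CATALOG <- data.frame(
  gene = c("IGHV1-2", "IGHV1-69", "IGHV2-5", "IGHV3-23", "IGHV3-30",
           "IGHV3-7", "IGHV4-34", "IGHV4-59", "IGHV5-51", "IGHV6-1"),
  weight = c(1.2, 1.5, 0.5, 2.2, 1.8, 1.2, 1.4, 1.0, 0.8, 0.4),
  seq = c(
    "AATTGGGGAGGGGTAACGATTAGGTTTTCGCTTTGCCCTTGAGCCCGCTGCGTCAAGTTTGATCAAAGAATTGCGGTGGCAGAAAGGTTAATTAATCGGGAATGAGACTAATTATCTGACAAATGATAGAGTGAGTCGCGCGGCCGGGGCAATCCATGATTGGAGAACATGGGCGGATATCACTTTAGGACATCCAACAGGCGGCTTTAGTCGTACCTGCCTGAATGGGTACAATACTTGACCTCTTATCATGTATAACGAGTAGTTAGTGACATGTTTGTGAAACTG",
    "TTTGGTGGGATATTTAAAGTAAGGAGGGATTCTGAGCTTCCTAGGTATGGGCGTGAACGCGCGTTGGCTCTCGGGAGTTGCCTAATTACTGTGGACGTGGGATCGTAGACAAGGTCATCCAAGTGGGTCGGGCAGCTGGAAGAATATCTCACCGCGAGTGGTAGGATTGGTTGAAGTGCCGTTCGCGACGTAACCAGACTATATGACTTGAGAGTTCGTCCAGGCGGGGACGCCGGGCGCAAGCGAGCGCGGTCCAAATGAGGCAACTATATGGGCGAATATTCGCCA",
    "TCAGAAAGTGGAAGTCGGAGCCCGACCTGTTCTTCAGATAACTGCCTAAAATTGGGCATTGCCACAAGGCTGGTTGATACGGTGCGATGATCTGGGCGTAGTGCTATTTTAAGACTAGTCAGCCCGATCAAATCGTCGCGCCTTAAATAAGGTGTTACGGCTTGGCGTCCATCCTCATTCGCGACAGGAGCGCATTTACAATAGTGGGCCGACAATGTGAGCGGACACACGCACGGTGGCATTAATCAGGATAATTAAGGGACGTGGATTCGCGCATAAGGAAAGAAT",
    "GCGCAACAAAGCGATAGGGCCGTCCTCTACTCGTCAGCGGTGGTCGCGTACCAGACGTTTCAGGATAAAGTATCCGGGGGATAAAATGCGGATTATAAGTACTGCGACTGACAAGATTGTACGTAAGACCAATAGTCTGGCGTATACGGTGGCAATGCGCGCCGATAAGGTATTAGGTGCTGTATGTGGTCTAGGGCGTGACGAATTCTCATTCGACGGAGATGTATCGACTCTGAGTCTCAGTGCGTTACATGTGGACCGTACAAGATACGGTCGCTGAGCCCATCT",
    "AAGTGAAGCCCGTAGGTGTCCTGGTGGGTGGTTAGAAAGGCATCCGCTCTGACGTTAGACGGTTGTTTAGTAGGGGAGATGGATTTGACCATAGTACCAGCTGAGATAAAAGTTAAGCTTGATTCTAGTATTGTTGAGGTGGAGAGGCCCTAAGAGAAGTCCACGTGTGTGGCCATTGAAGAGGATGTAACGCAGTCGCAAGGTAAGTTCTGTGGCACGAATCAATAAAGCGCAGCTCATACGTGAAGGAACAAATACATGATGGGCGGCCGATCTTACGTTTTACTC",
    "TCGGTGTTGCTTGCGGTGATTCCAACAATTAGGAGATCATCTACTACTTTCCCGAGGAATGTATCGCCTGAGCGTTTAGGAAGGGGGAGCTTTCAATCTGCCGCCGAGCCGATAAAGGGACTTTCTCGATCATCGAATTGGGTGGGCACCTATATTAGGGGATAAGGTGTACTGTATGGGGTGTCGCTAATCTGAAAGATGTCACGACAGATTAGGGGATCACGATGCTGAATAAGGTTGCTGACTGTGTAGTGAAATATTATCAGAAAGGGTATGCTGACCGTACTA",
    "CGTAGACTTAGGCGGAAATAGATAACTTATTTTAAGACCCCGTCTACGGGAGTCTTCTCTTTGACCGCAATGATCCTAGGGGGTGTTAGCAGTCTTACTGTCTTCGTCGGCAAAATTTTCTAGGTTAGTGACCTGATTACGCCACATACAACGCTGTGGCGAGATGGGATATTGGCAGGTGTTAACCAGCAGAGCCATGCACTGGGCGGAACCCACTCAGATAGAGGGAATTTTGCCCGCGGTAAAAAATGGTGCAGCCTCGGGGTTAAACGGTTAAAAAATTAATGT",
    "CAACTGGAGGAACGATATGTGTCAAGCTCTGGCTCGCCATGTGCACACGGGGTTTGTCCTGCGTAACCTTTAGGTGGAGTGGTCTGTATCTGCGGCAAGAGACGATCGTCAACTAATCTGTTCAGACACCCAAACGTTTGTACCGTCGCACATTTAATGAGATCGGTGGTCCGGTATGTCGGGGCGTAAAAAAAAGTTAGTGCACGTATGTAGCGCTTCAAATTGTGTAACGCAAAGTGCTTTTGATCACATTCTGATGGGATTAACCGTATACACTGAAATTGGAGT",
    "GCTGAGATCGGGAGACTTGAGAGGTGATTGAGGATGTTGGCGCGGCTGCGGTTATACATCCACATGACATCCACTAAATCCACTCATCTACGCCACCGGCCTGTTGGATGCTTGGAAGAGATCGGATGCTAAAAGATCTACAAGCTGTTGTCCTGGGGAGGATCAAGCGGTGCTGCCAGGAGAAGCCACAATGTAGTACGGGCTGGTGTAACGTGTGCTGCCCCCTCAGTCGCGGCAGGTAGCTTGTTGCACCATGGGGAGACGATTAGGGAAAAGGCCAACTATAGG",
    "TGGTGACATCTCCGGGCACCATTCTTGAGGCTACCGTACGTTGGGTAGAGTCAAGCATATTTGTACCCTAGGCCGTGTTACTAGCACAAGTACTGGGAGAGATCGCGTGGAGTAAGTCGGGTAGCCAAGTGTGCCTTGGGCTTATGGCAGCTTAAGTTTAGCGGGTTGTAGATGGGGAGAGTTAATAGTAGCCACCAGGCTCCCGGTAGTTGGTTGGTCGCGACTTTCGCCCTGTTAAAGGAGATCAGATGGGCACCGCGCCACCTCCGATCCTCGGGGCAGGAAGGA"),
  stringsAsFactors = FALSE
)

.J_CATALOG <- data.frame(
  gene = c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6"),
  weight = c(0.4, 0.6, 0.8, 3.0, 1.0, 1.6),
  seq = c(
    "AGTTTCGTATTCGTATGCGCTGGAACTGCTGAATGTTGGCATGTGCTA",
    "GGACGGCGAGGTTAAGGATGTGGGCTTTGAAGCTTGATTTCCATGGTC",
    "AGGGCGAAGCGCAATCGTACAATGAGCTCGAAACGCGCTATATCCTCG",
    "TGTCTGAGAAATGTATCCAAAGCGGTCGTTTTCATACAGCGGTTCTTC",
    "GTAGTCTTTGGTGAGACCGCCAATAGCATTAGCTCAAACGACTAGTAA",
    "CCATGTGAAGCCGGTGTACAGTGGTTCGCAGTCCTATTATGAATTCTC"),
  stringsAsFactors = FALSE
)

#' Built-in synthetic germline catalog
#'
#' Returns the small fixed V/J gene catalog used by the simulator: 10 V
#' genes across 6 families and 6 J genes, with usage weights. The
#' sequences are synthetic stand-ins carrying IMGT-style names, not real
#' germline alleles.
#'
#' @return A list with data.frames `v` and `j`, each with columns `gene`,
#'   `weight` and `seq`.
#' @examples
#' cat <- germlineCatalog()
#' nrow(cat$v)
#' @export
germlineCatalog <- function() {
  list(v = .V_CATALOG, j = .J_CATALOG)
}
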