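#' Ranked E. coli codon table
#'
#' Codons for the 20 standard amino acids ranked by usage frequency in
#' highly expressed *Escherichia coli* genes (rank 1 = preferred codon).
#' [reverse_translate()] walks down the ranks only when the preferred
#' codon would create a forbidden restriction motif, so oligo design is
#' deterministic.
#'
#' @return A tibble with columns `amino_acid` (one-letter code), `codon`
#'   (DNA triplet) and `rank` (1 = most used).
#' @export
#' @examples
#' ecoli_codon_table()
ecoli_codon_table <- function() {
  ranked <- list(
    A = c("GCG", "GCC", "GCA", "GCT"),
    R = c("CGT", "CGC", "CGG", "CGA", "AGA", "AGG"),
    N = c("AAC", "AAT"),
    D = c("GAT", "GAC"),
    C = c("TGC", "TGT"),
    Q = c("CAG", "CAA"),
    E = c("GAA", "GAG"),
    G = c("GGC", "GGT", "GGG", "GGA"),
    H = c("CAT", "CAC"),
    I = c("ATT", "ATC", "ATA"),
    L = c("CTG", "TTA", "TTG", "CTC", "CTT", "CTA"),
    K = c("AAA", "AAG"),
    M = "ATG",
    F = c("TTT", "TTC"),
    P = c("CCG", "CCA", "CCT", "CCC"),
    S = c("AGC", "TCT", "AGT", "TCC", "TCA", "TCG"),
    T = c("ACC", "ACG", "ACT", "ACA"),
    W = "TGG",
    Y = c("TAT", "TAC"),
    V = c("GTG", "GTT", "GTC", "GTA")
  )
  tibble(
    amino_acid = rep(names(ranked), lengths(ranked)),
    codon = unlist(ranked, use.names = FALSE),
    rank = unlist(lapply(lengths(ranked), seq_len), use.names = FALSE)
  )
}
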