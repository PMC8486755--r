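## Genetic code tables. Stops are "*".

.codons <- function() {
  nt <- c("T", "C", "A", "G")
  as.vector(outer(outer(nt, nt, function(a, b) paste0(a, b)), nt, paste0))
}

.standard_code <- function() {
  # 64 codons in TTT, CTT, ..., order produced by .codons(): first base
  # varies fastest, then second, then third.
  codons <- .codons()
  aa_by_codon <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa_by_codon[codons]
}

#' Genetic code table
#'
#' Returns a named character vector mapping the 64 codons to 1-letter amino
#' acids, with `"*"` for stop codons. The vertebrate mitochondrial code
#' (default elsewhere in the package) differs from the standard code at
#' AGA/AGG (stop), ATA (Met) and TGA (Trp); the invertebrate mitochondrial
#' code additionally assigns AGA/AGG to Ser.
#'
#' @param table One of `"vertebrate.mito"`, `"invertebrate.mito"`,
#'   `"standard"`.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(table = c("vertebrate.mito", "invertebrate.mito",
                                   "standard")) {
  table <- match.arg(table)
  code <- .standard_code()
  if (table == "vertebrate.mito") {
    code[c("AGA", "AGG")] <- "*"
    code["ATA"] <- "M"
    code["TGA"] <- "W"
  } else if (table == "invertebrate.mito") {
    code[c("AGA", "AGG")] <- "S"
    code["ATA"] <- "M"
    code["TGA"] <- "W"
  }
  code
}
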