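#' @keywords internal
"_PACKAGE"

## Amino-acid alphabets and physicochemical constants used across the package.

#' The 20 standard amino acids (1-letter codes, alphabetical)
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Characters accepted in alignment rows: residues, gap and ambiguity
#' @noRd
ALIGNMENT_ALPHABET <- c(AMINO_ACIDS, "-", "X")

# 3-letter <-> 1-letter residue codes (PDB convention)
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1_TO_3 <- stats::setNames(names(AA3), unname(AA3))

# Grantham (1974) polarity and volume, the two properties underlying the
# Miyata et al. (1979) physicochemical distance.
GRANTHAM_POLARITY <- c(
  A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
  G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
  P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)
GRANTHAM_VOLUME <- c(
  A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
  G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
  P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84)

.build_miyata <- function() {
  aa <- names(GRANTHAM_POLARITY)
  p <- GRANTHAM_POLARITY
  v <- GRANTHAM_VOLUME
  # Normalisation constants: standard deviation of the property differences
  # over the 190 unordered amino-acid pairs, per the published construction.
  pairs <- utils::combn(aa, 2)
  dp <- abs(p[pairs[1, ]] - p[pairs[2, ]])
  dv <- abs(v[pairs[1, ]] - v[pairs[2, ]])
  sp <- stats::sd(dp)
  sv <- stats::sd(dv)
  m <- sqrt(outer(p, p, "-")^2 / sp^2 + outer(v, v, "-")^2 / sv^2)
  dimnames(m) <- list(aa, aa)
  m
}

#' Miyata amino-acid distance matrix
#'
#' The symmetric 20x20 matrix of physicochemical distances between amino
#' acids of Miyata, Miyazawa and Yasunaga (1979), built from Grantham (1974)
#' polarity and volume with each property difference scaled by the standard
#' deviation of the 190 pairwise differences. The construction reproduces the
#' published entries at their printed precision (e.g. Pro-Ala 0.06, Leu-Ile
#' 0.14, Lys-Arg 0.40, Cys-Pro 1.33).
#'
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named by 1-letter amino-acid codes.
#' @examples
#' m <- miyata_matrix()
#' round(m["P", "A"], 2)  # 0.06
#' @export
miyata_matrix <- function() .MIYATA

.MIYATA <- .build_miyata()
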