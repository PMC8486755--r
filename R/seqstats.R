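## Standalone statistics: NG86 pairwise dN/dS, the hypergeometric
## conservation probability, and Miyata similarity ranks.

.split_codons <- function(x) {
  x <- toupper(gsub("\\s", "", x))
  if (nchar(x) %% 3 != 0)
    stop("sequence length (", nchar(x), ") is not a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# Fraction of the 9 single-nucleotide changes of a codon that are synonymous,
# summed per position (each position contributes syn/3). Changes to stop
# codons count as nonsynonymous, the usual NG86 convention.
.syn_sites <- function(codon, code) {
  nt <- c("T", "C", "A", "G")
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] != "*" && code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all orderings of single-nucleotide steps; paths through stop codons are
# excluded (all paths are used as fallback when every path is blocked).
.codon_diffs <- function(a, b, code) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1) list(pos) else {
    perms <- if (nd == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
    perms
  }
  walk <- function(order) {
    cur <- a
    syn <- 0; non <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") return(NULL)
      if (code[[cur]] == code[[nxt]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk))
  if (length(res) == 0) {
    # every route passes a stop: fall back to averaging over all routes,
    # scoring each step by amino-acid change
    walk_any <- function(order) {
      cur <- a; syn <- 0; non <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (code[[cur]] == code[[nxt]]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    }
    res <- lapply(paths, walk_any)
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[[1]], nd = m[[2]])
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Estimates synonymous (dS) and nonsynonymous (dN) substitution rates
#' between two in-frame codon sequences by the NG86 unweighted-pathway
#' method with Jukes-Cantor correction. Codons containing anything other
#' than A, C, G, T in either sequence, and codon pairs involving a stop
#' codon, are skipped pairwise.
#'
#' @param seq_a,seq_b Nucleotide strings of equal length, a multiple of 3.
#' @param table Translation table, see [genetic_code()]; vertebrate
#'   mitochondrial by default.
#' @return An object of class `"dnds"`: a list with elements `S`, `N`
#'   (average synonymous/nonsynonymous site counts), `Sd`, `Nd` (observed
#'   differences), `pS`, `pN`, `dS`, `dN` (Jukes-Cantor distances, `NA` when
#'   saturated, i.e. p >= 3/4), `ratio` (dN/dS; `NA` i.e. undefined when no
#'   synonymous divergence is observed; 0 when dN is 0 with synonymous
#'   divergence present), `n_codons` (codon pairs compared).
#' @examples
#' ng86_dnds("TTTTTA", "TTCTTA")  # one synonymous difference
#' @export
ng86_dnds <- function(seq_a, seq_b,
                      table = c("vertebrate.mito", "invertebrate.mito",
                                "standard")) {
  code <- genetic_code(match.arg(table))
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences differ in length: ", 3 * length(ca), " vs ",
         3 * length(cb), " nt")
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  is_stop <- rep(FALSE, length(ca))
  is_stop[clean] <- code[ca[clean]] == "*" | code[cb[clean]] == "*"
  clean <- clean & !is_stop
  ca <- ca[clean]; cb <- cb[clean]
  n_codons <- length(ca)
  if (n_codons == 0)
    stop("no comparable codon pairs after filtering gaps/ambiguity/stops")
  s_a <- sum(vapply(ca, .syn_sites, 0, code = code))
  s_b <- sum(vapply(cb, .syn_sites, 0, code = code))
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S
  diffs <- mapply(function(a, b) .codon_diffs(a, b, code), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)  # saturated
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  ratio <- if (Sd == 0) {
    NA_real_  # undefined: no synonymous divergence observed
  } else if (Nd == 0) {
    0
  } else if (is.na(dS) || is.na(dN)) {
    NA_real_
  } else {
    dN / dS
  }
  structure(
    list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN, ratio = ratio, n_codons = n_codons,
         saturated = (pS >= 3 / 4) || (pN >= 3 / 4)),
    class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat("Nei-Gojobori (1986) pairwise dN/dS\n")
  cat(sprintf("  codons compared: %d\n", x$n_codons))
  cat(sprintf("  sites      S = %.2f   N = %.2f\n", x$S, x$N))
  cat(sprintf("  differences Sd = %.2f  Nd = %.2f\n", x$Sd, x$Nd))
  cat(sprintf("  dS = %s  dN = %s  dN/dS = %s%s\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              if (is.na(x$ratio)) "undefined" else format(x$ratio, digits = 4),
              if (isTRUE(x$saturated)) "  [saturated]" else ""))
  invisible(x)
}

#' Probability that all contact sites fall on conserved residues
#'
#' Given a protein of `protein_length` residues of which `n_identical_sites`
#' are identical between two sequences, returns the probability that
#' `n_contacts` sites drawn without replacement all land among the identical
#' ones (hypergeometric, no non-identical site sampled):
#' prod_{i=0}^{k-1} (K - i) / (N - i).
#'
#' @param n_contacts Number of contact sites drawn (k).
#' @param n_identical_sites Number of identical sites (K).
#' @param protein_length Protein length (N).
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"binomial"` (the (K/N)^k approximation, exposed for comparison).
#' @return A probability in `[0, 1]`.
#' @examples
#' conserved_contact_probability(7, round(0.59 * 174), 174)
#' @export
conserved_contact_probability <- function(n_contacts, n_identical_sites,
                                          protein_length,
                                          method = c("hypergeometric",
                                                     "binomial")) {
  method <- match.arg(method)
  k <- n_contacts; K <- n_identical_sites; N <- protein_length
  if (k < 0 || K < 0 || N <= 0 || K > N)
    stop("need 0 <= n_identical_sites <= protein_length and n_contacts >= 0")
  if (k > N)
    stop("n_contacts (", k, ") exceeds protein_length (", N, ")")
  if (method == "binomial") return((K / N)^k)
  if (k > K) return(0)
  if (k == 0) return(1)
  prod((K - seq_len(k) + 1) / (N - seq_len(k) + 1))
}

#' Rank of an amino acid by Miyata physicochemical similarity
#'
#' Ranks `query_aa` among the 19 non-reference amino acids sorted by
#' ascending Miyata distance to `reference_aa`; ties are broken
#' alphabetically.
#'
#' @param reference_aa,query_aa Distinct 1-letter amino-acid codes.
#' @param matrix Distance matrix, by default [miyata_matrix()].
#' @return Integer rank in 1..19.
#' @examples
#' miyata_rank("V", "A")
#' @export
miyata_rank <- function(reference_aa, query_aa, matrix = miyata_matrix()) {
  if (!reference_aa %in% rownames(matrix) || !query_aa %in% rownames(matrix))
    stop("non-standard amino acid: ",
         paste(setdiff(c(reference_aa, query_aa), rownames(matrix)),
               collapse = ", "))
  if (reference_aa == query_aa)
    stop("reference and query amino acids must differ")
  others <- setdiff(rownames(matrix), reference_aa)
  d <- matrix[reference_aa, others]
  ordered <- others[order(d, others)]
  which(ordered == query_aa)
}
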