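## Pathogenic-mutation catalogue: rCRS coordinate mapping and the
## configurable pathogenicity rubric.

ND_GENES <- c("ND1", "ND2", "ND3", "ND4L", "ND4", "ND5", "ND6")

# rCRS spans of the seven mtDNA-encoded Complex I genes. ND6 is encoded on
# the light strand, so its reading frame runs from the high coordinate down.
.ND_SPANS <- data.frame(
  gene = ND_GENES,
  start = c(3307, 4470, 10059, 10470, 10760, 12337, 14149),
  end = c(4262, 5511, 10404, 10766, 12137, 14148, 14673),
  strand = c("heavy", "heavy", "heavy", "heavy", "heavy", "heavy", "light"),
  stringsAsFactors = FALSE)

#' rCRS coordinates of the mtDNA-encoded Complex I genes
#'
#' Packaged constants giving the revised Cambridge Reference Sequence span
#' and coding strand of ND1-ND6 and ND4L. The table is self-checked at every
#' call against three known nucleotide-to-protein mappings
#' (m.3481 -> ND1:59, m.10158 -> ND3:34, m.14487 -> ND6:63) so a transcription
#' error in the constants cannot pass silently.
#'
#' @return Data frame with columns `gene`, `start`, `end`, `strand`.
#' @export
gene_coordinates <- function() {
  coords <- .ND_SPANS
  chk <- function(gene, nt, expected) {
    .nt_to_protein_site_raw(gene, nt, coords) == expected
  }
  if (!(chk("ND1", 3481, 59) && chk("ND3", 10158, 34) &&
        chk("ND6", 14487, 63)))
    stop("packaged rCRS gene coordinates failed their self-check")
  coords
}

.nt_to_protein_site_raw <- function(gene, nt_position, coords) {
  row <- coords[coords$gene == gene, ]
  if (nrow(row) == 0) stop("unknown gene: ", gene)
  if (nt_position < row$start || nt_position > row$end)
    stop("position m.", nt_position, " outside ", gene, " span (",
         row$start, "-", row$end, ")")
  offset <- if (row$strand == "heavy") nt_position - row$start + 1
            else row$end - nt_position + 1
  as.integer(ceiling(offset / 3))
}

#' Map an rCRS nucleotide position to a protein residue number
#'
#' Heavy-strand genes read forward from `start`; the light-strand gene ND6
#' reads backward from `end`. The protein position is `ceiling(offset / 3)`
#' with a 1-based in-gene offset.
#'
#' @param gene Gene symbol, one of ND1, ND2, ND3, ND4L, ND4, ND5, ND6.
#' @param nt_position 1-based rCRS coordinate inside the gene.
#' @param coords Coordinate table, defaults to [gene_coordinates()].
#' @return Integer protein position (1-based from Met1).
#' @examples
#' nt_to_protein_site("ND1", 3481)  # 59
#' nt_to_protein_site("ND6", 14487) # 63 (light strand)
#' @export
nt_to_protein_site <- function(gene, nt_position, coords = gene_coordinates()) {
  .nt_to_protein_site_raw(gene, nt_position, coords)
}

#' Parse "m.3481G>A" / "E59K" change notations
#'
#' @param x Nucleotide change such as `"m.3481G>A"` (the `m.` prefix and
#'   spaces are optional) or amino-acid change such as `"E59K"`.
#' @return For `parse_nt_change`, a list with `position`, `ref`, `alt`; for
#'   `parse_aa_change`, a list with `ref`, `position`, `alt`.
#' @export
parse_nt_change <- function(x) {
  m <- regmatches(x, regexec("^m?\\.?\\s*(\\d+)\\s*([ACGT])\\s*>\\s*([ACGT])$",
                             gsub(" ", "", x)))[[1]]
  if (length(m) == 0) stop("cannot parse nucleotide change: '", x, "'")
  list(position = as.integer(m[2]), ref = m[3], alt = m[4])
}

#' @rdname parse_nt_change
#' @export
parse_aa_change <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])(\\d+)([A-Z])$", gsub(" ", "", x)))[[1]]
  if (length(m) == 0) stop("cannot parse amino-acid change: '", x, "'")
  if (!all(c(m[2], m[4]) %in% AMINO_ACIDS))
    stop("non-standard amino acid in change '", x, "'")
  if (m[2] == m[4]) stop("reference and alternate amino acids are equal in '",
                         x, "'")
  list(ref = m[2], position = as.integer(m[3]), alt = m[4])
}

#' Read a pathogenic-mutation catalogue
#'
#' Expects a TSV with columns `gene`, `nt_change` (e.g. `m.3481G>A`),
#' `aa_change` (e.g. `E59K`), `disease`, `status`, and optionally
#' `complex_disease_only` (logical pre-filter flag) plus evidence columns
#' named `ev_*` (logical). The protein position implied by `aa_change` is
#' checked against the nucleotide position through the coordinate map;
#' disagreement is a hard error naming the row.
#'
#' @param path TSV file.
#' @param filter_complex Drop records flagged `complex_disease_only`
#'   (default TRUE, mirroring the removal of variants reported only in
#'   association with complex diseases).
#' @return Data frame of class `"mutation_catalogue"` with added integer
#'   column `protein_position` and parsed `ref_aa`, `alt_aa`, `nt_position`.
#' @export
read_catalogue <- function(path, filter_complex = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "nt_change", "aa_change", "disease", "status")
  if (!all(need %in% names(tab)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  coords <- gene_coordinates()
  parsed_nt <- lapply(tab$nt_change, parse_nt_change)
  parsed_aa <- lapply(tab$aa_change, parse_aa_change)
  tab$nt_position <- vapply(parsed_nt, `[[`, 0L, "position")
  tab$ref_nt <- vapply(parsed_nt, `[[`, "", "ref")
  tab$alt_nt <- vapply(parsed_nt, `[[`, "", "alt")
  tab$ref_aa <- vapply(parsed_aa, `[[`, "", "ref")
  tab$alt_aa <- vapply(parsed_aa, `[[`, "", "alt")
  tab$protein_position <- vapply(parsed_aa, `[[`, 0L, "position")
  mapped <- mapply(nt_to_protein_site, tab$gene, tab$nt_position,
                   MoreArgs = list(coords = coords))
  bad <- which(mapped != tab$protein_position)
  if (length(bad) > 0)
    stop("catalogue row(s) ", paste(bad, collapse = ", "),
         ": nucleotide position maps to protein position ",
         paste(mapped[bad], collapse = ", "), " but aa_change says ",
         paste(tab$protein_position[bad], collapse = ", "))
  if (filter_complex && "complex_disease_only" %in% names(tab))
    tab <- tab[!as.logical(tab$complex_disease_only), , drop = FALSE]
  class(tab) <- c("mutation_catalogue", "data.frame")
  tab
}

#' @rdname read_catalogue
#' @param catalogue Data frame to write.
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.table(as.data.frame(catalogue), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

PATHOGENICITY_CRITERIA <- c("independent_reports", "heteroplasmy",
                            "segregation", "biochemical_defect",
                            "cybrid", "single_fibre", "prediction")

#' Default pathogenicity scoring rubric
#'
#' Shipped default weights and class thresholds for [score_pathogenicity()].
#' The weighting follows the principle that functional laboratory evidence
#' (cybrid transfer and single-fibre studies) carries the most persuasive
#' genotype-phenotype link and therefore the largest weights. The precise
#' point values are an assumption of this package, not a published schedule;
#' treat them as a starting configuration and tune to your catalogue.
#'
#' @return A list with elements `weights` (named non-negative numerics over
#'   the seven criteria) and `thresholds` (named, ascending: minimum score
#'   for `possibly`, `probably`, `definitely`).
#' @export
default_rubric <- function() {
  list(
    weights = c(independent_reports = 2, heteroplasmy = 2, segregation = 2,
                biochemical_defect = 4, cybrid = 7, single_fibre = 7,
                prediction = 2),
    thresholds = c(possibly = 5, probably = 11, definitely = 18))
}

#' Score pathogenicity evidence against a rubric
#'
#' The score is the sum of weights of satisfied criteria; the status is the
#' highest class whose threshold does not exceed the score. Classification is
#' therefore monotone non-decreasing in evidence.
#'
#' @param evidence Character vector of satisfied criterion names, or a named
#'   logical vector over criteria.
#' @param rubric A rubric as returned by [default_rubric()].
#' @return List with `score` and `status` (one of `"neutral"`, `"possibly"`,
#'   `"probably"`, `"definitely"`).
#' @export
score_pathogenicity <- function(evidence, rubric = default_rubric()) {
  if (is.logical(evidence)) evidence <- names(evidence)[evidence]
  unknown <- setdiff(evidence, names(rubric$weights))
  if (length(unknown) > 0)
    stop("unknown evidence criterion: ", paste(unknown, collapse = ", "))
  if (any(rubric$weights < 0)) stop("rubric weights must be non-negative")
  score <- sum(rubric$weights[evidence])
  th <- sort(rubric$thresholds)
  status <- "neutral"
  for (cls in names(th)) if (score >= th[[cls]]) status <- cls
  list(score = unname(score), status = status)
}
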