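## Mapping catalogue sites into alignment columns, column profiles, and the
## CPD species scan itself.

.align_chars <- function(alignment, column_index) {
  vapply(alignment$rows, substr, "", column_index, column_index)
}

#' Alignment column holding a human protein position
#'
#' Returns the column containing the `protein_position`-th non-gap character
#' of the human reference row.
#'
#' @param alignment A [species_alignment()].
#' @param protein_position 1-based residue number in the human sequence.
#' @return 1-based column index.
#' @export
site_to_column <- function(alignment, protein_position) {
  human <- strsplit(alignment$rows[[alignment$human_id]], "")[[1]]
  nongap <- cumsum(human != "-")
  hit <- which(human != "-" & nongap == protein_position)
  if (length(hit) == 0)
    stop("human sequence has only ", max(nongap), " residues; position ",
         protein_position, " does not exist")
  hit[1]
}

#' Amino-acid profile of an alignment column
#'
#' Counts amino acids over covered species only: gaps and `X` are excluded
#' from both counts and the coverage denominator, mirroring the convention
#' that prevalence percentages are quoted out of the species where the
#' position is covered.
#'
#' @param alignment A [species_alignment()].
#' @param column_index 1-based column.
#' @return Object of class `"column_profile"`: list with `column_index`,
#'   `counts` (named table), `coverage`, `frequencies` (counts/coverage;
#'   empty when coverage is 0) and `n_excluded` (gap or `X` species).
#' @export
column_profile <- function(alignment, column_index) {
  if (column_index < 1 || column_index > alignment$width)
    stop("column ", column_index, " outside alignment width ",
         alignment$width)
  chars <- .align_chars(alignment, column_index)
  covered <- chars %in% AMINO_ACIDS
  counts <- table(factor(chars[covered], levels = AMINO_ACIDS))
  counts <- counts[counts > 0]
  coverage <- sum(covered)
  structure(
    list(column_index = column_index,
         counts = counts,
         coverage = coverage,
         frequencies = if (coverage > 0) counts / coverage else counts,
         n_excluded = sum(!covered)),
    class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("column %d: coverage %d (%d gap/X excluded)\n",
              x$column_index, x$coverage, x$n_excluded))
  if (x$coverage > 0) {
    f <- sort(x$frequencies, decreasing = TRUE)
    cat(paste(sprintf("%s %.1f%%", names(f), 100 * as.numeric(f)),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Find species carrying a human pathogenic amino acid (a CPD)
#'
#' Maps the mutation's protein position into the alignment via the human
#' reference row and returns the non-human species whose state at that
#' column equals the pathogenic (alternate) amino acid. Species with a gap
#' or `X` at the column are never reported; their count is returned. When
#' the human row does not carry the expected reference amino acid at the
#' mapped column, a warning is raised and the hit is flagged as a possible
#' mapping or catalogue inconsistency.
#'
#' @param alignment A [species_alignment()].
#' @param mutation A single-row slice of a catalogue (needs `protein_position`,
#'   `ref_aa`, `alt_aa`; other columns are carried through), or a list with
#'   those fields.
#' @return Object of class `"cpd_hit"`: list with `mutation`, `column`,
#'   `species_with_cpd`, `clade_breakdown` (named counts; `NA` clade for
#'   species missing from the taxon table), `n_excluded` (gap/`X` species),
#'   `human_state`, `flagged` and `n_events` (NA until filled by
#'   [count_events_to()] via the pipeline).
#' @export
find_cpd_species <- function(alignment, mutation) {
  mut <- as.list(mutation)
  column <- site_to_column(alignment, mut$protein_position)
  chars <- .align_chars(alignment, column)
  human_state <- chars[[alignment$human_id]]
  flagged <- !identical(human_state, mut$ref_aa)
  if (flagged)
    warning("human row carries '", human_state, "' at mapped column ",
            column, " but catalogue reference is '", mut$ref_aa,
            "' - record flagged")
  others <- chars[names(chars) != alignment$human_id]
  covered <- others %in% AMINO_ACIDS
  hits <- names(others)[covered & others == mut$alt_aa]
  clades <- if (!is.null(alignment$taxon)) {
    cl <- alignment$taxon[hits]
    cl[is.na(cl)] <- "unknown"
    table(cl)
  } else NULL
  structure(
    list(mutation = mut, column = column,
         species_with_cpd = hits,
         clade_breakdown = clades,
         n_excluded = sum(!covered),
         human_state = human_state,
         flagged = flagged,
         n_events = NA_integer_),
    class = "cpd_hit")
}

#' @export
print.cpd_hit <- function(x, ...) {
  m <- x$mutation
  cat(sprintf("CPD scan %s %s%d%s: %d species carry the pathogenic state%s\n",
              m$gene %||% "", m$ref_aa, m$protein_position, m$alt_aa,
              length(x$species_with_cpd),
              if (x$flagged) "  [FLAGGED: human-row mismatch]" else ""))
  if (!is.null(x$clade_breakdown) && length(x$clade_breakdown) > 0)
    cat("  clades:",
        paste(sprintf("%s (%d)", names(x$clade_breakdown),
                      as.integer(x$clade_breakdown)), collapse = ", "), "\n")
  if (!is.na(x$n_events)) cat("  substitution events on tree:", x$n_events, "\n")
  invisible(x)
}
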