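## Alignment container and FASTA/taxonomy IO.

#' Construct and validate a species alignment
#'
#' A `species_alignment` is a per-gene amino-acid multiple sequence alignment
#' keyed by species id, with a designated human reference row and optional
#' clade labels per species. Rows must be equal length over the alphabet of
#' the 20 amino acids plus `-` (gap) and `X` (unknown; excluded from
#' profiles).
#'
#' @param rows Named character vector of aligned sequences (names are
#'   species ids).
#' @param human_id Species id of the human reference row.
#' @param taxon Optional named character vector mapping species id -> clade.
#' @param gene_name Optional gene label.
#' @return An object of class `"species_alignment"`.
#' @export
species_alignment <- function(rows, human_id, taxon = NULL,
                              gene_name = NA_character_) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must carry unique species ids as names")
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1) {
    off <- names(rows)[widths != stats::median(widths)]
    stop("ragged alignment: record(s) ", paste(off, collapse = ", "),
         " differ in length from the rest")
  }
  bad <- vapply(rows, function(s)
    grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "X-]"), s),
    TRUE)
  if (any(bad))
    stop("illegal characters in record(s): ",
         paste(names(rows)[bad], collapse = ", "))
  if (!human_id %in% names(rows))
    stop("human reference id '", human_id, "' not found among records")
  if (!is.null(taxon)) {
    taxon <- taxon[names(rows)[names(rows) %in% names(taxon)]]
  }
  structure(
    list(gene_name = gene_name, rows = rows, human_id = human_id,
         taxon = taxon, width = unname(widths[1])),
    class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species_alignment%s: %d species x %d columns (human: %s)\n",
              if (is.na(x$gene_name)) "" else paste0(" [", x$gene_name, "]"),
              length(x$rows), x$width, x$human_id))
  invisible(x)
}

#' Read an aligned amino-acid FASTA file
#'
#' @param path FASTA file of aligned protein sequences (gap `-`).
#' @param human_id Record id of the human reference sequence.
#' @param taxon_table Optional data frame with columns `species_id`, `clade`
#'   (as returned by [read_taxonomy()]), or a named character vector.
#' @param gene_name Optional gene label attached to the alignment.
#' @return A [species_alignment()].
#' @export
read_fasta_alignment <- function(path, human_id, taxon_table = NULL,
                                 gene_name = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(aa), names(aa))
  # FASTA headers may carry descriptions; keep the first token as the id
  names(rows) <- sub("\\s.*$", "", names(rows))
  taxon <- NULL
  if (!is.null(taxon_table)) {
    taxon <- if (is.data.frame(taxon_table))
      stats::setNames(as.character(taxon_table$clade),
                      taxon_table$species_id)
    else taxon_table
  }
  species_alignment(rows, human_id = human_id, taxon = taxon,
                    gene_name = gene_name)
}

#' Write a species alignment as FASTA
#'
#' @param alignment A [species_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  x <- Biostrings::BStringSet(alignment$rows)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a species -> clade taxonomy table
#'
#' Expects a TSV with columns `species_id` and `clade`.
#'
#' @param path TSV file.
#' @return Data frame with columns `species_id`, `clade`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "clade") %in% names(tab)))
    stop("taxonomy table must have columns species_id, clade")
  tab[, c("species_id", "clade")]
}

#' @rdname read_taxonomy
#' @param taxonomy Data frame as returned by `read_taxonomy`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
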