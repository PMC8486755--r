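## Cross-referencing CPD species against contact-site alignment states:
## nomination of potential masking (permissive) substitutions.

#' Classify contact-site states across CPD-carrying species
#'
#' For each residue in structural contact with a CPD site, inspects the
#' amino acids of the CPD-carrying species at that site and classifies the
#' contact as `"all"` (every covered CPD species carries a non-human amino
#' acid — a potential masking site), `"some"`, or `"none"` (all covered CPD
#' species agree with the human residue). CPD species with a gap or `X` at
#' the contact site are excluded from the determination and counted
#' separately; a contact with no covered CPD species is `"unassessable"`.
#'
#' @param alignment A [species_alignment()].
#' @param cpd_hit A [find_cpd_species()] result.
#' @param contact_pairs A [contact_sites()] result (or data frame with
#'   `site_j`, `distance`), in the same residue numbering as the catalogue;
#'   apply any structure-numbering offset before calling.
#' @param restrict_species Optional character vector: consider only these
#'   CPD species (used to honour the rule that masking is searched in all
#'   species for definitely pathogenic variants but only in primates for
#'   probably pathogenic and LHON variants).
#' @return List of class `"masking_candidates"`; one element per contact
#'   site with fields `cpd_site`, `contact_site`, `distance`, `column`,
#'   `human_aa`, `states_in_cpd_species`, `n_missing`, `category`,
#'   `prevalence` (dataset-wide frequency of each observed state) and
#'   `unmappable`.
#' @export
classify_contact_states <- function(alignment, cpd_hit, contact_pairs,
                                    restrict_species = NULL) {
  species <- cpd_hit$species_with_cpd
  if (!is.null(restrict_species))
    species <- intersect(species, restrict_species)
  if (length(species) == 0)
    stop("no CPD species to classify (empty hit after restriction)")
  cpd_site <- cpd_hit$mutation$protein_position
  out <- lapply(seq_len(nrow(contact_pairs)), function(i) {
    site_j <- contact_pairs$site_j[i]
    cand <- list(cpd_site = cpd_site, contact_site = site_j,
                 distance = contact_pairs$distance[i],
                 column = NA_integer_, human_aa = NA_character_,
                 states_in_cpd_species = NULL, n_missing = NA_integer_,
                 category = NA_character_, prevalence = NULL,
                 unmappable = FALSE)
    column <- tryCatch(site_to_column(alignment, site_j), error = function(e) NULL)
    if (is.null(column)) {
      cand$unmappable <- TRUE
      cand$category <- "unmappable"
      return(cand)
    }
    chars <- .align_chars(alignment, column)
    human_aa <- chars[[alignment$human_id]]
    st <- chars[species]
    covered <- st %in% AMINO_ACIDS
    cand$column <- column
    cand$human_aa <- human_aa
    cand$states_in_cpd_species <- st[covered]
    cand$n_missing <- sum(!covered)
    cand$category <- if (sum(covered) == 0) "unassessable"
      else if (all(st[covered] != human_aa)) "all"
      else if (all(st[covered] == human_aa)) "none"
      else "some"
    prof <- column_profile(alignment, column)
    obs <- unique(st[covered])
    cand$prevalence <- stats::setNames(
      as.numeric(prof$frequencies[obs]), obs)
    cand
  })
  structure(out, class = "masking_candidates", cpd_site = cpd_site)
}

#' Per-CPD masking summary
#'
#' Tallies [classify_contact_states()] candidates the way the headline
#' masking table is laid out: number of putatively interacting sites, how
#' many carry a non-human amino acid in at least one CPD species
#' (`n_some`, which includes the `"all"` sites), and how many in all CPD
#' species (`n_all`). `n_all <= n_some <= n_contacts` always.
#'
#' @param candidates A `"masking_candidates"` list.
#' @return One-row data frame with columns `cpd_site`, `n_contacts`,
#'   `n_some`, `n_all`, `sites_some`, `sites_all` (comma-separated contact
#'   positions), `n_unassessable`.
#' @export
masking_report <- function(candidates) {
  cat_of <- vapply(candidates, `[[`, "", "category")
  site_of <- vapply(candidates, `[[`, 0, "contact_site")
  some <- cat_of %in% c("some", "all")
  all_ <- cat_of == "all"
  data.frame(
    cpd_site = attr(candidates, "cpd_site") %||% NA_integer_,
    n_contacts = length(candidates),
    n_some = sum(some),
    n_all = sum(all_),
    sites_some = paste(site_of[some], collapse = ","),
    sites_all = paste(site_of[all_], collapse = ","),
    n_unassessable = sum(cat_of %in% c("unassessable", "unmappable")),
    stringsAsFactors = FALSE)
}

#' Joint amino-acid counts of species at two sites
#'
#' Counts species by their joint state at two protein positions (mapped to
#' alignment columns through the human row). Species with a gap or `X` at
#' either site are excluded. When `focus_states` is given, states outside
#' it are bucketed as `"other"`.
#'
#' @param alignment A [species_alignment()].
#' @param site_a,site_b Protein positions (human numbering).
#' @param focus_states Optional character vector of states of interest.
#' @return A contingency table (site_a states x site_b states); attribute
#'   `n_excluded` counts species dropped for missing data.
#' @export
cooccurrence_table <- function(alignment, site_a, site_b,
                               focus_states = NULL) {
  col_a <- site_to_column(alignment, site_a)
  col_b <- site_to_column(alignment, site_b)
  a <- .align_chars(alignment, col_a)
  b <- .align_chars(alignment, col_b)
  keep <- a %in% AMINO_ACIDS & b %in% AMINO_ACIDS
  a <- a[keep]; b <- b[keep]
  if (!is.null(focus_states)) {
    a[!a %in% focus_states] <- "other"
    b[!b %in% focus_states] <- "other"
  }
  structure(table(a, b, dnn = c(paste0("site_", site_a),
                                paste0("site_", site_b))),
            n_excluded = sum(!keep))
}
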