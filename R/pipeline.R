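## End-to-end orchestration: catalogue -> CPD scan -> parsimony events ->
## contacts -> masking, with deterministic report files and an exclusion log.

#' Run the full CPD analysis pipeline
#'
#' Drives every stage over a catalogue of variants: maps each variant into
#' its gene alignment, profiles the column, finds CPD-carrying species,
#' counts independent substitutions to the pathogenic amino acid by Fitch
#' parsimony, computes structural contacts of the variant site when a
#' structure is supplied, and classifies contact-site states across the CPD
#' species to nominate masking candidates. All report files are written
#' with fixed ordering, so a rerun on identical inputs is byte-identical.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{alignments}{named character vector, gene -> FASTA path (or a
#'       named list of `species_alignment` objects).}
#'     \item{tree}{Newick path or `phylo` object.}
#'     \item{catalogue}{catalogue TSV path or `mutation_catalogue`.}
#'     \item{taxonomy}{taxonomy TSV path or data frame (optional).}
#'     \item{structures}{named character vector, gene -> PDB path, or named
#'       list of `structure_model`s (optional).}
#'     \item{human_id}{human species id (required).}
#'     \item{chain_id}{chain to read from PDB files (default "A").}
#'     \item{threshold}{contact threshold in Angstrom (default 8).}
#'     \item{numbering_offset}{named integers per gene added to catalogue
#'       residue numbers to obtain structure numbering (default 0).}
#'     \item{restrict_clades}{named list: status -> clade labels to which
#'       the masking search is restricted; statuses absent from the list
#'       are searched in all species. Default restricts `probably` and
#'       `LHON-class` to `"primates"`.}
#'     \item{outdir}{output directory for report files (optional; no files
#'       are written when missing).}
#'   }
#' @return Object of class `"cpd_run"`: list with `variants` (per-variant
#'   summary data frame), `masking` (per-CPD masking summary), `candidates`
#'   (per contact-site detail), `hits`, `exclusions` (log data frame) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_config(config)
  catalogue <- cfg$catalogue
  exclusions <- list()
  log_excl <- function(stage, context, species, reason) {
    if (length(species) == 0) return()
    exclusions[[length(exclusions) + 1]] <<- data.frame(
      stage = stage, context = context, species = species, reason = reason,
      stringsAsFactors = FALSE)
  }

  variant_rows <- list()
  masking_rows <- list()
  candidate_rows <- list()
  hits <- list()

  for (r in seq_len(nrow(catalogue))) {
    rec <- catalogue[r, ]
    ctx <- sprintf("%s:%s%d%s", rec$gene, rec$ref_aa, rec$protein_position,
                   rec$alt_aa)
    aln <- cfg$alignments[[rec$gene]]
    if (is.null(aln)) {
      warning("no alignment for gene ", rec$gene, "; record ", ctx,
              " skipped")
      next
    }
    hit <- find_cpd_species(aln, rec)
    prof <- column_profile(aln, hit$column)
    log_excl("cpd_scan", ctx,
             setdiff(names(aln$rows)[!.align_chars(aln, hit$column) %in%
                                     AMINO_ACIDS], aln$human_id),
             "missing_state_at_variant_column")

    n_events <- 0L
    if (length(hit$species_with_cpd) > 0) {
      tip_states <- vapply(aln$rows, substr, "", hit$column, hit$column)
      in_tree <- intersect(names(tip_states), cfg$tree$tip.label)
      log_excl("phylo_events", ctx, setdiff(names(tip_states), in_tree),
               "not_in_tree")
      sub_tree <- ape::keep.tip(cfg$tree, in_tree)
      pruned <- prune_missing_states(sub_tree, tip_states[in_tree])
      fit <- parsimony_states(pruned$tree, pruned$tip_states)
      n_events <- count_events_to(fit, rec$alt_aa)$n_events
    }
    hit$n_events <- n_events
    hits[[ctx]] <- hit

    coverage_flag <- prof$coverage < 0.5 * length(aln$rows)
    clades <- if (!is.null(hit$clade_breakdown))
      paste(sprintf("%s (%d)", names(hit$clade_breakdown),
                    as.integer(hit$clade_breakdown)), collapse = "; ")
      else ""
    variant_rows[[length(variant_rows) + 1]] <- data.frame(
      gene = rec$gene, nt_change = rec$nt_change, aa_change = rec$aa_change,
      disease = rec$disease, status = rec$status,
      n_species_with_cpd = length(hit$species_with_cpd),
      clades_with_cpd = clades, n_substitutions = n_events,
      coverage = prof$coverage, low_coverage_flag = coverage_flag,
      human_row_mismatch = hit$flagged, stringsAsFactors = FALSE)

    # masking stage
    model <- cfg$structures[[rec$gene]]
    if (!is.null(model) && length(hit$species_with_cpd) > 0) {
      offset <- cfg$numbering_offset[[rec$gene]] %||% 0L
      .structure_seq_check(model, aln, offset)
      struct_site <- rec$protein_position + offset
      contacts <- contact_sites(model, struct_site,
                                threshold = cfg$threshold)
      contacts$site_i <- contacts$site_i - offset
      contacts$site_j <- contacts$site_j - offset
      restrict <- cfg$restrict_clades[[rec$status]]
      restrict_species <- NULL
      if (!is.null(restrict) && !is.null(aln$taxon)) {
        restrict_species <- names(aln$taxon)[aln$taxon %in% restrict]
        log_excl("masking", ctx,
                 setdiff(hit$species_with_cpd, restrict_species),
                 "outside_clade_restriction")
      }
      scoped <- if (is.null(restrict_species)) hit$species_with_cpd
                else intersect(hit$species_with_cpd, restrict_species)
      if (length(scoped) > 0) {
        cands <- classify_contact_states(aln, hit, contacts,
                                         restrict_species = restrict_species)
        masking_rows[[length(masking_rows) + 1]] <-
          cbind(data.frame(gene = rec$gene, aa_change = rec$aa_change,
                           stringsAsFactors = FALSE),
                masking_report(cands))
        for (cand in cands) {
          candidate_rows[[length(candidate_rows) + 1]] <- data.frame(
            gene = rec$gene, aa_change = rec$aa_change,
            cpd_site = cand$cpd_site, contact_site = cand$contact_site,
            distance = round(cand$distance, 2),
            human_aa = cand$human_aa %||% NA_character_,
            category = cand$category,
            states = paste(sort(unique(cand$states_in_cpd_species)),
                           collapse = ","),
            n_missing = cand$n_missing, stringsAsFactors = FALSE)
          if (!is.na(cand$n_missing) && cand$n_missing > 0) {
            st <- .align_chars(aln, cand$column)[scoped]
            log_excl("masking", paste0(ctx, " contact ", cand$contact_site),
                     names(st)[!st %in% AMINO_ACIDS],
                     "missing_state_at_contact_column")
          }
        }
      }
    }
  }

  res <- list(
    variants = .bind_or_empty(variant_rows, c(
      "gene", "nt_change", "aa_change", "disease", "status",
      "n_species_with_cpd", "clades_with_cpd", "n_substitutions",
      "coverage", "low_coverage_flag", "human_row_mismatch")),
    masking = .bind_or_empty(masking_rows, c(
      "gene", "aa_change", "cpd_site", "n_contacts", "n_some", "n_all",
      "sites_some", "sites_all", "n_unassessable")),
    candidates = .bind_or_empty(candidate_rows, c(
      "gene", "aa_change", "cpd_site", "contact_site", "distance",
      "human_aa", "category", "states", "n_missing")),
    hits = hits,
    exclusions = unique(.bind_or_empty(exclusions,
                                       c("stage", "context", "species",
                                         "reason"))),
    files = character(0))
  class(res) <- "cpd_run"

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(cfg$outdir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    files <- c(
      variants = wr(res$variants, "variants.tsv"),
      masking = wr(res$masking, "masking_summary.tsv"),
      candidates = wr(res$candidates, "masking_candidates.tsv"),
      exclusions = wr(res$exclusions, "exclusions.tsv"))
    summary_path <- file.path(cfg$outdir, "summary.json")
    jsonlite::write_json(
      list(n_variants = nrow(res$variants),
           n_with_cpd = sum(res$variants$n_species_with_cpd > 0),
           n_masking_all = if (nrow(res$masking)) sum(res$masking$n_all)
                           else 0L,
           threshold = cfg$threshold),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$files <- c(files, summary = summary_path)
  }
  res
}

#' @export
print.cpd_run <- function(x, ...) {
  cat("CPD pipeline run\n")
  cat(sprintf("  variants scanned: %d\n", nrow(x$variants)))
  cat(sprintf("  with >=1 CPD species: %d\n",
              sum(x$variants$n_species_with_cpd > 0)))
  if (nrow(x$masking) > 0)
    cat(sprintf("  masking: %d contact sites, %d 'some', %d 'all'\n",
                sum(x$masking$n_contacts), sum(x$masking$n_some),
                sum(x$masking$n_all)))
  if (nrow(x$exclusions) > 0)
    cat(sprintf("  exclusions logged: %d\n", nrow(x$exclusions)))
  invisible(x)
}

.bind_or_empty <- function(rows, cols) {
  if (length(rows) == 0) {
    df <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    return(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.validate_config <- function(config) {
  cfg <- config
  if (is.null(cfg$human_id)) stop("config$human_id is required")
  cfg$threshold <- cfg$threshold %||% 8.0
  if (cfg$threshold <= 0) stop("config$threshold must be positive")
  cfg$chain_id <- cfg$chain_id %||% "A"
  cfg$restrict_clades <- cfg$restrict_clades %||%
    list(probably = "primates", `LHON-class` = "primates")
  cfg$numbering_offset <- cfg$numbering_offset %||% list()

  taxon <- NULL
  if (!is.null(cfg$taxonomy)) {
    tab <- if (is.character(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
           else cfg$taxonomy
    taxon <- stats::setNames(as.character(tab$clade), tab$species_id)
  }
  if (is.character(cfg$catalogue))
    cfg$catalogue <- read_catalogue(cfg$catalogue)
  if (is.character(cfg$tree)) cfg$tree <- read_newick(cfg$tree)

  load_aln <- function(x, gene) {
    if (inherits(x, "species_alignment")) {
      if (!is.null(taxon)) x$taxon <- taxon[names(x$rows)[names(x$rows) %in%
                                                          names(taxon)]]
      return(x)
    }
    read_fasta_alignment(x, human_id = cfg$human_id, taxon_table = taxon,
                         gene_name = gene)
  }
  if (is.null(cfg$alignments)) stop("config$alignments is required")
  cfg$alignments <- stats::setNames(
    lapply(names(cfg$alignments), function(g)
      load_aln(cfg$alignments[[g]], g)),
    names(cfg$alignments))

  if (!is.null(cfg$structures)) {
    cfg$structures <- stats::setNames(
      lapply(names(cfg$structures), function(g) {
        x <- cfg$structures[[g]]
        if (inherits(x, "structure_model")) x
        else read_structure(x, chain_id = cfg$chain_id)
      }),
      names(cfg$structures))
  } else cfg$structures <- list()
  cfg
}

# cross-check: structure residue identities must agree with the human
# alignment row (after offset); >5% mismatch over comparable residues fails
.structure_seq_check <- function(model, alignment, offset) {
  human <- gsub("-", "", alignment$rows[[alignment$human_id]])
  pos <- model$resno - offset
  ok <- pos >= 1 & pos <= nchar(human) & !is.na(model$aa)
  if (sum(ok) == 0) return(invisible(TRUE))
  human_aa <- substring(human, pos[ok], pos[ok])
  mism <- mean(human_aa != model$aa[ok] & human_aa != "X")
  if (mism > 0.05)
    stop(sprintf(
      "structure/alignment sequence mismatch: %.1f%% of %d residues differ; check numbering_offset",
      100 * mism, sum(ok)))
  invisible(TRUE)
}
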