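## Deterministic synthetic bundles: tree, evolved alignment with planted
## CPDs and masking alleles, taxonomy, toy structure, catalogue and ground
## truth. Every pipeline stage is testable against these with no download.

#' Simulate a random rooted binary tree (Yule growth)
#'
#' Grows a tree by repeatedly splitting a uniformly chosen tip, which is the
#' Yule (pure-birth) topology process. All branch lengths are 1. Tips are
#' named `t0001`, `t0002`, ... in order of creation; by convention the first
#' tip doubles as the designated human reference in bundles.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; the same seed always yields the identical tree.
#' @return A rooted `ape::phylo`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  withr::with_seed(seed, {
    tree <- list(1, 2)
    leaves <- function(node) if (!is.list(node)) node
      else unlist(lapply(node, leaves))
    split_leaf <- function(node, target, newid) {
      if (!is.list(node))
        return(if (node == target) list(node, newid) else node)
      lapply(node, split_leaf, target = target, newid = newid)
    }
    if (n_tips > 2) for (k in 3:n_tips) {
      lv <- leaves(tree)
      tree <- split_leaf(tree, lv[sample.int(length(lv), 1)], k)
    }
    deparse_nwk <- function(node) {
      if (!is.list(node)) return(sprintf("t%04d:1", node))
      paste0("(", paste(vapply(node, deparse_nwk, ""), collapse = ","),
             "):1")
    }
    ape::read.tree(text = paste0(deparse_nwk(tree), ";"))
  })
}

.sample_other <- function(current, alphabet) {
  sample(setdiff(alphabet, current), 1)
}

#' Evolve an amino-acid alignment along a tree with planted signals
#'
#' Sequences evolve from a random root by per-branch, per-site Poisson
#' substitution events with uniform replacement. Afterwards, planted CPD
#' sites are overwritten: every tip gets the wild-type amino acid and each
#' designated clade gets the pathogenic one, so the parsimony count of
#' substitutions to the pathogenic state equals the number of clades (a
#' collision check enforces that no homoplasy remains at planted sites).
#' Planted masking sites are overwritten analogously across the CPD species.
#' True per-node states at planted sites are recorded in the ground truth.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param width Alignment width (sites).
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @param human_id Tip label of the human reference row.
#' @param planted_cpds List of entries `list(site, pathogenic_aa,
#'   wildtype_aa, clades)` where `clades` is a list of disjoint tip-label
#'   vectors (the human tip may not appear in any clade).
#' @param planted_maskers List of entries `list(cpd_site, partner_site,
#'   masking_aa, human_aa, scope)` with scope one of `"all"`, `"some"`,
#'   `"none"`; `cpd_site` must match a planted CPD.
#' @param taxon Optional named clade vector passed to the alignment.
#' @return List with `alignment` (a [species_alignment()]), `ancestral`
#'   (node x site state matrix, rownames as in [parsimony_states()]) and
#'   `truth` (planted CPD species sets, event counts and masking categories).
#' @export
evolve_alignment <- function(tree, width = 100, rate = 0.05, seed = 1,
                             human_id = "t0001",
                             planted_cpds = list(),
                             planted_maskers = list(),
                             taxon = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1
  planted_sites <- vapply(planted_cpds, `[[`, 0, "site")
  partner_sites <- vapply(planted_maskers, `[[`, 0, "partner_site")
  if (anyDuplicated(c(planted_sites, partner_sites)))
    stop("planted CPD and masking sites must be distinct")
  if (any(c(planted_sites, partner_sites) > width))
    stop("planted site beyond alignment width")

  states <- withr::with_seed(seed, {
    m <- matrix(NA_character_, nrow = ntip + nnode, ncol = width)
    m[root, ] <- sample(AMINO_ACIDS, width, replace = TRUE)
    post <- ape::reorder.phylo(tree, "postorder")
    edge <- post$edge
    bl_post <- post$edge.length
    if (is.null(bl_post)) bl_post <- rep(1, nrow(edge))
    for (i in rev(seq_len(nrow(edge)))) {  # parents before children
      parent <- edge[i, 1]; child <- edge[i, 2]
      seqc <- m[parent, ]
      hits <- which(stats::rpois(width, rate * bl_post[i]) > 0)
      for (h in hits) seqc[h] <- .sample_other(seqc[h], AMINO_ACIDS)
      m[child, ] <- seqc
    }
    m
  })

  node_labels <- c(tree$tip.label, paste0("node", root:(ntip + nnode)))
  rownames(states) <- node_labels

  # plant CPDs
  truth_cpds <- list()
  for (cpd in planted_cpds) {
    clades <- cpd$clades
    tips <- unlist(clades)
    if (anyDuplicated(tips) || human_id %in% tips)
      stop("planted clades must be disjoint and exclude the human tip")
    if (!all(tips %in% tree$tip.label))
      stop("planted clade tips not in tree: ",
           paste(setdiff(tips, tree$tip.label), collapse = ", "))
    site <- cpd$site
    states[seq_len(ntip), site] <- cpd$wildtype_aa
    states[(ntip + 1):(ntip + nnode), site] <- cpd$wildtype_aa
    for (clade in clades) {
      idx <- match(clade, tree$tip.label)
      states[idx, site] <- cpd$pathogenic_aa
      if (length(idx) > 1) {
        mrca <- ape::getMRCA(tree, clade)
        desc <- .descendants(tree, mrca)
        internal <- desc[desc > ntip]
        states[c(mrca, internal), site] <- cpd$pathogenic_aa
      }
    }
    truth_cpds[[as.character(site)]] <- list(
      site = site, pathogenic_aa = cpd$pathogenic_aa,
      wildtype_aa = cpd$wildtype_aa,
      species = sort(as.character(tips)), n_events = length(clades))
  }

  # plant masking alleles
  truth_maskers <- list()
  for (mk in planted_maskers) {
    key <- as.character(mk$cpd_site)
    if (!key %in% names(truth_cpds))
      stop("masker refers to unplanted CPD site ", mk$cpd_site)
    cpd_species <- truth_cpds[[key]]$species
    site <- mk$partner_site
    states[seq_len(ntip), site] <- mk$human_aa
    carriers <- switch(mk$scope,
      all = cpd_species,
      some = {
        if (length(cpd_species) < 2)
          stop("scope 'some' needs at least 2 CPD species")
        cpd_species[-1]
      },
      none = character(0),
      stop("unknown masker scope: ", mk$scope))
    states[match(carriers, tree$tip.label), site] <- mk$masking_aa
    truth_maskers[[length(truth_maskers) + 1]] <- list(
      cpd_site = mk$cpd_site, partner_site = site,
      masking_aa = mk$masking_aa, human_aa = mk$human_aa,
      scope = mk$scope, expected_category = mk$scope)
  }

  # collision check: at planted CPD sites the pathogenic state must occur in
  # exactly the planted species, and the planted clades must be independent
  # on the tree (parsimony must count exactly one event per clade; adjacent
  # or sister clades would merge into fewer events)
  for (tc in truth_cpds) {
    carriers <- tree$tip.label[states[seq_len(ntip), tc$site] ==
                               tc$pathogenic_aa]
    if (!setequal(carriers, tc$species))
      stop("homoplasy collision at planted site ", tc$site)
    if (tc$n_events > 0) {
      tip_states <- stats::setNames(states[seq_len(ntip), tc$site],
                                    tree$tip.label)
      fit <- parsimony_states(tree, tip_states)
      got <- count_events_to(fit, tc$pathogenic_aa)$n_events
      if (got != tc$n_events)
        stop("planted clades at site ", tc$site, " are not independent: ",
             "parsimony counts ", got, " events, expected ", tc$n_events)
    }
  }

  rows <- apply(states[seq_len(ntip), , drop = FALSE], 1, paste, collapse = "")
  aln <- species_alignment(rows, human_id = human_id, taxon = taxon)
  list(alignment = aln, ancestral = states,
       truth = list(cpds = truth_cpds, maskers = truth_maskers))
}

.descendants <- function(tree, node) {
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[1]; stack <- stack[-1]
    kids <- edge[edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}

#' Build a toy structure with designated contact distances
#'
#' Places residues far apart along a line (15 Angstrom spacing, so nothing
#' is in contact by default) and then moves the second member of each
#' designated pair to sit at exactly the target distance from the first.
#' Glycines receive a C-alpha representative atom, all other residues a
#' C-beta. The finished geometry is verified: every designated pair must
#' measure its target, and no undesignated pair may fall under
#' `guard_threshold`; violations are an error naming the pair.
#'
#' @param sequence Character string or vector of 1-letter residues; residue
#'   numbers run 1..n.
#' @param pairs Optional data frame with columns `i`, `j`, `dist`: residue
#'   `j` is repositioned at `dist` Angstrom from residue `i`. A residue may
#'   be moved only once.
#' @param guard_threshold Undesignated pairs must stay at or above this
#'   distance (default 8.0, the contact threshold).
#' @return A `structure_model` (see [read_structure()]), chain `"A"`.
#' @export
toy_structure <- function(sequence, pairs = NULL, guard_threshold = 8.0) {
  seq1 <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  if (!all(seq1 %in% AMINO_ACIDS))
    stop("sequence must use 1-letter amino-acid codes")
  n <- length(seq1)
  xyz <- cbind(x = 15 * seq_len(n), y = 0, z = 0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (anyDuplicated(pairs$j))
      stop("residue ", pairs$j[duplicated(pairs$j)][1],
           " is moved by more than one constraint; infeasible")
    if (any(pairs$dist <= 0)) stop("target distances must be positive")
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]; d <- pairs$dist[k]
      if (i > n || j > n || i == j) stop("bad pair (", i, ",", j, ")")
      theta <- 2 * pi * (k - 1) / nrow(pairs)
      xyz[j, ] <- xyz[i, ] + d * c(0, cos(theta), sin(theta))
    }
  }
  model <- data.frame(
    resno = seq_len(n),
    resname = unname(AA1_TO_3[seq1]),
    aa = seq1,
    atom = ifelse(seq1 == "G", "CA", "CB"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  # feasibility audit
  dm <- as.matrix(stats::dist(xyz))
  planted <- matrix(FALSE, n, n)
  if (!is.null(pairs) && nrow(pairs) > 0)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (abs(dm[i, j] - pairs$dist[k]) > 0.01)
        stop("constraint (", i, ",", j, ") not met; infeasible set")
      planted[i, j] <- planted[j, i] <- TRUE
    }
  # repositioned partners of one anchor are inevitably close to each other;
  # the guarantee defended here is that contacts of *unmoved* residues
  # (the anchors queried by tests and the pipeline) are exactly the planted
  # ones, so moved-moved proximity is allowed
  moved <- if (is.null(pairs)) integer(0) else pairs$j
  both_moved <- matrix(FALSE, n, n)
  if (length(moved) > 1) both_moved[moved, moved] <- TRUE
  close_unplanned <- which(dm < guard_threshold & !planted & !both_moved &
                           upper.tri(dm), arr.ind = TRUE)
  if (nrow(close_unplanned) > 0)
    stop("constraint set infeasible: undesignated pair (",
         close_unplanned[1, 1], ",", close_unplanned[1, 2],
         ") falls at ", round(dm[close_unplanned[1, , drop = FALSE]], 2),
         " Angstrom")
  structure(model, class = c("structure_model", "data.frame"),
            chain_id = "A", n_omitted = 0L, omitted_resno = integer(0))
}

#' Generate a complete synthetic study bundle
#'
#' Writes a self-consistent bundle to `dir`: a 64-tip tree (by default), an
#' ND1-like amino-acid alignment with planted CPDs and masking alleles, a
#' taxonomy table, a toy structure realising the planted contacts, a
#' mutation catalogue whose rCRS coordinates map to the planted sites, and
#' a `truth.json` ground-truth manifest. Fully deterministic per seed.
#'
#' Default study conditions: 64 tips, 140 alignment columns, substitution
#' rate 0.05 per site per branch; one CPD with a single 4-species clade
#' (site 59, E>K) carrying one "all", one "some" and one "none" masking
#' partner, one CPD with three independent origins (site 131, G>S, clades
#' of 5, 2 and 1 species) with one "all" partner, and one catalogued
#' variant absent from all species (site 20).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_tips Number of tips.
#' @param width Alignment width.
#' @param rate Substitution rate per site per unit branch length.
#' @return Invisibly, a list with `paths` (named file paths), `truth`, and
#'   the in-memory `alignment`, `tree`, `structure`.
#' @export
simulate_bundle <- function(dir, seed = 1, n_tips = 64, width = 140,
                            rate = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, seed = seed)
  human_id <- "t0001"
  tips <- tree$tip.label

  # clades for planting: take cherries/small clades that exclude the human
  # tip, chosen deterministically from the tree structure
  clade_pool <- .disjoint_clades(tree, sizes = c(4, 5, 2, 1),
                                 exclude = human_id)
  cpds <- list(
    list(site = 59, pathogenic_aa = "K", wildtype_aa = "E",
         clades = clade_pool[1]),
    list(site = 131, pathogenic_aa = "S", wildtype_aa = "G",
         clades = clade_pool[2:4]),
    # catalogued variant never observed as a CPD: wild type planted in every
    # species, no clade carries the pathogenic state
    list(site = 20, pathogenic_aa = "P", wildtype_aa = "A",
         clades = list()))
  maskers <- list(
    list(cpd_site = 59, partner_site = 61, masking_aa = "V",
         human_aa = "I", scope = "all"),
    list(cpd_site = 59, partner_site = 60, masking_aa = "R",
         human_aa = "L", scope = "some"),
    list(cpd_site = 59, partner_site = 66, masking_aa = "W",
         human_aa = "F", scope = "none"),
    list(cpd_site = 131, partner_site = 135, masking_aa = "C",
         human_aa = "A", scope = "all"))

  clade_names <- c("mites", "flatworms", "arachnids", "beetles")
  taxon <- stats::setNames(rep("other", length(tips)), tips)
  for (i in seq_along(clade_pool))
    taxon[clade_pool[[i]]] <- clade_names[i]
  taxon[human_id] <- "primates"

  ev <- evolve_alignment(tree, width = width, rate = rate, seed = seed,
                         human_id = human_id, planted_cpds = cpds,
                         planted_maskers = maskers, taxon = taxon)
  ev$alignment$gene_name <- "ND1"

  human_seq <- strsplit(ev$alignment$rows[[human_id]], "")[[1]]
  contact_pairs <- data.frame(
    i = c(59, 59, 59, 131),
    j = c(60, 61, 66, 135),
    dist = c(5.0, 6.5, 7.4, 4.8))
  model <- toy_structure(human_seq, contact_pairs)

  catalogue <- data.frame(
    gene = "ND1",
    nt_change = sprintf("m.%dG>A", 3307 + 3 * (c(59, 131, 20) - 1)),
    aa_change = c("E59K", "G131S", "A20P"),
    disease = c("MELAS", "MELAS", "LS"),
    status = c("definitely", "definitely", "definitely"),
    complex_disease_only = FALSE,
    ev_cybrid = TRUE, ev_single_fibre = TRUE, ev_biochemical_defect = TRUE,
    ev_independent_reports = TRUE, ev_heteroplasmy = TRUE,
    stringsAsFactors = FALSE)

  paths <- list(
    alignment = file.path(dir, "alignment_ND1.fasta"),
    tree = file.path(dir, "tree.nwk"),
    structure = file.path(dir, "structure_ND1.pdb"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    catalogue = file.path(dir, "catalogue.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta_alignment(ev$alignment, paths$alignment)
  write_newick(tree, paths$tree)
  write_structure(model, paths$structure)
  write_taxonomy(data.frame(species_id = names(taxon), clade = unname(taxon),
                            stringsAsFactors = FALSE), paths$taxonomy)
  utils::write.table(catalogue, paths$catalogue, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    seed = seed, n_tips = n_tips,
    cpds = unname(ev$truth$cpds),
    maskers = ev$truth$maskers,
    contacts = contact_pairs,
    absent_variant_site = 20)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, alignment = ev$alignment,
                 tree = tree, structure = model, taxon = taxon,
                 ancestral = ev$ancestral))
}

# pick disjoint clades of (approximately) the requested sizes, never
# containing `exclude`; deterministic given the tree. When no free clade of
# the exact size exists the size requirement is relaxed outward (s+1, s-1,
# s+2, ...). Each accepted clade must have a "witness" tip in its stem's
# sibling subtree that is not claimed by any other clade; the witness is
# reserved so later clades cannot absorb it. This keeps planted clades
# separated by wild-type lineages, so parsimony sees one event per clade
# (the generator's collision check verifies this independently).
.disjoint_clades <- function(tree, sizes, exclude) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  taken <- character(0)    # tips inside chosen clades
  reserved <- character(0) # witness tips pinned to the wild type
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    desc <- .descendants(tree, node)
    tree$tip.label[desc[desc <= ntip]]
  }
  witness_for <- function(node_or_tip) {
    parent <- edge[edge[, 2] == node_or_tip, 1]
    if (length(parent) == 0) return(NULL)  # root cannot be a clade here
    sibs <- setdiff(edge[edge[, 1] == parent, 2], node_or_tip)
    sib_tips <- unlist(lapply(sibs, tips_under))
    cand <- setdiff(sib_tips, c(taken, reserved))
    if (length(cand) == 0) NULL else cand[1]
  }
  clade_of_size <- function(s) {
    if (s == 1) {
      for (tip in rev(seq_len(ntip))) {
        lab <- tree$tip.label[tip]
        if (lab %in% c(taken, reserved, exclude)) next
        w <- witness_for(tip)
        if (!is.null(w)) return(list(tips = lab, witness = w))
      }
      return(NULL)
    }
    for (node in (ntip + 2):(ntip + tree$Nnode)) {
      dt <- tips_under(node)
      if (length(dt) != s || exclude %in% dt ||
          any(dt %in% c(taken, reserved))) next
      w <- witness_for(node)
      if (!is.null(w)) return(list(tips = dt, witness = w))
    }
    NULL
  }
  out <- list()
  for (s in sizes) {
    found <- NULL
    for (delta in c(0, 1, -1, 2, -2, 3, -3)) {
      sz <- s + delta
      if (sz < 1) next
      found <- clade_of_size(sz)
      if (!is.null(found)) break
    }
    if (is.null(found))
      stop("tree has no free clade near size ", s, "; use a larger tree")
    out <- c(out, list(found$tips))
    taken <- c(taken, found$tips)
    reserved <- c(reserved, found$witness)
  }
  out
}
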