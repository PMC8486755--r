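# Shared fixture builders. Everything is generated in code; nothing binary.

make_alignment <- function(rows, human = "human", taxon = NULL,
                           gene = "ND1") {
  species_alignment(rows, human_id = human, taxon = taxon, gene_name = gene)
}

# minimal PDB text: one line per supplied atom
pdb_text <- function(atoms) {
  # atoms: data.frame(serial, name, alt, resname, resno, x, y, z, occ)
  lines <- sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    atoms$serial, atoms$name, atoms$alt, atoms$resname, "A", atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occ, 0.00)
  c(lines, "END")
}

write_pdb_fixture <- function(atoms, path = tempfile(fileext = ".pdb")) {
  writeLines(pdb_text(atoms), path)
  path
}

atom_row <- function(serial, name, resname, resno, x, y, z,
                     alt = " ", occ = 1.0) {
  data.frame(serial = serial, name = name, alt = alt, resname = resname,
             resno = resno, x = x, y = y, z = z, occ = occ,
             stringsAsFactors = FALSE)
}

# exhaustive minimum-change count over all internal labelings (the
# independent oracle for Fitch parsimony)
exhaustive_parsimony <- function(tree, tip_states, alphabet) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  tip_idx <- match(tip_states[tree$tip.label], alphabet)
  grids <- rep(list(seq_along(alphabet)), nnode)
  labelings <- as.matrix(expand.grid(grids))
  full <- cbind(matrix(tip_idx, nrow = nrow(labelings), ncol = ntip,
                       byrow = TRUE), labelings)
  changes <- rep(0L, nrow(labelings))
  for (e in seq_len(nrow(edge)))
    changes <- changes + (full[, edge[e, 1]] != full[, edge[e, 2]])
  min(changes)
}

# independent NG86 site/difference oracle: per-codon synonymous fraction by
# direct enumeration of the 9 single-nucleotide neighbours
oracle_syn_sites <- function(codon, code) {
  nt <- c("T", "C", "A", "G")
  s <- 0
  for (pos in 1:3) for (b in nt) {
    if (b == substr(codon, pos, pos)) next
    neigh <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
    if (code[[neigh]] != "*" && code[[neigh]] == code[[codon]])
      s <- s + 1 / 3
  }
  s
}

random_codon <- function(code) {
  repeat {
    c3 <- paste(sample(c("T", "C", "A", "G"), 3, replace = TRUE),
                collapse = "")
    if (code[[c3]] != "*") return(c3)
  }
}
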