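## PDB coordinate reading and the representative-atom rule.

#' Read one chain of a PDB file as a representative-atom model
#'
#' Parses the coordinate section of a PDB file (ATOM records only; HETATM is
#' ignored) and reduces each residue to a single representative atom: the
#' C-beta atom, or C-alpha for glycine. Non-glycine residues lacking a
#' C-beta fall back to C-alpha with a warning; residues with neither atom
#' are omitted and counted. Alternate locations are resolved to the
#' highest-occupancy record (ties: first encountered). Insertion codes are
#' rejected.
#'
#' @param path PDB-format file.
#' @param chain_id Chain identifier to extract.
#' @return An object of class `"structure_model"`: a data frame with columns
#'   `resno`, `resname` (3-letter), `aa` (1-letter, `NA` for non-standard
#'   residues), `atom` (`"CB"` or `"CA"`), `x`, `y`, `z`; attributes
#'   `chain_id`, `n_omitted` and `omitted_resno`.
#' @export
read_structure <- function(path, chain_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  # rm.alt = FALSE: keep all alternate locations so the highest-occupancy
  # policy below sees every record
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  chains <- sort(unique(at$chain))
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain_id, , drop = FALSE]
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins))
    stop("insertion codes present at residue(s) ",
         paste(unique(at$resno[ins]), collapse = ", "),
         "; renumber the chain before use")
  resnos <- unique(at$resno)
  pick <- function(rows, name) {
    cand <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    if (nrow(cand) > 1) {
      occ <- ifelse(is.na(cand$o), 1, cand$o)
      cand <- cand[which.max(occ), , drop = FALSE]  # ties: first encountered
    }
    cand
  }
  out <- vector("list", length(resnos))
  omitted <- integer(0)
  fallback <- integer(0)
  for (i in seq_along(resnos)) {
    rows <- at[at$resno == resnos[i], , drop = FALSE]
    resname <- rows$resid[1]
    rep_atom <- if (identical(resname, "GLY")) pick(rows, "CA") else {
      cb <- pick(rows, "CB")
      if (is.null(cb)) {
        ca <- pick(rows, "CA")
        if (!is.null(ca)) fallback <- c(fallback, resnos[i])
        ca
      } else cb
    }
    if (is.null(rep_atom)) {
      omitted <- c(omitted, resnos[i])
      next
    }
    out[[i]] <- data.frame(
      resno = resnos[i], resname = resname,
      aa = if (resname %in% names(AA3)) unname(AA3[resname]) else NA_character_,
      atom = rep_atom$elety, x = rep_atom$x, y = rep_atom$y, z = rep_atom$z,
      stringsAsFactors = FALSE)
  }
  model <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(model) || nrow(model) == 0)
    stop("chain '", chain_id, "' has no residues with CA or CB atoms")
  if (any(diff(model$resno) <= 0))
    stop("residue numbers are not strictly increasing in chain ", chain_id)
  if (any(!is.finite(as.matrix(model[, c("x", "y", "z")]))))
    stop("non-finite coordinates in chain ", chain_id)
  if (length(fallback) > 0)
    warning("non-glycine residue(s) without C-beta, used C-alpha: ",
            paste(fallback, collapse = ", "))
  if (length(omitted) > 0)
    message(length(omitted), " residue(s) lacked both C-beta and C-alpha ",
            "and were omitted: ", paste(omitted, collapse = ", "))
  structure(model, class = c("structure_model", "data.frame"),
            chain_id = chain_id, n_omitted = length(omitted),
            omitted_resno = omitted)
}

#' Write a representative-atom model as PDB text
#'
#' Emits one ATOM record per residue (its representative atom). Used mainly
#' by the synthetic-data generator; the output is readable by
#' [read_structure()] and standard tools.
#'
#' @param model A `structure_model` (or data frame with columns `resno`,
#'   `resname`, `atom`, `x`, `y`, `z`).
#' @param path Output file.
#' @param chain_id Chain identifier (defaults to the model's).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, chain_id = NULL) {
  if (is.null(chain_id))
    chain_id <- attr(model, "chain_id") %||% "A"
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
    seq_len(nrow(model)), model$atom, model$resname, chain_id, model$resno,
    model$x, model$y, model$z, 1.00, 0.00, "C")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
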