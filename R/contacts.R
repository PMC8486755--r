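## Residue contacts from representative-atom coordinates.

.model_xyz <- function(model, site) {
  row <- which(model$resno == site)
  if (length(row) == 0) return(NULL)
  as.numeric(model[row[1], c("x", "y", "z")])
}

#' Distance between the representative atoms of two residues
#'
#' @param model A [read_structure()] model.
#' @param site_i,site_j Residue numbers.
#' @return Euclidean distance in Angstrom, or `NA` with a warning when
#'   either residue is unresolved in the model (an "unresolved" signal,
#'   distinct from any distance).
#' @export
pairwise_distance <- function(model, site_i, site_j) {
  a <- .model_xyz(model, site_i)
  b <- .model_xyz(model, site_j)
  if (is.null(a) || is.null(b)) {
    missing <- c(site_i, site_j)[c(is.null(a), is.null(b))]
    warning("residue(s) unresolved in model: ",
            paste(missing, collapse = ", "))
    return(NA_real_)
  }
  sqrt(sum((a - b)^2))
}

#' Residues in contact with a site
#'
#' Returns every same-chain residue whose representative atom (C-beta,
#' C-alpha for glycine) lies strictly closer than `threshold` Angstrom to
#' the site's representative atom. A residue at exactly the threshold is
#' not a contact. No minimum sequence separation is applied by default
#' (near-in-sequence neighbours count); set `min_separation` to filter.
#'
#' @param model A [read_structure()] model.
#' @param site Residue number (must be resolved in the model).
#' @param threshold Distance threshold in Angstrom (default 8.0).
#' @param min_separation Minimum `|i - j|` in primary sequence (default 0 =
#'   no filter).
#' @return Data frame of class `"contact_pairs"` with columns `site_i`,
#'   `site_j`, `distance`, `seq_separation`, sorted by `site_j`; residues
#'   absent from the model are listed in attribute `unresolved` (they are
#'   unassessable, not absent contacts).
#' @export
contact_sites <- function(model, site, threshold = 8.0, min_separation = 0) {
  if (threshold <= 0) stop("threshold must be positive")
  centre <- .model_xyz(model, site)
  if (is.null(centre)) {
    near <- model$resno[order(abs(model$resno - site))][seq_len(min(5, nrow(model)))]
    stop("site ", site, " unresolved in model; nearest resolved residues: ",
         paste(sort(near), collapse = ", "))
  }
  others <- model[model$resno != site, , drop = FALSE]
  d <- sqrt((others$x - centre[1])^2 + (others$y - centre[2])^2 +
            (others$z - centre[3])^2)
  sep <- abs(others$resno - site)
  keep <- d < threshold & sep >= min_separation
  out <- data.frame(site_i = rep(site, sum(keep)), site_j = others$resno[keep],
                    distance = d[keep], seq_separation = sep[keep])
  out <- out[order(out$site_j), , drop = FALSE]
  rownames(out) <- NULL
  full <- if (nrow(model) > 0) seq(min(model$resno), max(model$resno)) else integer(0)
  unresolved <- setdiff(full, model$resno)
  structure(out, class = c("contact_pairs", "data.frame"),
            threshold = threshold, unresolved = unresolved)
}
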