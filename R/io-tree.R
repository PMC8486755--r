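## Newick tree IO (thin, validated wrappers around ape).

#' Read a rooted phylogeny from a Newick file
#'
#' @param path File containing a single Newick tree.
#' @return An `ape::phylo` object, rooted, with tip names preserved verbatim.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop("unbalanced parentheses in ", path, ": ", n_open, " '(' vs ",
         n_close, "')' (near character ",
         max(utils::tail(gregexpr("[()]", txt)[[1]], 1), 1), ")")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (inherits(tr, "multiPhylo"))
    stop(path, " contains ", length(tr), " trees; expected a single tree")
  if (!ape::is.rooted(tr))
    stop("tree in ", path, " is unrooted; a rooted tree is required")
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree An `ape::phylo` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
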