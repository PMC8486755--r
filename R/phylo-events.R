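## Fitch parsimony ancestral reconstruction and substitution/reversion
## counting on a rooted tree.

#' Drop tips without usable character states
#'
#' Removes tips whose state is missing (`NA`), a gap or `X`. Pruning never
#' increases the parsimony score.
#'
#' @param tree `ape::phylo`.
#' @param tip_states Named character vector over (a superset of) the tips.
#' @return List with `tree` (pruned) and `tip_states` (restricted).
#' @export
prune_missing_states <- function(tree, tip_states) {
  states <- tip_states[tree$tip.label]
  names(states) <- tree$tip.label
  # non-amino-acid alphabets (e.g. nucleotides in simulations) are allowed:
  # only NA, "-" and "X" count as missing
  bad <- is.na(states) | states %in% c("-", "X")
  if (all(bad)) stop("no tips with usable states remain")
  if (any(bad)) {
    tree <- ape::drop.tip(tree, tree$tip.label[bad])
    states <- states[tree$tip.label]
  }
  list(tree = tree, tip_states = states)
}

#' Fitch parsimony ancestral states
#'
#' Assigns one minimum-change state per node under uniform substitution
#' costs. The bottom-up pass computes candidate sets (intersection when
#' non-empty, otherwise union, incrementing the score); the top-down pass
#' resolves each node to its parent's state when that state is a candidate,
#' otherwise to the alphabetically first candidate. The root is resolved
#' alphabetically and flagged when its candidate set is ambiguous. The
#' parsimony score is independent of this tie rule.
#'
#' @param tree Rooted `ape::phylo` (internal nodes of degree >= 2).
#' @param tip_states Named character vector of single-character states for
#'   every tip (prune missing data first, see [prune_missing_states()]).
#' @return Object of class `"fitch_states"`: list with `states` (named by
#'   tip label for tips and `node<N>` for internal nodes, in ape node
#'   order), `score`, `root_ambiguous`, `candidate_sets`, and the `tree`.
#' @export
parsimony_states <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- tip_states[tree$tip.label]
  if (anyNA(states))
    stop("tip(s) without a state: ",
         paste(tree$tip.label[is.na(states)], collapse = ", "))
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[[i]]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  score <- 0
  children <- split(edge[, 2], edge[, 1])
  # in postorder the first edge out of a node comes after all edges inside
  # its subtrees, so unique() yields a child-before-parent node order
  post_parents <- unique(edge[, 1])
  for (node in post_parents) {
    kid_sets <- sets[children[[as.character(node)]]]
    acc <- kid_sets[[1]]
    for (k in kid_sets[-1]) {
      inter <- intersect(acc, k)
      if (length(inter) > 0) acc <- inter
      else {
        acc <- union(acc, k)
        score <- score + 1
      }
    }
    sets[[node]] <- acc
  }
  root <- ntip + 1
  assigned <- character(ntip + nnode)
  assigned[seq_len(ntip)] <- unname(states)
  root_set <- sort(sets[[root]])
  assigned[root] <- root_set[1]
  # preorder: reverse postorder edge list visits each child after its parent
  for (i in rev(seq_len(nrow(edge)))) {
    parent <- edge[i, 1]; child <- edge[i, 2]
    if (child <= ntip) next
    cand <- sets[[child]]
    assigned[child] <- if (assigned[parent] %in% cand) assigned[parent]
                       else sort(cand)[1]
  }
  names(assigned) <- c(tree$tip.label, paste0("node", root:(ntip + nnode)))
  structure(
    list(states = assigned, score = score,
         root_ambiguous = length(root_set) > 1,
         candidate_sets = sets, tree = tree),
    class = "fitch_states")
}

#' @export
print.fitch_states <- function(x, ...) {
  cat(sprintf("Fitch reconstruction: %d tips, parsimony score %d%s\n",
              length(x$tree$tip.label), x$score,
              if (x$root_ambiguous) " (root state ambiguous, resolved alphabetically)" else ""))
  invisible(x)
}

.branch_table <- function(fit) {
  tree <- fit$tree
  edge <- tree$edge
  labels <- names(fit$states)
  data.frame(
    parent = labels[edge[, 1]], child = labels[edge[, 2]],
    parent_id = edge[, 1], child_id = edge[, 2],
    from_aa = unname(fit$states[edge[, 1]]),
    to_aa = unname(fit$states[edge[, 2]]),
    stringsAsFactors = FALSE)
}

#' Count independent substitutions to a target state
#'
#' Counts branches on which the reconstructed parent state differs from
#' `target_aa` while the child state equals it: the number of independent
#' substitution events to the target on the tree.
#'
#' @param fit A [parsimony_states()] result (or any list with `states` and
#'   `tree` in the same layout, e.g. user-supplied ancestral states).
#' @param target_aa Target state.
#' @return List with `n_events` and `events` (data frame of branches with
#'   `parent`, `child`, `from_aa`, `to_aa`).
#' @export
count_events_to <- function(fit, target_aa) {
  br <- .branch_table(fit)
  ev <- br[br$from_aa != target_aa & br$to_aa == target_aa,
           c("parent", "child", "from_aa", "to_aa")]
  rownames(ev) <- NULL
  list(n_events = nrow(ev), events = ev)
}

#' Count reversions to an earlier ancestral state
#'
#' A reversion is a branch with parent state `aa_from` and child state
#' `aa_to` lying below an earlier forward event (`aa_to` to `aa_from`) on
#' its path from the root — i.e. the state `aa_to` is being restored.
#'
#' @inheritParams count_events_to
#' @param aa_from State being left (the derived state).
#' @param aa_to State being restored (the earlier ancestral state).
#' @return Integer count of reversion branches.
#' @export
count_reversions <- function(fit, aa_from, aa_to) {
  br <- .branch_table(fit)
  parent_of <- stats::setNames(br$parent_id, as.character(br$child_id))
  states <- fit$states
  # TRUE when some edge on the path root -> node is a forward
  # aa_to -> aa_from event
  prior_forward <- function(node_id) {
    cur <- node_id
    repeat {
      key <- as.character(cur)
      if (!key %in% names(parent_of)) return(FALSE)  # reached the root
      p <- parent_of[[key]]
      if (states[[p]] == aa_to && states[[cur]] == aa_from) return(TRUE)
      cur <- p
    }
  }
  rev_rows <- which(br$from_aa == aa_from & br$to_aa == aa_to)
  sum(vapply(br$parent_id[rev_rows], prior_forward, TRUE))
}
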