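# Phylogenetic tree comparison: Robinson-Foulds symmetric distance and the
# branch score distance, on unrooted split semantics, with pruning to
# common leaf sets.

# splits of an unrooted tree: named numeric vector split-key -> branch
# length. Keys canonicalize each bipartition by the side NOT containing
# the lexicographically smallest tip. Trivial (single-tip) splits are
# included; RF uses only the non-trivial ones.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  # descendant tips per node via one postorder pass
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tips[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  lens <- tree$edge.length %||% rep(0, nrow(tree$edge))
  # reorder lengths to match postorder edges
  key_e <- paste(tree$edge[, 1L], tree$edge[, 2L])
  lens <- lens[match(paste(edges[, 1L], edges[, 2L]), key_e)]
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1L]
    ch <- edges[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    side <- desc[[edges[r, 2L]]]
    if (ref %in% side) side <- setdiff(tips, side)
    keys[r] <- paste(sort(side), collapse = "|")
  }
  # an unrooted tree has no duplicate splits except possibly when a basal
  # trifurcation produces a complement pair; sum lengths defensively
  tapply(lens, keys, sum)
}

#' Robinson-Foulds and branch score distances between two trees
#'
#' The symmetric (Robinson-Foulds) distance counts the non-trivial
#' bipartitions present in exactly one of the two unrooted trees. The
#' branch score distance sums, over the union of all bipartitions
#' (including terminal branches), the squared difference of branch lengths,
#' with length 0 for a split absent from a tree; its square root is also
#' reported.
#'
#' @param t1,t2 `phylo` objects (or Newick strings / file paths) with
#'   identical leaf sets; use [prune_to_common()] first otherwise.
#' @return list with `symmetric`, `branch_score` and `branch_score_sqrt`.
#' @export
tree_distance <- function(t1, t2) {
  t1 <- as_phylo(t1)
  t2 <- as_phylo(t2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stopf("leaf sets differ; prune_to_common() first")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  ntips <- length(t1$tip.label)
  nontrivial <- function(keys) {
    sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
    keys[sizes > 1L & sizes < ntips - 1L]
  }
  n1 <- nontrivial(names(s1))
  n2 <- nontrivial(names(s2))
  rf <- length(setdiff(n1, n2)) + length(setdiff(n2, n1))
  all_keys <- union(names(s1), names(s2))
  l1 <- ifelse(all_keys %in% names(s1), s1[all_keys], 0)
  l2 <- ifelse(all_keys %in% names(s2), s2[all_keys], 0)
  bs <- sum((l1 - l2)^2)
  list(symmetric = rf, branch_score = bs, branch_score_sqrt = sqrt(bs))
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(ape::read.tree(x))
    return(ape::read.tree(text = x))
  }
  stopf("expected a phylo object, Newick string, or tree file path")
}

#' Prune two trees to their common leaf set
#'
#' Restricts both trees to the shared leaves; degree-2 internal nodes are
#' suppressed with their branch lengths summed.
#'
#' @param t1,t2 `phylo` objects (or Newick strings / file paths).
#' @return list of the two pruned `phylo` trees.
#' @export
prune_to_common <- function(t1, t2) {
  t1 <- as_phylo(t1)
  t2 <- as_phylo(t2)
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 3L) stopf("fewer than 3 shared leaves (%d)", length(common))
  list(ape::keep.tip(t1, common), ape::keep.tip(t2, common))
}
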