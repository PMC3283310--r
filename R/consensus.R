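# ---------------------------------------------------------------------------
# Consensus species-tree methods operating on a list of gene trees sharing a
# common leaf set. Split frequencies are computed on the unrooted view of
# each input tree.
# ---------------------------------------------------------------------------

check_gene_tree_set <- function(trees) {
  if (length(trees) == 0) abort("empty gene-tree set")
  if (!all(vapply(trees, inherits, logical(1), "phylo"))) {
    abort("gene trees must be phylo objects")
  }
  ls <- tip_set(trees[[1]])
  for (t in trees[-1]) {
    if (!identical(tip_set(t), ls)) abort("gene trees are on different leaf sets")
  }
  ls
}

# frequency table of splits over a tree list; returns tibble
# (key, freq, small_size, small_tuple) sorted by the greedy ordering
split_frequencies <- function(trees) {
  leaves <- check_gene_tree_set(trees)
  n <- length(leaves)
  keys <- unlist(lapply(trees, bipartitions), use.names = FALSE)
  if (length(keys) == 0) {
    return(tibble::tibble(
      key = character(0), freq = numeric(0),
      small_size = integer(0), small_tuple = character(0)
    ))
  }
  tab <- table(keys)
  key <- names(tab)
  sides <- lapply(key, split_side)
  small <- lapply(sides, function(s) {
    comp <- setdiff(leaves, s)
    if (length(comp) < length(s)) return(sort(comp))
    if (length(s) < length(comp)) return(sort(s))
    cands <- list(sort(s), sort(comp))
    cands[[order(vapply(cands, paste, character(1), collapse = ","))[1]]]
  })
  out <- tibble::tibble(
    key = key,
    freq = as.numeric(tab) / length(trees),
    small_size = lengths(small),
    small_tuple = vapply(small, paste, character(1), collapse = ",")
  )
  out[order(-out$freq, out$small_size, out$small_tuple), , drop = FALSE]
}

#' Majority consensus tree
#'
#' The tree displaying exactly the bipartitions that occur in strictly more
#' than half of the input trees. Majority splits are always pairwise
#' compatible, so the result is well defined; it may be unresolved.
#'
#' @param trees List of `phylo` objects on a common leaf set.
#' @return A `phylo`.
#' @export
majority_consensus <- function(trees) {
  leaves <- check_gene_tree_set(trees)
  fr <- split_frequencies(trees)
  keep <- fr$key[fr$freq > 0.5]
  tree_from_bipartitions(leaves, as.list(lapply(keep, split_side)))
}

#' Greedy (extended majority) consensus tree
#'
#' Starts from the majority consensus and then walks the remaining observed
#' bipartitions in decreasing frequency, adding each one that is compatible
#' with the set accumulated so far. Equal frequencies are ordered
#' deterministically by smaller-side size, then lexicographically by the
#' smaller side's label tuple. The output always refines the majority
#' consensus.
#'
#' @inheritParams majority_consensus
#' @return A `phylo`.
#' @export
greedy_consensus <- function(trees) {
  leaves <- check_gene_tree_set(trees)
  fr <- split_frequencies(trees)
  accepted <- lapply(fr$key[fr$freq > 0.5], split_side)
  rest <- fr$key[fr$freq <= 0.5]
  for (k in rest) {
    side <- split_side(k)
    if (is_compatible(side, accepted, leaves)) {
      accepted <- c(accepted, list(side))
    }
  }
  tree_from_bipartitions(leaves, accepted)
}
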