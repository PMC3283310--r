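# ---------------------------------------------------------------------------
# Tree accuracy scoring. The missing-branch (false negative, FN) rate is the
# fraction of the true tree's internal bipartitions absent from the estimate;
# unlike Robinson-Foulds it does not penalize the estimate for being
# unresolved, which is why it is the error measure of choice when estimated
# species trees may be partially resolved.
# ---------------------------------------------------------------------------

#' Missing-branch (false negative) rate of an estimated tree
#'
#' Computes the proportion of internal branches of the true tree whose induced
#' bipartitions are missing from the estimated tree. The estimate may be
#' unresolved; the denominator is the internal edge count of the true tree. A
#' rate of 0 means every true bipartition is recovered; 1 means none are.
#'
#' @param true_tree The reference `phylo`; must have at least one internal
#'   edge (a star reference leaves the rate undefined and is an error).
#' @param est_tree The estimated `phylo` on the same leaf set.
#' @return A one-row tibble with columns `fn_rate`, `missing_count`,
#'   `reference_internal_edges`.
#' @examples
#' t1 <- read_newick("((A,B),(C,D),E);")
#' missing_branch_rate(t1, t1)$fn_rate  # 0
#' @export
missing_branch_rate <- function(true_tree, est_tree) {
  check_same_leaves(true_tree, est_tree)
  bt <- bipartitions(true_tree)
  if (length(bt) == 0) {
    abort("true tree has no internal edges: FN rate undefined")
  }
  be <- bipartitions(est_tree)
  miss <- sum(!(bt %in% be))
  tibble::tibble(
    fn_rate = miss / length(bt),
    missing_count = as.integer(miss),
    reference_internal_edges = length(bt)
  )
}

#' Robinson-Foulds (bipartition) distance
#'
#' Size of the symmetric difference between the two trees' sets of non-trivial
#' bipartitions. For two fully resolved trees on `n` leaves the maximum is
#' `2 * (n - 3)`.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  as.integer(sum(!(b1 %in% b2)) + sum(!(b2 %in% b1)))
}
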