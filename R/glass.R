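# ---------------------------------------------------------------------------
# GLASS: species tree from the element-wise minimum of per-gene distance
# matrices, by single-linkage agglomeration. Under a molecular clock the
# minimum coalescence time between two species across many genes converges to
# the species divergence time, so clustering the minima is statistically
# consistent when gene distances are correct.
# ---------------------------------------------------------------------------

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d))) abort("distance matrix must be labeled")
  if (!identical(rownames(d), colnames(d))) abort("row and column labels differ")
  if (anyNA(d)) abort("NaN/NA entries in distance matrix")
  if (any(d < 0)) abort("negative entries in distance matrix")
  invisible(d)
}

#' GLASS species tree from per-gene distance matrices
#'
#' Takes the element-wise minimum across the gene matrices and performs
#' single-linkage agglomeration on the result (at each step the two clusters
#' with the smallest cross-pair distance are merged). The output is a rooted
#' tree whose node depths equal the merge heights; the final merge defines the
#' root.
#'
#' @param matrices A single labeled symmetric matrix or a list of them, all on
#'   the same taxon set; entries nonnegative, zero diagonal.
#' @return A rooted ultrametric `phylo`.
#' @export
glass_tree <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) == 0) abort("need at least one distance matrix")
  taxa <- sort(rownames(matrices[[1]]))
  mats <- lapply(matrices, function(m) {
    check_distance_matrix(m)
    if (!identical(sort(rownames(m)), taxa)) abort("distance matrices are on different taxon sets")
    m[taxa, taxa]
  })
  dmin <- Reduce(pmin, mats)
  dmin <- (dmin + t(dmin)) / 2  # enforce exact symmetry
  hc <- stats::hclust(stats::as.dist(dmin), method = "single")
  phy <- ape::as.phylo(hc)
  # as.phylo.hclust sets leaf depth to height/2; rescale so that node depths
  # are the single-linkage merge heights
  phy$edge.length <- phy$edge.length * 2
  phy
}

#' Path-length distance matrix of a tree
#'
#' Sum of branch lengths along the path between each pair of leaves.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Labeled symmetric matrix with zero diagonal, taxa sorted.
#' @export
tree_path_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  taxa <- sort(rownames(d))
  d[taxa, taxa]
}
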