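# ---------------------------------------------------------------------------
# Desk-scale gene-tree estimation: logdet distances from alignments, neighbor
# joining, nonparametric bootstrap support, and point estimates from tree
# samples. External ML/Bayesian estimators are not reimplemented; trees
# produced by such tools can enter the pipeline through read_newick_lines().
# ---------------------------------------------------------------------------

# coerce an alignment to a character matrix (taxa x sites)
as_alignment <- function(aln) {
  if (is.matrix(aln)) {
    storage.mode(aln) <- "character"
    return(aln)
  }
  if (is.character(aln) && !is.null(names(aln))) {
    lens <- nchar(aln)
    if (length(unique(lens)) != 1) abort("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
    return(m)
  }
  abort("alignment must be a character matrix or a named character vector")
}

check_alignment <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("alignment taxa must be uniquely named")
  }
  invisible(m)
}

#' Logdet distance matrix from an alignment
#'
#' For each taxon pair, counts the 4x4 site pattern matrix `F` over sites
#' where neither sequence has a gap or ambiguity (pairwise deletion) and
#' computes the logdet (paralinear) distance
#' `d = -(1/4) * (ln det(F/n) - (1/2) * sum_i ln(f_i g_i))`, where `f` and `g`
#' are the two sequences' base frequencies; the correction makes `d = 0` for
#' identical sequences. Saturated pairs (singular `F`) are capped at
#' `cap` with a warning.
#'
#' @param aln Character matrix (taxa x sites) over `A,C,G,T,-,N`, or a named
#'   character vector.
#' @param cap Distance assigned to saturated pairs.
#' @return Labeled symmetric matrix, taxa sorted, zero diagonal.
#' @export
logdet_distance <- function(aln, cap = 10) {
  m <- check_alignment(as_alignment(aln))
  taxa <- sort(rownames(m))
  m <- m[taxa, , drop = FALSE]
  idx <- matrix(match(m, DNA_BASES), nrow = nrow(m))  # NA for gaps/ambiguity
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (!any(ok)) abort(sprintf("taxa %s and %s share no comparable sites", taxa[i], taxa[j]))
      FF <- matrix(tabulate((idx[i, ok] - 1L) * 4L + idx[j, ok], nbins = 16L), 4, 4,
                   byrow = TRUE) / sum(ok)
      fi <- rowSums(FF)
      gj <- colSums(FF)
      det_f <- det(FF)
      if (det_f <= 0 || any(fi == 0) || any(gj == 0)) {
        d[i, j] <- d[j, i] <- cap
        capped <- TRUE
      } else {
        val <- -(log(det_f) - 0.5 * sum(log(fi * gj))) / 4
        d[i, j] <- d[j, i] <- max(val, 0)
      }
    }
  }
  if (capped) {
    warn(sprintf("saturated taxon pair(s): distance capped at %g", cap))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; negative estimated branch lengths are clamped
#' to zero.
#'
#' @param d Labeled symmetric distance matrix on >= 4 taxa.
#' @return Unrooted `phylo` with branch lengths.
#' @export
nj_tree <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 4) abort("neighbor joining needs >= 4 taxa")
  phy <- ape::nj(d)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Gene tree with nonparametric bootstrap support
#'
#' The point tree is the neighbor-joining tree on the logdet distances of the
#' alignment. For each replicate, alignment columns are resampled with
#' replacement and the tree recomputed; the support of each internal edge of
#' the point tree is the fraction of replicate trees displaying its
#' bipartition. Supports are attached as internal node labels.
#'
#' @param aln Alignment (see [logdet_distance()]).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed.
#' @return Unrooted `phylo` with supports in `node.label`.
#' @export
bootstrap_support <- function(aln, replicates = 100, seed = NULL) {
  m <- check_alignment(as_alignment(aln))
  if (replicates < 1) abort("replicates must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  point <- nj_tree(suppressWarnings(logdet_distance(m)))
  keys <- bipartitions(point)
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- tryCatch(
      nj_tree(suppressWarnings(logdet_distance(m[, cols, drop = FALSE]))),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) next
    hit <- keys %in% bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  attach_supports(point, counts / replicates)
}

# write per-split supports into node labels of the (unrooted) tree
attach_supports <- function(phy, supports) {
  leaves <- tip_set(phy)
  n <- length(leaves)
  clades <- node_clades(phy)
  ntip <- Ntip(phy)
  labs <- rep("", Nnode(phy))
  for (v in seq.int(ntip + 1L, ntip + Nnode(phy))) {
    if (v == root_node(phy)) next
    cl <- clades[[v]]
    if (length(cl) < 2 || length(cl) > n - 2) next
    key <- split_key(cl, leaves)
    if (key %in% names(supports)) labs[v - ntip] <- as.character(supports[[key]])
  }
  phy$node.label <- labs
  phy
}

#' Point estimate from a sample of trees
#'
#' `kind = "majority"` returns the majority consensus of the sample;
#' `kind = "map"` returns the most frequent (unrooted) topology, ties broken
#' by first occurrence.
#'
#' @param sample Non-empty list of `phylo` objects on a common leaf set.
#' @param kind `"majority"` or `"map"`.
#' @return A `phylo`.
#' @export
point_estimates <- function(sample, kind = c("majority", "map")) {
  kind <- match.arg(kind)
  check_gene_tree_set(sample)
  if (kind == "majority") return(majority_consensus(sample))
  keys <- vapply(sample, topology_key, character(1))
  counts <- table(factor(keys, levels = unique(keys)))  # first-occurrence ties
  sample[[match(names(counts)[which.max(counts)], keys)]]
}
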