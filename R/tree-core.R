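#' @importFrom ape read.tree write.tree unroot is.rooted root multi2di di2multi
#' @importFrom ape Ntip Nnode rphylo
#' @importFrom rlang abort warn
#' @importFrom stats cophenetic hclust as.dist setNames reorder
NULL

# ---------------------------------------------------------------------------
# Tree data model: trees are ape "phylo" objects throughout. Edge supports
# live in node.label, normalized to [0, 1] at parse time. Bipartitions are
# encoded as canonical keys: the side NOT containing the lexicographically
# smallest leaf, sorted and comma-joined.
# ---------------------------------------------------------------------------

#' Parse a Newick string into a phylogenetic tree
#'
#' Reads a Newick tree with optional branch lengths and internal-node support
#' labels. Support values may be on a 0--1 or a 0--100 scale; any value above 1
#' triggers the percentage interpretation and all supports are normalized to
#' \[0, 1\]. Multifurcations are preserved.
#'
#' @param text A Newick string (terminated by `;`).
#' @param file Alternatively, path to a file whose first tree is read.
#' @return An [ape::read.tree()] `phylo` object with normalized supports in
#'   `node.label` (when present).
#' @examples
#' tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    abort("supply either `text` or `file`")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_brackets(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Newick parse error: no tree could be read")
  validate_tree(phy)
  normalize_supports(phy)
}

#' Read a file of Newick trees, one per line
#'
#' @param file Path to a file with one Newick tree per line.
#' @return A list of `phylo` objects.
#' @export
read_newick_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) read_newick(text = l))
}

# cheap structural pre-check so the common malformation (unbalanced brackets)
# gets an error naming the character offset
check_newick_brackets <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Newick parse error: unmatched ')' at character %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "Newick parse error: %d unclosed '(' at end of string (length %d)",
      depth, length(chars)
    ))
  }
  invisible(TRUE)
}

validate_tree <- function(phy) {
  if (anyDuplicated(phy$tip.label)) {
    abort(paste0(
      "duplicate leaf label(s): ",
      paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", ")
    ))
  }
  if (any(!nzchar(phy$tip.label))) abort("empty leaf label")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0)) {
    abort("negative branch length")
  }
  invisible(phy)
}

normalize_supports <- function(phy) {
  if (is.null(phy$node.label)) return(phy)
  supp <- suppressWarnings(as.numeric(phy$node.label))
  if (all(is.na(supp))) return(phy)            # labels are names, not supports
  if (any(supp > 1, na.rm = TRUE)) supp <- supp / 100
  if (any(supp < 0 | supp > 1, na.rm = TRUE)) {
    abort("support values outside [0,1] after scale normalization")
  }
  phy$node.label <- ifelse(is.na(supp), phy$node.label, as.character(supp))
  phy
}

#' Write a tree as a Newick string
#'
#' Inverse of [read_newick()]: the returned string re-reads to an isomorphic
#' tree (topology, labels, branch lengths to printed precision, supports).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

tip_set <- function(phy) sort(phy$tip.label)

# list of leaf-label vectors for every node (tips and internals), indexed by
# ape node id
node_clades <- function(phy) {
  n <- Ntip(phy)
  m <- n + Nnode(phy)
  clades <- vector("list", m)
  clades[seq_len(n)] <- as.list(phy$tip.label)
  po <- postorder_nodes(phy)
  kids <- children_map(phy)
  for (v in po) {
    if (v > n) clades[[v]] <- unlist(clades[kids[[v]]], use.names = FALSE)
  }
  clades
}

postorder_nodes <- function(phy) {
  e <- stats::reorder(phy, "postorder")$edge
  unique(c(e[, 2], e[nrow(e), 1]))  # children in postorder, then the root
}

children_map <- function(phy) {
  m <- Ntip(phy) + Nnode(phy)
  kids <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  kids
}

root_node <- function(phy) Ntip(phy) + 1L

# canonical key of the split separating `side` from the rest of `leaves`:
# the side not containing the lexicographically smallest leaf, sorted
split_key <- function(side, leaves) {
  if (min(leaves) %in% side) side <- setdiff(leaves, side)
  paste(sort(side), collapse = ",")
}

split_side <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

#' Non-trivial bipartitions of a tree
#'
#' Returns the edge-induced taxon bipartitions of the (unrooted view of the)
#' tree, one per internal edge, as canonical keys: each key lists the side of
#' the split that does not contain the lexicographically smallest leaf, sorted
#' and comma-joined. The root is ignored, so rooted and unrooted versions of
#' the same topology give identical sets.
#'
#' @param tree A `phylo` object.
#' @return Character vector of split keys with attribute `leaves` (the sorted
#'   leaf set). Empty for trees with fewer than 4 leaves or a star topology.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tip_set(tree)
  n <- length(leaves)
  if (n < 4) return(structure(character(0), leaves = leaves))
  clades <- node_clades(tree)
  keys <- character(0)
  for (v in seq.int(Ntip(tree) + 1L, Ntip(tree) + Nnode(tree))) {
    if (v == root_node(tree)) next
    cl <- clades[[v]]
    if (length(cl) >= 2 && length(cl) <= n - 2) {
      keys <- c(keys, split_key(cl, leaves))
    }
  }
  structure(unique(keys), leaves = leaves)
}

# per-split supports of the unrooted view; errors if any internal edge lacks one
split_supports <- function(tree) {
  leaves <- tip_set(tree)
  n <- length(leaves)
  clades <- node_clades(tree)
  ntip <- Ntip(tree)
  labs <- tree$node.label
  if (is.null(labs)) abort("tree carries no support values")
  keys <- character(0)
  vals <- numeric(0)
  for (v in seq.int(ntip + 1L, ntip + Nnode(tree))) {
    if (v == root_node(tree)) next
    cl <- clades[[v]]
    if (length(cl) < 2 || length(cl) > n - 2) next
    keys <- c(keys, split_key(cl, leaves))
    vals <- c(vals, suppressWarnings(as.numeric(labs[v - ntip])))
  }
  out <- vapply(split(vals, keys), function(x) {
    # a rooted binary tree's two root children induce the same split; keep max
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(out)) abort("internal edge without support value; supply a fully annotated tree")
  out
}

#' Contract low-support branches
#'
#' Collapses every internal edge whose support is strictly below `threshold`
#' (an edge with support exactly at the threshold is kept), producing a
#' possibly multifurcating tree. Leaf edges are never touched. All internal
#' edges must carry a support value. Branch lengths are not propagated: the
#' output is a topology for topology-only consumers (consensus, constrained
#' MDC scoring).
#'
#' @param tree A `phylo` with supports on all internal edges (see
#'   [read_newick()]).
#' @param threshold Support threshold in \[0, 1\], e.g. `0.75`.
#' @return An unrooted `phylo` displaying exactly the retained bipartitions.
#' @export
contract_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), threshold >= 0, threshold <= 1)
  leaves <- tip_set(tree)
  if (length(leaves) < 4) return(star_tree(leaves))
  supp <- split_supports(tree)
  keep <- names(supp)[supp >= threshold]
  tree_from_bipartitions(leaves, as.list(lapply(keep, split_side)))
}

#' Star tree on a leaf set
#'
#' @param leaves Character vector of leaf labels.
#' @return A `phylo` with a single internal node.
#' @export
star_tree <- function(leaves) {
  read_newick(text = paste0("(", paste(sort(leaves), collapse = ","), ");"))
}

#' Test whether a bipartition is compatible with a set of bipartitions
#'
#' Two splits of the same leaf set are compatible when some one of the four
#' pairwise side intersections is empty; a split is compatible with a set when
#' it is pairwise compatible with every member (pairwise compatibility of
#' splits implies joint displayability on a single tree).
#'
#' @param b One side of the candidate split (character vector of leaf labels),
#'   or a canonical key string.
#' @param bs A set of splits: character vector of keys, or list of sides.
#' @param leaves The full leaf set.
#' @return `TRUE` or `FALSE`.
#' @export
is_compatible <- function(b, bs, leaves) {
  side <- as_side(b)
  if (!all(side %in% leaves)) abort("split side contains labels outside the leaf set")
  sides <- lapply(as_side_list(bs), function(s) {
    if (!all(s %in% leaves)) abort("split side contains labels outside the leaf set")
    s
  })
  all(vapply(sides, function(s) splits_compatible(side, s, leaves), logical(1)))
}

as_side <- function(b) {
  if (length(b) == 1 && grepl(",", b, fixed = TRUE)) split_side(b) else b
}

as_side_list <- function(bs) {
  if (is.list(bs)) lapply(bs, as_side) else lapply(bs, function(k) split_side(k))
}

splits_compatible <- function(a, b, leaves) {
  ca <- setdiff(leaves, a)
  cb <- setdiff(leaves, b)
  length(intersect(a, b)) == 0 || length(intersect(a, cb)) == 0 ||
    length(intersect(ca, b)) == 0 || length(intersect(ca, cb)) == 0
}

#' Build the minimal tree displaying a compatible set of bipartitions
#'
#' @param leaves Full leaf set (character vector).
#' @param biparts Splits as a character vector of canonical keys or a list of
#'   sides. Trivial splits (a side with fewer than 2 or more than
#'   `length(leaves) - 2` leaves) are rejected.
#' @return A `phylo` whose [bipartitions()] equal the input set. The empty set
#'   yields the star tree.
#' @export
tree_from_bipartitions <- function(leaves, biparts = list()) {
  leaves <- sort(leaves)
  n <- length(leaves)
  sides <- as_side_list(biparts)
  if (length(sides) == 0) return(star_tree(leaves))
  clusters <- unique(vapply(sides, split_key, character(1), leaves = leaves))
  cl_sides <- lapply(clusters, split_side)
  sizes <- lengths(cl_sides)
  if (any(sizes < 2 | sizes > n - 2)) abort("trivial bipartition supplied")
  for (i in seq_along(cl_sides)) {
    for (j in seq_len(i - 1L)) {
      if (!splits_compatible(cl_sides[[i]], cl_sides[[j]], leaves)) {
        abort("incompatible bipartition set")
      }
    }
  }
  # canonical sides exclude the smallest leaf, hence form a laminar family
  nwk <- paste0("(", build_laminar_newick(leaves, cl_sides), ");")
  read_newick(text = nwk)
}

build_laminar_newick <- function(set, clusters) {
  inside <- clusters[vapply(clusters, function(cl) all(cl %in% set) && length(cl) < length(set), logical(1))]
  maximal <- inside[vapply(seq_along(inside), function(i) {
    !any(vapply(seq_along(inside), function(j) {
      length(inside[[i]]) < length(inside[[j]]) && all(inside[[i]] %in% inside[[j]])
    }, logical(1)))
  }, logical(1))]
  covered <- unique(unlist(maximal))
  singles <- setdiff(set, covered)
  parts <- c(
    sort(singles),
    vapply(maximal, function(cl) {
      paste0("(", build_laminar_newick(cl, inside), ")")
    }, character(1))
  )
  paste(parts, collapse = ",")
}

#' All rootings of an unrooted tree
#'
#' Inserts a root on each edge of the (unrooted view of the) input tree and
#' returns the resulting rooted trees, one per edge.
#'
#' @param tree A `phylo`; a rooted input is unrooted first.
#' @return List of rooted `phylo` objects; length equals the unrooted edge
#'   count (`2n - 3` for a binary tree on `n` leaves).
#' @export
all_rootings <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  u <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (Ntip(u) < 3) abort("need at least 3 leaves to enumerate rootings")
  clades <- node_clades(u)
  lapply(seq_len(nrow(u$edge)), function(i) {
    side <- clades[[u$edge[i, 2]]]
    ape::root(u, outgroup = side, resolve.root = TRUE)
  })
}

# rooted clusters (leaf-label vectors) of all internal non-root nodes,
# i.e. the clusters with an edge above them
internal_clusters <- function(tree) {
  clades <- node_clades(tree)
  ids <- seq.int(Ntip(tree) + 1L, Ntip(tree) + Nnode(tree))
  ids <- ids[ids != root_node(tree)]
  clades[ids]
}

# full clade family of a rooted tree: every node's leaf set (tips, internals,
# root), as a list of character vectors
clade_family <- function(tree) {
  node_clades(tree)
}

# canonical unrooted-topology fingerprint
topology_key <- function(tree) {
  paste(sort(bipartitions(tree)), collapse = ";")
}

#' Randomly resolve multifurcations to a binary tree
#'
#' @param tree A `phylo`, possibly multifurcating.
#' @param seed Optional integer; when given the resolution is reproducible.
#' @return A fully resolved `phylo`.
#' @export
random_resolve <- function(tree, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  ape::multi2di(tree, random = TRUE)
}

same_leaf_sets <- function(t1, t2) identical(tip_set(t1), tip_set(t2))

check_same_leaves <- function(t1, t2) {
  if (!same_leaf_sets(t1, t2)) abort("trees are on different leaf sets")
  invisible(TRUE)
}
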