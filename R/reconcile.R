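# ---------------------------------------------------------------------------
# Gene-tree / species-tree reconciliation criteria.
#
# Deep coalescences (extra lineages) are counted with the standard
# maximal-clades-per-cluster formula: for each cluster C of the species tree
# (one per internal edge), k_C is the number of maximal gene-tree clades whose
# leaf sets lie inside C, and the branch above C carries k_C - 1 extra
# lineages. Duplications and losses use the LCA mapping: a gene node is a
# duplication when it maps to the same species node as one of its children,
# and losses accumulate along the mapped path lengths.
# ---------------------------------------------------------------------------

# per-species-tree scoring context reused across many gene trees
species_context <- function(species) {
  stopifnot(inherits(species, "phylo"))
  if (!ape::is.rooted(species)) abort("species tree must be rooted")
  clades <- node_clades(species)
  m <- Ntip(species) + Nnode(species)
  depth <- integer(m)
  kids <- children_map(species)
  walk <- function(v, d) {
    depth[v] <<- d
    for (u in kids[[v]]) walk(u, d + 1L)
  }
  walk(root_node(species), 0L)
  internal_ids <- setdiff(seq.int(Ntip(species) + 1L, m), root_node(species))
  list(
    tree = species,
    leaves = tip_set(species),
    clades = clades,
    depth = depth,
    internal_ids = internal_ids,
    internal_clusters = clades[internal_ids]
  )
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every node of a rooted gene tree to the lowest common ancestor, in the
#' species tree, of the gene node's leaf labels. The map is monotone: a node
#' maps at or below its parent's image.
#'
#' @param gene Rooted `phylo` whose leaf labels are a subset of the species
#'   tree's.
#' @param species Rooted `phylo`.
#' @return Integer vector indexed by gene node id (tips `1..Ntip`, then
#'   internal nodes in ape numbering), giving species node ids.
#' @export
lca_mapping <- function(gene, species) {
  if (!ape::is.rooted(gene)) abort("gene tree must be rooted")
  ctx <- species_context(species)
  if (!all(gene$tip.label %in% ctx$leaves)) {
    abort("gene leaf labels are not a subset of the species leaf set")
  }
  gclades <- node_clades(gene)
  vapply(gclades, function(cl) lca_of_set(ctx, cl), integer(1))
}

lca_of_set <- function(ctx, labels) {
  containing <- which(vapply(ctx$clades, function(s) all(labels %in% s), logical(1)))
  containing[which.min(lengths(ctx$clades[containing]))]
}

# extra-lineage count from a gene clade family (list of leaf-label vectors)
mdc_from_family <- function(ctx, family) {
  total <- 0L
  for (C in ctx$internal_clusters) {
    inC <- family[vapply(family, function(cl) all(cl %in% C), logical(1))]
    if (length(inC) == 0) next
    ord <- order(-lengths(inC))
    maximal <- list()
    for (i in ord) {
      cl <- inC[[i]]
      if (!any(vapply(maximal, function(mx) all(cl %in% mx), logical(1)))) {
        maximal <- c(maximal, list(cl))
      }
    }
    total <- total + length(maximal) - 1L
  }
  as.integer(total)
}

#' Deep-coalescence (MDC) score of a rooted gene tree
#'
#' Number of extra lineages implied by embedding the gene tree in the species
#' tree. A multifurcating gene tree is scored as the minimum over its rooted
#' binary refinements (enumerated exhaustively, with a guard on the number of
#' refinements).
#'
#' @param species Rooted `phylo` on the gene tree's leaf set.
#' @param gene Rooted `phylo`; an unrooted gene tree is an error (use
#'   [mdc_score_unrooted()]).
#' @param refinement_limit Maximum number of refinements enumerated for
#'   multifurcating gene trees.
#' @return Nonnegative integer.
#' @export
mdc_score <- function(species, gene, refinement_limit = 20000) {
  if (!ape::is.rooted(gene)) abort("gene tree is unrooted; use mdc_score_unrooted()")
  check_same_leaves(species, gene)
  ctx <- species_context(species)
  if (is_binary_rooted(gene)) {
    return(mdc_from_family(ctx, clade_family(gene)))
  }
  fams <- refinement_families(gene, refinement_limit)
  min(vapply(fams, function(f) mdc_from_family(ctx, f), integer(1)))
}

#' Constrained MDC score of an unrooted, possibly unresolved gene tree
#'
#' Minimum deep-coalescence score over all rootings of the gene tree and all
#' rooted binary refinements of each rooting. This treats the observed gene
#' tree topology as a constraint on the true (rooted, binary) gene tree, so a
#' star gene tree scores 0 against any species tree.
#'
#' @inheritParams mdc_score
#' @param gene `phylo`, unrooted and possibly multifurcating (a rooted input
#'   is unrooted first).
#' @return Nonnegative integer.
#' @export
mdc_score_unrooted <- function(species, gene, refinement_limit = 20000) {
  check_same_leaves(species, gene)
  ctx <- species_context(species)
  fams <- constrained_gene_families(gene, refinement_limit)
  min(vapply(fams, function(f) mdc_from_family(ctx, f), integer(1)))
}

# All clade families realizable by an estimated gene tree under the
# constrained-MDC contract: every rooted binary tree whose unrooted topology
# displays the gene tree's splits. Refinement happens on the unrooted
# topology first (anchored at a leaf edge, which every tree has), and each
# refined binary tree is then rooted on each of its edges -- this covers
# roots on edges that only exist after refinement.
constrained_gene_families <- function(gene, refinement_limit = 20000) {
  u <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  anchored <- ape::root(u, outgroup = tip_set(u)[1], resolve.root = TRUE)
  refs <- if (is_binary_rooted(anchored)) {
    list(anchored)
  } else {
    refinement_trees(anchored, refinement_limit)
  }
  unlist(lapply(refs, function(b) {
    lapply(all_rootings(b), clade_family)
  }), recursive = FALSE)
}

is_binary_rooted <- function(phy) {
  ape::is.rooted(phy) && ape::is.binary(phy)
}

# ---- exhaustive enumeration of binary refinements (clade families) --------

refinement_count <- function(phy) {
  kids <- children_map(phy)
  counts <- vapply(kids, length, integer(1))
  degs <- counts[counts > 2]
  prod(vapply(degs, function(k) prod(seq(2 * k - 3, 1, by = -2)), numeric(1)))
}

# all rooted binary refinements of a rooted (possibly multifurcating) tree
refinement_trees <- function(phy, refinement_limit = 20000) {
  nref <- refinement_count(phy)
  if (nref > refinement_limit) {
    abort(sprintf(
      "gene tree has %.0f binary refinements, above the enumeration limit (%d)",
      nref, refinement_limit
    ))
  }
  kids <- children_map(phy)
  refine_node <- function(v) {
    if (v <= Ntip(phy)) return(phy$tip.label[v])
    child_alts <- lapply(kids[[v]], refine_node)  # per child: newick fragments
    out <- character(0)
    for (combo in cartesian_character(child_alts)) {
      out <- c(out, binary_join(combo))
    }
    out
  }
  lapply(refine_node(root_node(phy)), function(nwk) {
    read_newick(text = paste0(nwk, ";"))
  })
}

# list of clade families, one per rooted binary refinement of `phy`
refinement_families <- function(phy, refinement_limit = 20000) {
  lapply(refinement_trees(phy, refinement_limit), clade_family)
}

# all combinations across a list of character vectors
cartesian_character <- function(alts) {
  grid <- expand.grid(alts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
}

# all fully resolved newick fragments joining the given block fragments
binary_join <- function(blocks) {
  if (length(blocks) == 1) return(blocks)
  if (length(blocks) == 2) return(paste0("(", blocks[1], ",", blocks[2], ")"))
  rest <- blocks[-1]
  out <- character(0)
  for (asz in 0:(length(rest) - 1)) {
    picks <- if (asz == 0) list(integer(0)) else combn(seq_along(rest), asz, simplify = FALSE)
    for (pick in picks) {
      A <- c(blocks[1], rest[pick])
      B <- if (asz == 0) rest else rest[-pick]
      for (a in binary_join(A)) {
        for (b in binary_join(B)) {
          out <- c(out, paste0("(", a, ",", b, ")"))
        }
      }
    }
  }
  out
}

#' Duplication and loss reconciliation score
#'
#' Reconciles a rooted binary gene tree against a rooted binary species tree
#' on the same leaf set under the LCA mapping and returns the implied
#' duplication, loss and extra-lineage counts.
#'
#' @param species,gene Rooted binary `phylo` objects on the same leaf set.
#' @return One-row tibble with columns `duplications`, `losses`,
#'   `extra_lineages`.
#' @export
dup_loss_score <- function(species, gene) {
  check_same_leaves(species, gene)
  if (!is_binary_rooted(gene)) abort("gene tree must be rooted and fully resolved")
  if (!is_binary_rooted(species)) abort("species tree must be rooted and fully resolved")
  ctx <- species_context(species)
  gctx <- gene_context(gene)
  dl <- dup_loss_core(ctx, gctx)
  tibble::tibble(
    duplications = dl$dup,
    losses = dl$loss,
    extra_lineages = mdc_from_family(ctx, gctx$clades)
  )
}

# precomputed gene-side structures, reusable across species trees
gene_context <- function(gene) {
  list(
    clades = clade_family(gene),
    kids = children_map(gene),
    ntip = Ntip(gene),
    nnode = Nnode(gene)
  )
}

dup_loss_core <- function(ctx, gctx) {
  M <- vapply(gctx$clades, function(cl) lca_of_set(ctx, cl), integer(1))
  dup <- 0L
  loss <- 0L
  for (v in seq.int(gctx$ntip + 1L, gctx$ntip + gctx$nnode)) {
    ch <- gctx$kids[[v]]
    is_dup <- any(M[ch] == M[v])
    dup <- dup + as.integer(is_dup)
    path <- sum(ctx$depth[M[ch]] - ctx$depth[M[v]])
    loss <- loss + path - if (is_dup) 0L else 2L
  }
  list(dup = as.integer(dup), loss = as.integer(loss))
}
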