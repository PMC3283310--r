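# ---------------------------------------------------------------------------
# Hill-climbing search for the species tree minimizing a reconciliation
# criterion (deep coalescences, duplications, or duplications + losses)
# summed over the gene trees. Moves are rooted NNI rearrangements; the start
# tree is the greedy consensus of the gene trees, randomly refined to binary,
# optionally followed by random-topology restarts. Deterministic given seed.
# ---------------------------------------------------------------------------

#' Search configuration for [search_species_tree()]
#'
#' @param criterion One of `"mdc"`, `"dup"`, `"duploss"`.
#' @param moves `"nni"` for rooted nearest-neighbor interchanges, or `"spr"`
#'   for the larger rooted subtree-prune-and-regraft neighborhood (which
#'   contains the NNI moves).
#' @param max_iterations Maximum hill-climbing steps per start (>= 1).
#' @param random_restarts Number of additional random starting topologies.
#' @param seed Integer seed controlling start-tree refinement and restarts.
#' @param refinement_limit Passed to the constrained-MDC scorer.
#' @return A list of class `search_config`.
#' @export
search_config <- function(criterion = c("mdc", "dup", "duploss"),
                          moves = c("nni", "spr"),
                          max_iterations = 100L,
                          random_restarts = 2L,
                          seed = 1L,
                          refinement_limit = 20000) {
  criterion <- match.arg(criterion)
  moves <- match.arg(moves)
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  if (random_restarts < 0) abort("random_restarts must be >= 0")
  structure(
    list(
      criterion = criterion,
      moves = moves,
      max_iterations = as.integer(max_iterations),
      random_restarts = as.integer(random_restarts),
      seed = as.integer(seed),
      refinement_limit = refinement_limit
    ),
    class = "search_config"
  )
}

# Precompute everything about the gene trees that the criterion needs, so
# that evaluating one candidate species tree is cheap.
criterion_context <- function(trees, config) {
  leaves <- check_gene_tree_set(trees)
  crit <- config$criterion
  if (crit == "mdc") {
    # rooted gene trees are scored as given; unrooted (or unresolved) ones over
    # all rootings and binary refinements: the constrained-MDC contract
    fams <- lapply(trees, function(g) {
      if (ape::is.rooted(g)) {
        if (is_binary_rooted(g)) list(clade_family(g)) else refinement_families(g, config$refinement_limit)
      } else {
        constrained_gene_families(g, config$refinement_limit)
      }
    })
    score_fun <- function(species) {
      ctx <- species_context(species)
      sum(vapply(fams, function(fs) {
        min(vapply(fs, function(f) mdc_from_family(ctx, f), integer(1)))
      }, integer(1)))
    }
  } else {
    # dup / duploss need fully resolved gene trees; unrooted inputs are scored
    # at their best rooting
    gene_rootings <- lapply(trees, function(g) {
      rs <- if (is_binary_rooted(g)) {
        list(g)
      } else if (!ape::is.rooted(g) && ape::is.binary(g)) {
        all_rootings(g)
      } else {
        abort("dup/duploss criteria require fully resolved gene trees")
      }
      lapply(rs, gene_context)
    })
    score_fun <- function(species) {
      ctx <- species_context(species)
      sum(vapply(gene_rootings, function(rs) {
        min(vapply(rs, function(gctx) {
          dl <- dup_loss_core(ctx, gctx)
          if (crit == "dup") dl$dup else dl$dup + dl$loss
        }, integer(1)))
      }, integer(1)))
    }
  }
  list(leaves = leaves, score = score_fun)
}

#' Estimate a species tree by criterion-based search
#'
#' Minimizes the chosen reconciliation criterion (total over gene trees) by
#' hill climbing over rooted binary species trees with NNI moves. The first
#' start is the greedy consensus of the gene trees randomly refined to binary;
#' `random_restarts` further climbs start from random topologies. Ties are
#' broken by first encounter, so the result is deterministic given the seed.
#'
#' @param trees List of gene trees (`phylo`) on a common leaf set. Under
#'   `"mdc"` they may be unrooted and partially resolved; under `"dup"` and
#'   `"duploss"` they must be fully resolved (rooted, or unrooted and scored
#'   at their best rooting).
#' @param config A [search_config()].
#' @return An object of class `stree_search` with elements `tree` (rooted
#'   binary `phylo`), `score`, and `criterion`; it has [print()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
search_species_tree <- function(trees, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  ctx <- criterion_context(trees, config)
  withr::local_seed(config$seed)
  starts <- list(random_resolve(rooted_from_unrooted(greedy_consensus(trees))))
  if (config$random_restarts > 0) {
    for (i in seq_len(config$random_restarts)) {
      starts <- c(starts, list(random_rooted_tree(ctx$leaves)))
    }
  }
  nbr_fun <- if (config$moves == "spr") rooted_spr_neighbors else rooted_nni_neighbors
  best <- NULL
  for (s in starts) {
    res <- hill_climb(s, ctx$score, config$max_iterations, nbr_fun)
    if (is.null(best) || res$score < best$score) best <- res
  }
  structure(
    list(
      tree = best$tree, score = best$score, criterion = config$criterion,
      n_genes = length(trees), config = config
    ),
    class = "stree_search"
  )
}

#' @export
print.stree_search <- function(x, ...) {
  cat(sprintf(
    "Species-tree search (%s criterion): score %d over %d gene tree(s)\n",
    x$criterion, x$score, x$n_genes
  ))
  cat(write_newick(x$tree), "\n")
  invisible(x)
}

rooted_from_unrooted <- function(phy) {
  if (ape::is.rooted(phy)) return(phy)
  ape::root(phy, outgroup = tip_set(phy)[1], resolve.root = TRUE)
}

random_rooted_tree <- function(leaves) {
  ape::rtree(length(leaves), tip.label = sample(leaves), br = NULL)
}

# Steepest-descent hill climbing with bounded plateau walking: strictly
# improving moves are always taken (first-found ties); when none exists, up
# to `plateau` consecutive equal-score moves to unvisited topologies are
# allowed, which escapes the flat regions typical of reconciliation
# criteria.
hill_climb <- function(start, score_fun, max_iterations,
                       neighbor_fun = rooted_nni_neighbors, plateau = 10L) {
  cur <- start
  cur_score <- score_fun(cur)
  visited <- nested_canonical(as_nested(cur))
  plateau_left <- plateau
  for (it in seq_len(max_iterations)) {
    nbrs <- neighbor_fun(cur)
    scores <- vapply(nbrs, score_fun, integer(1))
    if (any(scores < cur_score)) {
      pick <- which.min(scores)
      cur <- nbrs[[pick]]
      cur_score <- scores[pick]
      visited <- c(visited, nested_canonical(as_nested(cur)))
      plateau_left <- plateau
      next
    }
    if (plateau_left > 0L && any(scores == cur_score)) {
      keys <- vapply(nbrs, function(nb) nested_canonical(as_nested(nb)), character(1))
      open <- which(scores == cur_score & !(keys %in% visited))
      if (length(open) > 0) {
        cur <- nbrs[[open[1]]]
        visited <- c(visited, keys[open[1]])
        plateau_left <- plateau_left - 1L
        next
      }
    }
    break
  }
  list(tree = cur, score = cur_score)
}

# All rooted NNI neighbors: for every internal edge (u -> v with v internal),
# swap one grandchild (child of v) with v's sibling.
rooted_nni_neighbors <- function(phy) {
  stopifnot(is_binary_rooted(phy))
  clades <- node_clades(phy)
  kids <- children_map(phy)
  ntip <- Ntip(phy)
  out <- list()
  for (u in seq.int(ntip + 1L, ntip + Nnode(phy))) {
    ch <- kids[[u]]
    for (j in seq_along(ch)) {
      v <- ch[j]
      if (v <= ntip) next
      sib <- ch[-j]
      gch <- kids[[v]]
      for (g in gch) {
        # new subtree at u: ( (sibling, other grandchild), swapped grandchild )
        other <- setdiff(gch, g)
        out <- c(out, list(rebuild_with_swap(phy, clades, u, sib, g, other)))
      }
    }
  }
  out
}

# ---- rooted SPR neighborhood ----------------------------------------------
# Trees are manipulated as nested lists (tip = label, internal node = list of
# children); every non-root subtree is pruned and regrafted onto every node
# of the remainder (including above its root). Duplicate topologies are
# removed via a canonical rooted key.

as_nested <- function(phy) {
  kids <- children_map(phy)
  build <- function(v) {
    if (v <= Ntip(phy)) return(phy$tip.label[v])
    lapply(kids[[v]], build)
  }
  build(root_node(phy))
}

nested_to_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, nested_to_newick, character(1)), collapse = ","), ")")
}

nested_canonical <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(sort(vapply(node, nested_canonical, character(1))), collapse = ","), ")")
}

nested_paths <- function(node, prefix = integer(0)) {
  if (is.character(node)) return(list())
  out <- list()
  for (i in seq_along(node)) {
    out <- c(out, list(c(prefix, i)), nested_paths(node[[i]], c(prefix, i)))
  }
  out
}

nested_get <- function(node, path) {
  for (i in path) node <- node[[i]]
  node
}

nested_remove <- function(node, path) {
  if (length(path) == 1) {
    rest <- node[-path[1]]
    if (length(rest) == 1) return(rest[[1]])  # collapse the unary node
    return(rest)
  }
  node[[path[1]]] <- nested_remove(node[[path[1]]], path[-1])
  node
}

nested_replace <- function(node, path, value) {
  if (length(path) == 0) return(value)
  node[[path[1]]] <- nested_replace(node[[path[1]]], path[-1], value)
  node
}

rooted_spr_neighbors <- function(phy) {
  stopifnot(is_binary_rooted(phy))
  root <- as_nested(phy)
  seen <- character(0)
  out <- list()
  for (p in nested_paths(root)) {
    S <- nested_get(root, p)
    R <- nested_remove(root, p)
    if (is.character(R)) next  # pruning next to the root leaf: nothing to graft onto
    for (q in c(list(integer(0)), nested_paths(R))) {
      N <- nested_replace(R, q, list(S, nested_get(R, q)))
      key <- nested_canonical(N)
      if (key %in% seen) next
      seen <- c(seen, key)
      out <- c(out, list(read_newick(text = paste0(nested_to_newick(N), ";"))))
    }
  }
  out
}

# Rebuild the tree (as newick on leaf-label groups) with the NNI applied.
rebuild_with_swap <- function(phy, clades, u, sib, g, other) {
  kids <- children_map(phy)
  nwk_of <- function(v) {
    if (v <= Ntip(phy)) return(phy$tip.label[v])
    if (v == u) {
      inner <- paste0("(", nwk_of(sib), ",", nwk_of(other), ")")
      return(paste0("(", inner, ",", nwk_of(g), ")"))
    }
    paste0("(", paste(vapply(kids[[v]], nwk_of, character(1)), collapse = ","), ")")
  }
  read_newick(text = paste0(nwk_of(root_node(phy)), ";"))
}
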