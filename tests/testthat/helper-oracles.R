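# Independent brute-force oracles used to validate the reconciliation
# criteria. They never call the package's scoring formulas: costs are
# computed from first principles by enumerating every valid reconciliation
# map (each gene node mapped to a species node at or above the LCA of its
# children's images) and minimizing each objective over the maps.

# structural description of a rooted tree, in ape node ids
tree_struct <- function(phy) {
  m <- ape::Ntip(phy) + ape::Nnode(phy)
  parent <- rep(NA_integer_, m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  kids <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  clades <- vector("list", m)
  clades[seq_len(ape::Ntip(phy))] <- as.list(phy$tip.label)
  e <- stats::reorder(phy, "postorder")$edge
  for (v in unique(c(e[, 2], e[nrow(e), 1]))) {
    if (v > ape::Ntip(phy)) clades[[v]] <- unlist(clades[kids[[v]]])
  }
  anc <- matrix(FALSE, m, m)  # anc[a, b]: a is ancestor-or-equal of b
  for (b in seq_len(m)) {
    a <- b
    while (!is.na(a)) {
      anc[a, b] <- TRUE
      a <- parent[a]
    }
  }
  depth <- integer(m)
  ord <- ape::Ntip(phy) + 1L
  # depths by walking down from the root
  walk <- c(ape::Ntip(phy) + 1L)
  while (length(walk)) {
    v <- walk[1]; walk <- walk[-1]
    for (u in kids[[v]]) {
      depth[u] <- depth[v] + 1L
      walk <- c(walk, u)
    }
  }
  lca <- matrix(0L, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    cands <- which(anc[, a] & anc[, b])
    lca[a, b] <- cands[which.max(depth[cands])]
  }
  list(
    ntip = ape::Ntip(phy), m = m, parent = parent, kids = kids,
    clades = clades, anc = anc, depth = depth, lca = lca,
    root = ape::Ntip(phy) + 1L, tips = phy$tip.label
  )
}

# Enumerate all valid maps and return component-wise minima of the three
# criteria. `species` and `gene` are rooted binary phylo objects on the same
# leaf set.
oracle_reconcile <- function(species, gene) {
  S <- tree_struct(species)
  G <- tree_struct(gene)
  leaf_img <- match(G$tips, S$tips)  # gene tip i -> species node
  g_int <- setdiff(seq_len(G$m), seq_len(G$ntip))
  # static LCA of each gene node's leaf set in the species tree
  static_lca <- integer(G$m)
  static_lca[seq_len(G$ntip)] <- leaf_img
  for (v in g_int[order(-G$depth[g_int])]) {
    ch <- G$kids[[v]]
    l <- static_lca[ch[1]]
    for (c2 in ch[-1]) l <- S$lca[l, static_lca[c2]]
    static_lca[v] <- l
  }
  cand <- lapply(g_int, function(v) which(S$anc[, static_lca[v]]))
  combos <- as.matrix(expand.grid(cand))
  nmaps <- nrow(combos)
  # full map matrix: combos x gene nodes
  M <- matrix(0L, nmaps, G$m)
  for (i in seq_len(G$ntip)) M[, i] <- leaf_img[i]
  for (j in seq_along(g_int)) M[, g_int[j]] <- combos[, j]
  valid <- rep(TRUE, nmaps)
  for (v in g_int) {
    for (ch in G$kids[[v]]) {
      valid <- valid & S$anc[cbind(M[, v], M[, ch])]
    }
  }
  M <- M[valid, , drop = FALSE]
  nmaps <- nrow(M)
  dup_tot <- integer(nmaps)
  loss_tot <- integer(nmaps)
  for (v in g_int) {
    c1 <- G$kids[[v]][1]; c2 <- G$kids[[v]][2]
    lcac <- S$lca[cbind(M[, c1], M[, c2])]
    spec <- (M[, v] == lcac) & (M[, c1] != M[, v]) & (M[, c2] != M[, v])
    dup_tot <- dup_tot + as.integer(!spec)
    loss_tot <- loss_tot +
      (S$depth[M[, c1]] - S$depth[M[, v]]) +
      (S$depth[M[, c2]] - S$depth[M[, v]]) - 2L * as.integer(spec)
  }
  # deep coalescences: lineage occupancy of each internal species branch
  s_int <- setdiff(seq.int(S$ntip + 1L, S$m), S$root)
  dc_tot <- integer(nmaps)
  g_nonroot <- setdiff(seq_len(G$m), G$root)
  for (s in s_int) {
    occ <- integer(nmaps)
    for (u in g_nonroot) {
      occ <- occ + as.integer(S$anc[s, M[, u]] & !S$anc[s, M[, G$parent[u]]])
    }
    occ <- occ + as.integer(S$anc[s, M[, G$root]])
    dc_tot <- dc_tot + (occ - 1L)
  }
  list(
    dup = min(dup_tot), loss = min(loss_tot),
    duploss = min(dup_tot + loss_tot), dc = min(dc_tot)
  )
}

# expand a multiPhylo into a plain list of phylo (restores shared tip labels)
as_tree_list <- function(trees) lapply(seq_along(trees), function(i) trees[[i]])

# exhaustive minimum of a criterion over all rooted binary species trees
oracle_best_species_score <- function(gene_trees, criterion,
                                      refinement_limit = 20000) {
  leaves <- sort(gene_trees[[1]]$tip.label)
  cands <- as_tree_list(phangorn::allTrees(length(leaves), rooted = TRUE, tip.label = leaves))
  score_one <- function(sp) {
    sum(vapply(gene_trees, function(g) {
      if (criterion == "mdc") {
        if (ape::is.rooted(g)) {
          mdc_score(sp, g, refinement_limit)
        } else {
          mdc_score_unrooted(sp, g, refinement_limit)
        }
      } else {
        gs <- if (ape::is.rooted(g)) list(g) else all_rootings(g)
        min(vapply(gs, function(r) {
          sc <- dup_loss_score(sp, r)
          if (criterion == "dup") sc$duplications else sc$duplications + sc$losses
        }, integer(1)))
      }
    }, integer(1)))
  }
  min(vapply(cands, score_one, integer(1)))
}

# random rooted binary tree on a label set
random_rooted <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels), br = NULL)
}

# random unrooted binary tree on a label set
random_unrooted <- function(labels) {
  ape::unroot(random_rooted(labels))
}

all_rooted_trees <- function(labels) {
  as_tree_list(phangorn::allTrees(length(labels), rooted = TRUE, tip.label = sort(labels)))
}

all_unrooted_trees <- function(labels) {
  as_tree_list(phangorn::allTrees(length(labels), rooted = FALSE, tip.label = sort(labels)))
}

combn_list_sides <- function(leaves, k) utils::combn(leaves, k, simplify = FALSE)

# brute-force split-set displayability: some binary unrooted tree on the
# leaf set displays all the splits
oracle_jointly_displayable <- function(sides, leaves) {
  cands <- all_unrooted_trees(leaves)
  keys <- vapply(sides, faststree:::split_key, character(1), leaves = sort(leaves))
  any(vapply(cands, function(tr) all(keys %in% bipartitions(tr)), logical(1)))
}
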