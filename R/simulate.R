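# ---------------------------------------------------------------------------
# Synthetic-data generator: birth-death species trees, multispecies-coalescent
# (MSC) gene trees within a species tree, branch-length perturbation for the
# no-ILS protocol, and sequence evolution under GTR+Gamma with insertions and
# deletions, tracking true alignment homology.
#
# Unit conventions: species-tree branch lengths entering the MSC are in
# coalescent units (2N generations), so a pair of lineages coalesces at rate
# 1 and k lineages at rate k(k-1)/2. Sequence evolution interprets branch
# lengths as expected substitutions per site; `subst_scale` converts.
# ---------------------------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

#' GTR+Gamma(+I) substitution model
#'
#' Builds a general time reversible rate matrix from exchangeabilities and
#' base frequencies, normalized to one expected substitution per unit time,
#' with continuous gamma rate heterogeneity across sites and an optional
#' proportion of invariant sites.
#'
#' @param exchangeabilities Six nonnegative rates in the order AC, AG, AT, CG,
#'   CT, GT.
#' @param base_frequencies Four positive frequencies (A, C, G, T) summing to 1.
#' @param gamma_shape Shape of the mean-1 gamma rate distribution; `Inf`
#'   disables rate heterogeneity.
#' @param invariant_proportion Proportion of sites with rate 0, in \[0, 1).
#' @param preset `"JC"` for the Jukes-Cantor special case (equal rates, equal
#'   frequencies, no rate heterogeneity).
#' @return A list of class `substitution_model` carrying the normalized rate
#'   matrix and its eigendecomposition.
#' @export
substitution_model <- function(exchangeabilities = rep(1, 6),
                               base_frequencies = rep(0.25, 4),
                               gamma_shape = 1,
                               invariant_proportion = 0,
                               preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "JC")
    exchangeabilities <- rep(1, 6)
    base_frequencies <- rep(0.25, 4)
    gamma_shape <- Inf
    invariant_proportion <- 0
  }
  if (length(exchangeabilities) != 6 || any(exchangeabilities < 0)) {
    abort("need 6 nonnegative exchangeabilities (AC, AG, AT, CG, CT, GT)")
  }
  if (length(base_frequencies) != 4 || any(base_frequencies <= 0)) {
    abort("need 4 positive base frequencies")
  }
  if (abs(sum(base_frequencies) - 1) > 1e-8) abort("base frequencies must sum to 1")
  if (gamma_shape <= 0) abort("gamma_shape must be positive")
  if (invariant_proportion < 0 || invariant_proportion >= 1) {
    abort("invariant_proportion must be in [0, 1)")
  }
  pi <- base_frequencies / sum(base_frequencies)
  R <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  R[upper.tri(R)] <- exchangeabilities
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # reversibility makes D^{1/2} Q D^{-1/2} symmetric: real eigensystem
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(
    list(
      exchangeabilities = exchangeabilities,
      base_frequencies = pi,
      gamma_shape = gamma_shape,
      invariant_proportion = invariant_proportion,
      Q = Q,
      eigenvalues = es$values,
      V = diag(1 / sq) %*% es$vectors,
      Vinv = t(es$vectors) %*% diag(sq)
    ),
    class = "substitution_model"
  )
}

#' Indel model for sequence simulation
#'
#' Insertions and deletions occur as Poisson processes along each branch at
#' the given per-site, per-substitution-unit rates; event lengths follow a
#' truncated geometric distribution (or an explicit probability vector over
#' `1..max_length`).
#'
#' @param insertion_rate,deletion_rate Events per site per unit branch length.
#' @param length_p Geometric parameter for event lengths (ignored when
#'   `length_probs` is given).
#' @param length_probs Optional explicit probability vector over lengths
#'   `1..max_length`.
#' @param max_length Maximum indel length.
#' @return List of class `indel_model`.
#' @export
indel_model <- function(insertion_rate = 0.01, deletion_rate = 0.01,
                        length_p = 0.3, length_probs = NULL, max_length = 10L) {
  if (insertion_rate < 0 || deletion_rate < 0) abort("indel rates must be >= 0")
  if (max_length < 1) abort("max_length must be >= 1")
  if (is.null(length_probs)) {
    length_probs <- length_p * (1 - length_p)^(seq_len(max_length) - 1)
  }
  if (length(length_probs) != max_length || any(length_probs < 0)) {
    abort("length_probs must be nonnegative with one entry per length 1..max_length")
  }
  length_probs <- length_probs / sum(length_probs)
  structure(
    list(
      insertion_rate = insertion_rate,
      deletion_rate = deletion_rate,
      length_probs = length_probs,
      max_length = as.integer(max_length)
    ),
    class = "indel_model"
  )
}

#' Simulate a species tree under a birth-death model
#'
#' Forward birth-death simulation conditioned on the number of extant taxa,
#' yielding an ultrametric rooted binary tree with branch lengths in time
#' units.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param birth,death Speciation and extinction rates; `birth > death >= 0`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Rooted ultrametric `phylo` with tips `t1..tn`.
#' @export
generate_species_tree <- function(n_taxa, birth = 1, death = 0, seed = NULL) {
  if (n_taxa < 4) abort("n_taxa must be >= 4")
  if (!(birth > death && death >= 0)) abort("need birth > death >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  phy <- ape::rphylo(n_taxa, birth = birth, death = death)
  phy$tip.label <- paste0("t", seq_len(n_taxa))
  phy
}

#' Uniformly scale branch lengths
#'
#' @param tree `phylo` with branch lengths.
#' @param factor Positive multiplier.
#' @return The tree with every branch length multiplied by `factor`.
#' @export
scale_branches <- function(tree, factor) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (factor <= 0) abort("factor must be positive")
  tree$edge.length <- tree$edge.length * factor
  tree
}

# ages (time above the tips) of all nodes of an ultrametric rooted tree
node_ages <- function(phy, tol = 1e-8) {
  m <- Ntip(phy) + Nnode(phy)
  depth <- numeric(m)
  kids <- children_map(phy)
  elen <- numeric(m)
  elen[phy$edge[, 2]] <- phy$edge.length
  walk <- function(v, d) {
    depth[v] <<- d
    for (u in kids[[v]]) walk(u, d + elen[u])
  }
  walk(root_node(phy), 0)
  h <- max(depth[seq_len(Ntip(phy))])
  if (any(abs(depth[seq_len(Ntip(phy))] - h) > max(tol, 1e-6 * h))) {
    abort("species tree must be ultrametric for coalescent simulation")
  }
  h - depth
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Runs the coalescent backwards in time within each branch of an ultrametric
#' species tree whose branch lengths are in coalescent units: with `k`
#' lineages present, successive coalescences occur after exponential waiting
#' times with rate `k(k-1)/2`, truncated at the branch end; lineages surviving
#' to the species root coalesce freely above it. One lineage is sampled per
#' species.
#'
#' @param species Rooted ultrametric `phylo`, branch lengths in coalescent
#'   units.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Rooted binary gene tree on the species leaf set, branch lengths in
#'   coalescent units.
#' @export
simulate_msc_gene_tree <- function(species, seed = NULL) {
  stopifnot(inherits(species, "phylo"))
  if (is.null(species$edge.length)) abort("species tree has no branch lengths")
  if (!is.null(seed)) withr::local_seed(seed)
  ages <- node_ages(species)
  kids <- children_map(species)
  ntip <- Ntip(species)

  # a lineage is a list(newick fragment, age of its top)
  coalesce_in_interval <- function(lineages, t_start, t_end) {
    t <- t_start
    while (length(lineages) > 1) {
      k <- length(lineages)
      wait <- stats::rexp(1, rate = k * (k - 1) / 2)
      if (is.finite(t_end) && t + wait > t_end) break
      t <- t + wait
      pair <- sample.int(k, 2)
      a <- lineages[[pair[1]]]
      b <- lineages[[pair[2]]]
      merged <- list(
        nwk = paste0("(", a$nwk, ":", format(t - a$age, digits = 12),
                     ",", b$nwk, ":", format(t - b$age, digits = 12), ")"),
        age = t
      )
      lineages <- c(lineages[-pair], list(merged))
    }
    lineages
  }

  pool_at <- function(v) {
    if (v <= ntip) {
      return(list(list(nwk = species$tip.label[v], age = 0)))
    }
    pool <- list()
    for (u in kids[[v]]) {
      sub <- pool_at(u)
      sub <- coalesce_in_interval(sub, ages[u], ages[v])
      pool <- c(pool, sub)
    }
    pool
  }

  pool <- pool_at(root_node(species))
  pool <- coalesce_in_interval(pool, ages[root_node(species)], Inf)
  read_newick(text = paste0(pool[[1]]$nwk, ";"))
}

#' Multiplicatively perturb branch lengths, preserving total tree length
#'
#' Each branch length is multiplied by an independent positive draw with
#' expectation 1 (lognormal with `meanlog = -sdlog^2/2`), and all lengths are
#' then rescaled by a single constant so the total tree length equals the
#' input's. The topology is unchanged.
#'
#' @param tree `phylo` with branch lengths.
#' @param sdlog Log-scale standard deviation of the lognormal multipliers.
#' @param seed Optional integer seed.
#' @return Perturbed `phylo`.
#' @export
perturb_branch_lengths <- function(tree, sdlog = 0.3, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (!is.null(seed)) withr::local_seed(seed)
  if (sdlog == 0) return(tree)
  mult <- stats::rlnorm(length(tree$edge.length), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  new_len <- tree$edge.length * mult
  tree$edge.length <- new_len * sum(tree$edge.length) / sum(new_len)
  tree
}

# vectorized substitution of integer-coded bases along one branch
substitute_states <- function(states, rates, t, model) {
  if (length(states) == 0 || t == 0) return(states)
  lam <- model$eigenvalues
  E <- exp(outer(rates * t, lam))
  P <- (model$V[states, , drop = FALSE] * E) %*% model$Vinv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  u <- stats::runif(length(states))
  cs1 <- P[, 1]
  cs2 <- cs1 + P[, 2]
  cs3 <- cs2 + P[, 3]
  1L + (u > cs1) + (u > cs2) + (u > cs3)
}

draw_site_rates <- function(n, model) {
  if (n == 0) return(numeric(0))
  r <- if (is.finite(model$gamma_shape)) {
    stats::rgamma(n, shape = model$gamma_shape, rate = model$gamma_shape)
  } else {
    rep(1, n)
  }
  p <- model$invariant_proportion
  if (p > 0) {
    inv <- stats::runif(n) < p
    r[inv] <- 0
    r[!inv] <- r[!inv] / (1 - p)
  }
  r
}

#' Simulate sequences down a gene tree under GTR+Gamma with indels
#'
#' The root sequence is drawn from the model's base frequencies. Along each
#' branch, sites substitute according to `exp(Q t r)` with per-site gamma rate
#' multipliers, and insertion/deletion events occur as Poisson processes at
#' the indel model's rates (event counts use the branch's starting sequence
#' length). Insertions draw fresh residues from the base frequencies and fall
#' uniformly between sites; deletions start uniformly and clip at the
#' sequence end. Homology is tracked exactly, so the true alignment (with `-`
#' for non-homologous positions) is returned alongside the ungapped
#' sequences.
#'
#' @param gene_tree Rooted `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param subst A [substitution_model()].
#' @param indel An [indel_model()]; rates of 0 give gap-free alignments.
#' @param root_length Root sequence length (>= 1).
#' @param seed Optional integer seed.
#' @return List with `alignment` (character matrix, taxa x columns, gaps as
#'   `-`) and `sequences` (named character vector of ungapped sequences).
#' @export
simulate_sequences <- function(gene_tree, subst = substitution_model(),
                               indel = indel_model(), root_length = 1000,
                               seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(subst, "substitution_model"),
            inherits(indel, "indel_model"))
  if (is.null(gene_tree$edge.length)) abort("gene tree has no branch lengths")
  if (root_length < 1) abort("root_length must be >= 1")
  if (!ape::is.rooted(gene_tree)) abort("gene tree must be rooted")
  if (!is.null(seed)) withr::local_seed(seed)

  ntip <- Ntip(gene_tree)
  kids <- children_map(gene_tree)
  elen <- numeric(ntip + Nnode(gene_tree))
  elen[gene_tree$edge[, 2]] <- gene_tree$edge.length

  env <- new.env(parent = emptyenv())
  env$order <- seq_len(root_length)   # global column order (by column id)
  env$next_id <- root_length + 1L
  env$leaf_states <- list()

  root_state <- list(
    chars = sample.int(4L, root_length, replace = TRUE, prob = subst$base_frequencies),
    ids = seq_len(root_length),
    rates = draw_site_rates(root_length, subst)
  )

  evolve_branch <- function(state, t) {
    state$chars <- substitute_states(state$chars, state$rates, t, subst)
    L0 <- length(state$chars)
    n_ins <- stats::rpois(1, indel$insertion_rate * t * L0)
    n_del <- stats::rpois(1, indel$deletion_rate * t * L0)
    events <- sample(c(rep("I", n_ins), rep("D", n_del)))
    for (ev in events) {
      L <- length(state$chars)
      len <- sample.int(indel$max_length, 1, prob = indel$length_probs)
      if (ev == "I") {
        pos <- sample.int(L + 1L, 1) - 1L            # insert after position pos
        new_ids <- seq.int(env$next_id, length.out = len)
        env$next_id <- env$next_id + len
        anchor <- if (pos == 0L) {
          if (L == 0L) length(env$order) else match(state$ids[1], env$order) - 1L
        } else {
          match(state$ids[pos], env$order)
        }
        env$order <- append(env$order, new_ids, after = anchor)
        state$chars <- append(state$chars,
                              sample.int(4L, len, replace = TRUE,
                                         prob = subst$base_frequencies),
                              after = pos)
        state$ids <- append(state$ids, new_ids, after = pos)
        state$rates <- append(state$rates, draw_site_rates(len, subst), after = pos)
      } else {
        if (L == 0L) next
        start <- sample.int(L, 1)
        drop <- seq.int(start, min(L, start + len - 1L))
        state$chars <- state$chars[-drop]
        state$ids <- state$ids[-drop]
        state$rates <- state$rates[-drop]
      }
    }
    state
  }

  walk <- function(v, state) {
    if (v <= ntip) {
      env$leaf_states[[gene_tree$tip.label[v]]] <- state
      return(invisible(NULL))
    }
    for (u in kids[[v]]) {
      walk(u, evolve_branch(state, elen[u]))
    }
  }
  walk(root_node(gene_tree), root_state)

  taxa <- sort(gene_tree$tip.label)
  used <- sort(unique(unlist(lapply(env$leaf_states, `[[`, "ids"))))
  cols <- env$order[env$order %in% used]
  aln <- matrix("-", nrow = length(taxa), ncol = length(cols),
                dimnames = list(taxa, NULL))
  for (tx in taxa) {
    st <- env$leaf_states[[tx]]
    aln[tx, match(st$ids, cols)] <- DNA_BASES[st$chars]
  }
  list(
    alignment = aln,
    sequences = stats::setNames(
      vapply(taxa, function(tx) {
        paste(DNA_BASES[env$leaf_states[[tx]]$chars], collapse = "")
      }, character(1)),
      taxa
    )
  )
}

#' Experiment configuration for [generate_dataset()]
#'
#' Bundles the parameters of the two simulation protocols: coalescent gene
#' trees within a branch-scaled species tree (`mode = "ILS"`), or
#' topologically identical gene trees with mean-1 multiplicatively perturbed
#' branch lengths (`mode = "noILS"`), each followed by sequence evolution with
#' substitutions and indels from a root sequence of length `root_length`.
#'
#' @param n_taxa Number of species (>= 4).
#' @param n_genes Number of genes (>= 1).
#' @param mode `"ILS"` or `"noILS"`.
#' @param root_length Root sequence length (default 1000).
#' @param branch_scale Uniform scaling applied to the species tree before
#'   coalescent simulation (default 0.05; small values shorten branches in
#'   coalescent units and hence intensify incomplete lineage sorting).
#' @param birth,death Birth-death parameters of the species tree.
#' @param subst_scale Multiplier converting gene-tree branch lengths to
#'   expected substitutions per site for sequence simulation.
#' @param perturbation_sd Lognormal `sdlog` of the no-ILS branch multipliers.
#' @param subst,indel Model objects; see [substitution_model()] and
#'   [indel_model()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_taxa = 100, n_genes = 25,
                              mode = c("ILS", "noILS"),
                              root_length = 1000,
                              branch_scale = 0.05,
                              birth = 1, death = 0,
                              subst_scale = 1,
                              perturbation_sd = 0.3,
                              subst = substitution_model(),
                              indel = indel_model(),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (n_taxa < 4) abort("n_taxa must be >= 4")
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (root_length < 1) abort("root_length must be >= 1")
  if (branch_scale <= 0) abort("branch_scale must be positive")
  structure(
    list(
      n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes), mode = mode,
      root_length = as.integer(root_length), branch_scale = branch_scale,
      birth = birth, death = death, subst_scale = subst_scale,
      perturbation_sd = perturbation_sd, subst = subst, indel = indel,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Generate a full synthetic dataset
#'
#' Simulates a species tree and, depending on the mode, either coalescent gene
#' trees within the branch-scaled species tree (ILS) or gene trees identical
#' in topology to the species tree, half with its branch lengths verbatim and
#' half perturbed (no ILS). Optionally evolves sequences (with true
#' alignments) down each gene tree.
#'
#' @param config An [experiment_config()].
#' @param with_sequences Simulate sequences too? Set `FALSE` when only gene
#'   trees are needed.
#' @return List with `species_tree`, `gene_trees` (coalescent-unit lengths in
#'   ILS mode), `alignments`, `sequences`, and the `config`.
#' @export
generate_dataset <- function(config, with_sequences = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  withr::local_seed(config$seed)
  species <- generate_species_tree(config$n_taxa, config$birth, config$death)
  if (config$mode == "ILS") {
    scaled <- scale_branches(species, config$branch_scale)
    gene_trees <- lapply(seq_len(config$n_genes), function(i) {
      simulate_msc_gene_tree(scaled)
    })
    species_out <- scaled
  } else {
    half <- ceiling(config$n_genes / 2)
    gene_trees <- lapply(seq_len(config$n_genes), function(i) {
      if (i <= half) species else perturb_branch_lengths(species, config$perturbation_sd)
    })
    species_out <- species
  }
  alignments <- NULL
  sequences <- NULL
  if (with_sequences) {
    sims <- lapply(gene_trees, function(g) {
      simulate_sequences(
        scale_branches(g, config$subst_scale),
        subst = config$subst, indel = config$indel,
        root_length = config$root_length
      )
    })
    alignments <- lapply(sims, `[[`, "alignment")
    sequences <- lapply(sims, `[[`, "sequences")
  }
  list(
    species_tree = species_out,
    gene_trees = gene_trees,
    alignments = alignments,
    sequences = sequences,
    config = config
  )
}

#' Write a dataset bundle to a directory
#'
#' Writes the species tree and gene trees (Newick), true alignments and
#' unaligned sequences (FASTA), and a plain-text manifest recording the
#' configuration and seed.
#'
#' @param dataset A bundle from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$species_tree, file.path(dir, "species.nwk"))
  writeLines(
    vapply(dataset$gene_trees, write_newick, character(1)),
    file.path(dir, "gene_trees.nwk")
  )
  if (!is.null(dataset$alignments)) {
    for (i in seq_along(dataset$alignments)) {
      aln <- dataset$alignments[[i]]
      write_fasta(
        stats::setNames(apply(aln, 1, paste, collapse = ""), rownames(aln)),
        file.path(dir, sprintf("gene%03d_true_aln.fasta", i))
      )
      write_fasta(dataset$sequences[[i]],
                  file.path(dir, sprintf("gene%03d.fasta", i)))
    }
  }
  cfg <- dataset$config
  manifest <- c(
    sprintf("n_taxa=%d", cfg$n_taxa), sprintf("n_genes=%d", cfg$n_genes),
    sprintf("mode=%s", cfg$mode), sprintf("root_length=%d", cfg$root_length),
    sprintf("branch_scale=%g", cfg$branch_scale),
    sprintf("subst_scale=%g", cfg$subst_scale),
    sprintf("perturbation_sd=%g", cfg$perturbation_sd),
    sprintf("seed=%d", cfg$seed)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param file Output path.
#' @export
write_fasta <- function(sequences, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(c(paste0(">", nm), sequences[[nm]]), con)
  }
  invisible(file)
}

#' Read a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of sequences (uppercased).
#' @export
read_fasta <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a FASTA file: no '>' headers")
  idx <- cumsum(hdr)
  names <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  stats::setNames(toupper(unname(seqs)), names)
}
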