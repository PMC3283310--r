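test_that("birth-death species trees are ultrametric binary with n leaves", {
  tr <- generate_species_tree(4, seed = 1)
  expect_equal(ape::Ntip(tr), 4)
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))
  expect_identical(write_newick(generate_species_tree(7, seed = 3)),
                   write_newick(generate_species_tree(7, seed = 3)))
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tr <- generate_species_tree(n)
    expect_equal(ape::Ntip(tr), n)
    ages <- faststree:::node_ages(tr)   # errors if not ultrametric
    expect_true(all(ages >= 0))
  }
  expect_error(generate_species_tree(3), "n_taxa")
  expect_error(generate_species_tree(5, birth = 1, death = 2), "birth")
})

test_that("branch scaling multiplies every length", {
  tr <- generate_species_tree(6, seed = 2)
  s <- scale_branches(tr, 0.05)
  expect_equal(s$edge.length, tr$edge.length * 0.05)
  expect_equal(sum(scale_branches(tr, 1)$edge.length), sum(tr$edge.length))
  expect_error(scale_branches(star_tree(LETTERS[1:4]), 2), "lengths")
})

test_that("two-species coalescence time is the divergence plus an Exp(1) draw", {
  tau <- 1.5
  sp <- read_newick(sprintf("(A:%g,B:%g);", tau, tau))
  set.seed(72)
  depths <- replicate(3000, {
    g <- simulate_msc_gene_tree(sp)
    stats::cophenetic(g)["A", "B"] / 2
  })
  expect_true(all(depths >= tau))
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - (tau + 1)), 3 * se)
})

test_that("three-species concordance matches 1 - (2/3) e^{-T} at moderate T", {
  T <- 1
  sp <- read_newick(sprintf("((A:1,B:1):%g,C:%g);", T, 1 + T))
  set.seed(73)
  n <- 4000
  hits <- sum(replicate(n, {
    ape::is.monophyletic(simulate_msc_gene_tree(sp), c("A", "B"))
  }))
  p_theory <- 1 - (2 / 3) * exp(-T)
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(hits / n - p_theory), 3 * se)
})

test_that("coalescences never predate speciations", {
  sp <- generate_species_tree(6, seed = 5)
  sp <- scale_branches(sp, 0.5)
  ages_sp <- faststree:::node_ages(sp)
  clades_sp <- faststree:::node_clades(sp)
  set.seed(74)
  for (i in 1:20) {
    g <- simulate_msc_gene_tree(sp)
    ages_g <- faststree:::node_ages(g)
    clades_g <- faststree:::node_clades(g)
    for (v in seq.int(ape::Ntip(sp) + 1L, ape::Ntip(sp) + ape::Nnode(sp))) {
      cl <- clades_sp[[v]]
      # age of the gene LCA of this species clade
      containing <- which(vapply(clades_g, function(x) all(cl %in% x), logical(1)))
      lca_age <- min(ages_g[containing])
      expect_gte(lca_age, ages_sp[v] - 1e-9)
    }
  }
})

test_that("branch perturbation preserves topology and total tree length", {
  tr <- generate_species_tree(8, seed = 6)
  out <- perturb_branch_lengths(tr, sdlog = 0.4, seed = 7)
  expect_equal(sum(out$edge.length), sum(tr$edge.length))
  expect_equal(rf_distance(out, tr), 0L)
  expect_false(isTRUE(all.equal(out$edge.length, tr$edge.length)))
  # degenerate distribution: identity
  expect_equal(perturb_branch_lengths(tr, sdlog = 0)$edge.length, tr$edge.length)
  set.seed(75)
  for (i in 1:20) {
    expect_equal(rf_distance(perturb_branch_lengths(tr, 0.6), tr), 0L)
  }
})

test_that("without indels the alignment is gap-free with the root length", {
  g <- read_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  sim <- simulate_sequences(g, substitution_model(preset = "JC"),
                            indel_model(0, 0), root_length = 500, seed = 8)
  expect_equal(dim(sim$alignment), c(4L, 500L))
  expect_false(any(sim$alignment == "-"))
  expect_equal(unname(nchar(sim$sequences)), rep(500L, 4))
})

test_that("indel simulation keeps homology consistent and emits no all-gap columns", {
  g <- read_newick("((A:0.5,B:0.5):0.2,(C:0.5,D:0.5):0.2);")
  sim <- simulate_sequences(g, substitution_model(preset = "JC"),
                            indel_model(0.02, 0.02), root_length = 300, seed = 9)
  aln <- sim$alignment
  expect_true(any(aln == "-"))
  expect_true(all(colSums(aln != "-") >= 1))
  # stripping gaps reproduces the unaligned sequences
  for (tx in rownames(aln)) {
    expect_identical(paste(aln[tx, aln[tx, ] != "-"], collapse = ""),
                     unname(sim$sequences[tx]))
  }
})

test_that("Jukes-Cantor divergence matches the closed form", {
  t <- 0.5
  p_expected <- 0.75 * (1 - exp(-4 * t / 3))
  g <- read_newick(sprintf("(A:%g,B:0);", t))
  set.seed(10)
  sim <- simulate_sequences(g, substitution_model(preset = "JC"),
                            indel_model(0, 0), root_length = 100000)
  p_obs <- mean(sim$alignment["A", ] != sim$alignment["B", ])
  se <- sqrt(p_expected * (1 - p_expected) / 100000)
  expect_lt(abs(p_obs - p_expected), 3 * se)
})

test_that("base composition converges to the stationary frequencies", {
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  m <- substitution_model(exchangeabilities = c(1, 2, 1, 1, 2, 1),
                          base_frequencies = freqs, gamma_shape = Inf)
  g <- read_newick("(A:20,B:20);")
  set.seed(11)
  sim <- simulate_sequences(g, m, indel_model(0, 0), root_length = 5000)
  obs <- table(factor(sim$alignment["A", ], levels = c("A", "C", "G", "T"))) / 5000
  for (i in 1:4) {
    se <- sqrt(freqs[i] * (1 - freqs[i]) / 5000)
    expect_lt(abs(obs[i] - freqs[i]), 4 * se)
  }
})

test_that("model constructors validate their inputs", {
  expect_error(substitution_model(base_frequencies = c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
  expect_error(substitution_model(exchangeabilities = rep(-1, 6)), "nonnegative")
  expect_error(substitution_model(gamma_shape = 0), "positive")
  expect_error(indel_model(-0.1, 0), "rates")
  expect_error(indel_model(length_probs = c(0.5, 0.5), max_length = 3), "length_probs")
  m <- substitution_model()
  expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(m$base_frequencies * diag(m$Q)), 1, tolerance = 1e-12)
})

test_that("no-ILS datasets have topologically identical gene trees; bundles are reproducible", {
  cfg <- experiment_config(n_taxa = 8, n_genes = 6, mode = "noILS",
                           root_length = 50, seed = 12)
  ds <- generate_dataset(cfg, with_sequences = FALSE)
  for (g in ds$gene_trees) {
    expect_equal(rf_distance(g, ds$species_tree), 0L)
  }
  # half verbatim, half perturbed
  same <- vapply(ds$gene_trees, function(g) {
    isTRUE(all.equal(sort(g$edge.length), sort(ds$species_tree$edge.length)))
  }, logical(1))
  expect_equal(sum(same), 3L)

  cfg2 <- experiment_config(n_taxa = 6, n_genes = 2, mode = "ILS",
                            root_length = 60, seed = 13)
  d1 <- generate_dataset(cfg2)
  d2 <- generate_dataset(cfg2)
  expect_identical(lapply(d1$gene_trees, write_newick), lapply(d2$gene_trees, write_newick))
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(d1$sequences, d2$sequences)
})

test_that("dataset bundles round-trip through disk", {
  cfg <- experiment_config(n_taxa = 6, n_genes = 2, mode = "ILS",
                           root_length = 40, seed = 14)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "species.nwk")))
  trees <- read_newick_lines(file.path(dir, "gene_trees.nwk"))
  expect_length(trees, 2)
  expect_equal(rf_distance(trees[[1]], ds$gene_trees[[1]]), 0L)
  fa <- read_fasta(file.path(dir, "gene001.fasta"))
  expect_identical(unname(fa), unname(ds$sequences[[1]]))
  expect_true(any(grepl("seed=14", readLines(file.path(dir, "manifest.txt")))))
})
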