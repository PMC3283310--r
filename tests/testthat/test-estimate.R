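test_that("logdet distance is zero for identical sequences and symmetric", {
  aln <- c(A = "ACGTACGTAC", B = "ACGTACGTAC", C = "ACGTAAGTAC")
  d <- logdet_distance(aln)
  expect_equal(d["A", "B"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
})

test_that("logdet handles gaps by pairwise deletion and flags saturation", {
  aln <- c(A = "ACGT-CGTAC", B = "ACGTAC-TAC", C = "TGCAGTACGT")
  d <- suppressWarnings(logdet_distance(aln))
  expect_true(all(d >= 0))
  # fully divergent short pair: saturated, capped with a warning
  expect_warning(logdet_distance(c(A = "AAAA", B = "CCCC")), "capped")
  expect_error(logdet_distance(c(A = "AC--", B = "--GT")), "comparable")
})

test_that("logdet is consistent under Jukes-Cantor evolution", {
  t <- 0.3
  g <- read_newick(sprintf("(A:%g,B:0);", t))
  set.seed(81)
  sim <- simulate_sequences(g, substitution_model(preset = "JC"),
                            indel_model(0, 0), root_length = 100000)
  d <- logdet_distance(sim$alignment)
  expect_lt(abs(d["A", "B"] - t) / t, 0.02)
  # agrees with the reference implementation in ape
  dnb <- ape::as.DNAbin(tolower(sim$alignment))
  ref <- as.matrix(ape::dist.dna(dnb, model = "logdet", pairwise.deletion = TRUE))
  expect_equal(d["A", "B"], ref["A", "B"], tolerance = 1e-3)
})

test_that("path distances and NJ invert each other on additive inputs", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(tree_path_distances(tr)["A", "B"], 3)
  set.seed(82)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    src <- ape::rtree(n, tip.label = paste0("s", 1:n))
    src$edge.length <- stats::runif(nrow(src$edge), 0.1, 1)
    est <- nj_tree(tree_path_distances(src))
    expect_equal(rf_distance(est, src), 0L)
    expect_true(all(est$edge.length >= 0))
  }
  # ultrametric source gives an ultrametric matrix
  um <- generate_species_tree(6, seed = 83)
  d <- tree_path_distances(um)
  trip <- utils::combn(rownames(d), 3)
  for (k in seq_len(ncol(trip))) {
    v <- sort(c(d[trip[1, k], trip[2, k]], d[trip[1, k], trip[3, k]],
                d[trip[2, k], trip[3, k]]), decreasing = TRUE)
    expect_lt(v[1] - v[2], 1e-8)
  }
})

test_that("nj output is invariant to taxon order", {
  set.seed(84)
  src <- ape::rtree(7, tip.label = paste0("s", 1:7))
  src$edge.length <- stats::runif(nrow(src$edge), 0.1, 1)
  d <- tree_path_distances(src)
  perm <- sample(rownames(d))
  expect_equal(rf_distance(nj_tree(d), nj_tree(d[perm, perm])), 0L)
  expect_error(nj_tree(d[1:3, 1:3]), ">= 4")
})

test_that("bootstrap supports are reproducible, bounded, and high for clean signal", {
  src <- read_newick("(((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2):0.1,(E:0.3,F:0.3):0.2);")
  set.seed(85)
  sim <- simulate_sequences(src, substitution_model(preset = "JC"),
                            indel_model(0, 0), root_length = 10000)
  bt1 <- bootstrap_support(sim$alignment, replicates = 50, seed = 42)
  bt2 <- bootstrap_support(sim$alignment, replicates = 50, seed = 42)
  expect_identical(bt1$node.label, bt2$node.label)
  supp <- faststree:::split_supports(bt1)
  expect_true(all(supp >= 0 & supp <= 1))
  expect_true(all(supp >= 0.95))
  expect_equal(rf_distance(bt1, src), 0L)
})

test_that("point estimates summarize tree samples", {
  t1 <- read_newick("((A,B),(C,D),E);")
  t2 <- read_newick("((A,C),(B,D),E);")
  expect_equal(rf_distance(point_estimates(list(t1), "majority"), t1), 0L)
  expect_equal(rf_distance(point_estimates(list(t1), "map"), t1), 0L)
  # 60/40: MAP is the modal topology
  smp <- c(rep(list(t1), 3), rep(list(t2), 2))
  expect_equal(rf_distance(point_estimates(smp, "map"), t1), 0L)
  # 50/50 split: majority consensus drops the contested splits
  half <- c(rep(list(t1), 2), rep(list(t2), 2))
  expect_length(bipartitions(point_estimates(half, "majority")), 0)
  expect_error(point_estimates(list(), "map"), "empty")
})
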