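test_that("LCA mapping sends leaves to leaves, the root to the LCA, and is monotone", {
  sp <- read_newick("(((A,B),C),(D,E));")
  g <- read_newick("((A,D),B);")
  M <- lca_mapping(g, sp)
  expect_equal(M[match("A", g$tip.label)], match("A", sp$tip.label))
  # gene root maps to species LCA of {A, B, D} = species root
  expect_equal(M[ape::Ntip(g) + 1L], ape::Ntip(sp) + 1L)
  expect_error(lca_mapping(ape::unroot(read_newick("((A,B),(C,D));")), sp), "rooted")

  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    labs <- paste0("s", 1:n)
    sp_i <- random_rooted(labs)
    g_i <- random_rooted(labs)
    M <- lca_mapping(g_i, sp_i)
    S <- tree_struct(sp_i)
    for (e in seq_len(nrow(g_i$edge))) {
      p <- g_i$edge[e, 1]; ch <- g_i$edge[e, 2]
      expect_true(S$anc[M[p], M[ch]])  # parent image at or above child image
    }
  }
})

test_that("mdc_score matches known small cases and rejects unrooted genes", {
  sp <- read_newick("((A,B),C);")
  expect_equal(mdc_score(sp, sp), 0L)
  expect_equal(mdc_score(sp, read_newick("((A,C),B);")), 1L)
  set.seed(52)
  tr <- random_rooted(paste0("s", 1:6))
  expect_equal(mdc_score(tr, tr), 0L)
  expect_error(mdc_score(sp, ape::unroot(read_newick("((A,B),(C,D));"))), "unrooted")
})

test_that("reconciliation scores equal the brute-force map-enumeration oracle (n = 4)", {
  labs <- LETTERS[1:4]
  cands <- all_rooted_trees(labs)
  for (sp in cands) {
    for (g in cands) {
      o <- oracle_reconcile(sp, g)
      expect_identical(mdc_score(sp, g), as.integer(o$dc))
      dl <- dup_loss_score(sp, g)
      expect_identical(dl$duplications, as.integer(o$dup))
      expect_identical(dl$losses, as.integer(o$loss))
    }
  }
})

test_that("extra lineages equal losses minus twice duplications (shared leaf set)", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    labs <- paste0("s", 1:n)
    sp <- random_rooted(labs)
    g <- random_rooted(labs)
    dl <- dup_loss_score(sp, g)
    expect_identical(dl$extra_lineages, dl$losses - 2L * dl$duplications)
    expect_identical(dl$extra_lineages, mdc_score(sp, g))
  }
})

test_that("dup_loss_score requires resolved rooted inputs", {
  sp <- read_newick("((A,B),(C,D));")
  expect_error(dup_loss_score(sp, read_newick("(A,B,(C,D));")), "resolved")
  expect_error(dup_loss_score(read_newick("(A,B,(C,D));"), sp), "resolved")
  dl <- dup_loss_score(sp, sp)
  expect_identical(dl$duplications, 0L)
  expect_identical(dl$losses, 0L)
})

test_that("constrained MDC minimizes over rootings and refinements", {
  sp <- read_newick("(((A,B),C),(D,E));")
  # a resolved unrooted gene tree that admits a zero-cost rooting
  g <- ape::unroot(read_newick("(((A,B),C),(D,E));"))
  expect_equal(mdc_score_unrooted(sp, g), 0L)
  # full refinement freedom: star gene tree costs 0 against any species tree
  set.seed(54)
  for (i in 1:5) {
    spr <- random_rooted(LETTERS[1:5])
    expect_equal(mdc_score_unrooted(spr, star_tree(LETTERS[1:5])), 0L)
  }
})

test_that("constrained MDC equals brute force over displayed binary trees (5 taxa)", {
  labs <- LETTERS[1:5]
  binaries <- all_unrooted_trees(labs)
  set.seed(55)
  genes <- list(
    random_unrooted(labs),                         # resolved
    read_newick("((A,B),C,D,E);"),                 # one polytomy
    read_newick("((A,B),(C,D),E);"),               # unrooted caterpillar-ish
    star_tree(labs)                                # fully unresolved
  )
  species <- lapply(1:6, function(i) random_rooted(labs))
  for (sp in species) {
    for (g in genes) {
      gk <- bipartitions(g)
      displayed <- Filter(function(b) all(gk %in% bipartitions(b)), binaries)
      oracle <- min(vapply(displayed, function(b) {
        min(vapply(all_rootings(b), function(r) oracle_reconcile(sp, r)$dc, numeric(1)))
      }, numeric(1)))
      expect_identical(mdc_score_unrooted(sp, g), as.integer(oracle))
    }
  }
})

test_that("refinement enumeration is guarded against large polytomies", {
  labs <- paste0("s", 1:12)
  sp <- random_rooted(labs)
  expect_error(mdc_score_unrooted(sp, star_tree(labs)), "enumeration limit")
})
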