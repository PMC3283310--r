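test_that("Newick parsing reads lengths, supports and multifurcations", {
  t1 <- read_newick("((A:1,B:1):0.5,C:1.5);")
  expect_s3_class(t1, "phylo")
  expect_setequal(t1$tip.label, c("A", "B", "C"))
  expect_equal(sort(t1$edge.length), c(0.5, 1, 1, 1.5))

  star <- read_newick("(A,B,C);")
  expect_equal(ape::Nnode(star), 1)
  expect_length(bipartitions(star), 0)

  t2 <- read_newick("((A,B)0.9,(C,D)0.4);")
  expect_setequal(setdiff(t2$node.label, ""), c("0.9", "0.4"))

  # percentage-scale supports are normalized to [0, 1]
  t3 <- read_newick("((A,B)90,(C,D)40);")
  expect_setequal(setdiff(t3$node.label, ""), c("0.9", "0.4"))
})

test_that("malformed or invalid Newick is rejected with a useful message", {
  expect_error(read_newick("((A,B),C;"), "unclosed")
  expect_error(read_newick("(A,B)),C;"), "character 6")
  expect_error(read_newick("((A,B),A);"), "duplicate")
})

test_that("Newick round-trips are isomorphic (random trees)", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, tip.label = paste0("s", sample(n)))
    tr2 <- read_newick(write_newick(tr))
    expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
    expect_setequal(as.character(bipartitions(tr2)), as.character(bipartitions(tr)))
    expect_equal(stats::cophenetic(tr2)[tr$tip.label, tr$tip.label],
                 stats::cophenetic(tr), tolerance = 1e-8)
  }
})

test_that("bipartitions counts internal edges of the unrooted tree", {
  set.seed(1)
  t17 <- ape::rtree(17, tip.label = paste0("s", 1:17))
  expect_length(bipartitions(t17), 14)
  expect_length(bipartitions(read_newick("((A,B),(C,D));")), 1)
  expect_equal(as.character(bipartitions(read_newick("((A,B),(C,D));"))), "C,D")
})

test_that("support contraction keeps edges at or above the threshold", {
  allhi <- read_newick("(((A,B)1.0,(C,D)1.0)1.0,E,F);")
  kept <- contract_low_support(allhi, 0.75)
  expect_setequal(as.character(bipartitions(kept)), as.character(bipartitions(allhi)))

  alllo <- read_newick("(((A,B)0.0,(C,D)0.0)0.0,E,F);")
  expect_length(bipartitions(contract_low_support(alllo, 0.75)), 0)

  # boundary: "below 75%" is strict, so exactly 0.75 survives
  tr <- read_newick("(((A,B)0.9,(C,D)0.74)0.75,E,F);")
  out <- contract_low_support(tr, 0.75)
  keys <- as.character(bipartitions(out))
  leaves <- sort(tr$tip.label)
  expect_true(faststree:::split_key(c("A", "B"), leaves) %in% keys)
  expect_true(faststree:::split_key(c("A", "B", "C", "D"), leaves) %in% keys)
  expect_false(faststree:::split_key(c("C", "D"), leaves) %in% keys)

  expect_error(contract_low_support(read_newick("((A,B),(C,D),E);"), 0.75),
               "support")
})

test_that("contraction only removes bipartitions, never adds them", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    tr <- ape::rtree(n, tip.label = paste0("s", 1:n))
    tr$node.label <- as.character(round(stats::runif(ape::Nnode(tr)), 2))
    for (th in c(0, 0.3, 0.75, 1)) {
      out <- contract_low_support(tr, th)
      expect_true(all(bipartitions(out) %in% bipartitions(tr)))
    }
  }
})

test_that("all_rootings yields one rooted tree per edge", {
  q <- read_newick("((A,B),(C,D));")
  expect_length(all_rootings(q), 5)
  expect_length(all_rootings(read_newick("(A,B,C);")), 3)
  set.seed(3)
  for (n in c(5, 8)) {
    tr <- ape::unroot(ape::rtree(n, tip.label = paste0("s", 1:n)))
    rs <- all_rootings(tr)
    expect_length(rs, 2 * n - 3)
    for (r in rs) {
      expect_true(ape::is.rooted(r))
      expect_setequal(r$tip.label, tr$tip.label)
      expect_setequal(as.character(bipartitions(r)), as.character(bipartitions(tr)))
    }
  }
})

test_that("tree_from_bipartitions displays exactly the given splits", {
  leaves <- LETTERS[1:6]
  expect_length(bipartitions(tree_from_bipartitions(leaves)), 0)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    tr <- ape::rtree(n, tip.label = paste0("s", 1:n))
    keys <- as.character(bipartitions(tr))
    sub <- sample(keys, sample(0:length(keys), 1))
    out <- tree_from_bipartitions(sort(tr$tip.label), as.list(sub))
    expect_setequal(as.character(bipartitions(out)), sub)
  }
  # full split set reconstructs the tree
  tr <- ape::rtree(8, tip.label = paste0("s", 1:8))
  out <- tree_from_bipartitions(sort(tr$tip.label), as.character(bipartitions(tr)))
  expect_setequal(as.character(bipartitions(out)), as.character(bipartitions(tr)))
  expect_error(
    tree_from_bipartitions(LETTERS[1:5], list(c("A", "B"), c("A", "C"))),
    "incompatible"
  )
})

test_that("split compatibility matches brute-force tree enumeration on 5 taxa", {
  leaves <- LETTERS[1:5]
  sides <- c(combn_list_sides(leaves, 2), combn_list_sides(leaves, 3))
  for (a in sides) {
    for (b in sides) {
      mine <- is_compatible(a, list(b), leaves)
      expect_identical(mine, oracle_jointly_displayable(list(a, b), leaves),
                       info = paste(paste(a, collapse = ""), "vs", paste(b, collapse = "")))
    }
  }
  expect_true(is_compatible(c("A", "B"), list(c("A", "B", "C")), leaves))
  expect_false(is_compatible(c("A", "B"), list(c("A", "C")), leaves))
  expect_error(is_compatible(c("A", "Z"), list(c("A", "B")), leaves), "leaf set")
})
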