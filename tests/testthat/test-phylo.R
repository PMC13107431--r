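test_that("scores convert to distances by the min-self-score rule", {
  S <- matrix(c(100, 60, 60, 80), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  D <- score_to_distance(S)
  expect_equal(unname(D["A", "B"]), 20)
  expect_equal(diag(D), c(A = 0, B = 0))

  S2 <- matrix(c(100, 80, 80, 80), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(score_to_distance(S2)["A", "B"]), 0)

  bad <- matrix(c(100, 90, 90, 80), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(score_to_distance(bad), "dominance violated")

  fx <- toy_score_matrix()
  D3 <- score_to_distance(fx)
  expect_equal(D3, t(D3))
  expect_true(all(D3 >= 0))
})

test_that("neighbor joining is exact on an additive four-taxon matrix", {
  # distances generated by the tree ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(rf_distance(tr, ape::read.tree(
    text = "((A:1,B:2):1,(C:3,D:4):0);")), 0)
  tip_edge <- tr$edge[, 2] <= 4
  tip_len <- unname(tr$edge.length[tip_edge][order(tr$edge[tip_edge, 2])])
  expect_equal(tip_len, c(1, 2, 3, 4), tolerance = 1e-12)
  expect_equal(unname(tr$edge.length[!tip_edge]), 1, tolerance = 1e-12)
})

test_that("three taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  len <- tr$edge.length[order(tr$edge[, 2])]
  expect_equal(len, c(1, 2, 3), tolerance = 1e-12)
})

test_that("neighbor joining recovers generating topologies exactly", {
  for (s in 1:8) {
    n <- 4 + (s %% 5)
    gen <- random_tree(n, seed = 40 + s)
    D <- stats::cophenetic(gen)
    tr <- suppressMessages(neighbor_joining(D))
    expect_equal(rf_distance(tr, gen), 0)
    # branch lengths are recovered too (additive input)
    expect_equal(stats::cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # n - 3 internal edges, 2n - 3 edges in total
    expect_equal(tr$Nnode, n - 2L)
    expect_equal(nrow(tr$edge), 2L * n - 3L)
  }
})

test_that("neighbor joining agrees with the exhaustive-topology oracle", {
  for (s in 1:4) {
    n <- if (s %% 2 == 0) 5L else 6L
    gen <- random_tree(n, seed = 50 + s)
    D <- stats::cophenetic(gen)
    nj <- suppressMessages(neighbor_joining(D))
    oracle <- best_topology_by_ols(D)
    expect_equal(phangorn::RF.dist(ape::unroot(nj), ape::unroot(oracle)), 0)
  }
})

test_that("negative branch lengths are clamped with a message", {
  # violates the triangle inequality: the three-point formula for A is
  # (1 + 1 - 3) / 2 = -0.5
  D <- matrix(c(0, 1, 1,
                1, 0, 3,
                1, 3, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_message(tr <- neighbor_joining(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("outgroup rooting requires an edge-separable outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(r1))
  r2 <- root_with_outgroup(tr, c("A", "B"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("A", "B")))
  expect_error(root_with_outgroup(tr, c("A", "C")), "not separable")
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")
})

test_that("Robinson-Foulds distance matches brute-force split counting", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 1)              # normalized
  expect_equal(rf_distance(t1, t2, normalized = FALSE), 2)

  for (s in 1:100) {
    n <- 4 + (s %% 4)
    a <- random_tree(n, seed = 1000 + s)
    b <- random_tree(n, seed = 2000 + s)
    got <- rf_distance(a, b, normalized = FALSE)
    expect_equal(got, as.numeric(phangorn::RF.dist(a, b)))
    expect_equal(rf_distance(a, b), got / (2 * (n - 3)))
  }
  expect_error(
    rf_distance(random_tree(5, 1),
                ape::read.tree(text = "((A,B),(C,(D,E)));")),
    "leaf sets")
})

test_that("Robinson-Foulds is a metric on resolved trees", {
  for (s in 1:30) {
    n <- 5 + (s %% 3)
    a <- random_tree(n, seed = 3000 + s)
    b <- random_tree(n, seed = 4000 + s)
    c0 <- random_tree(n, seed = 5000 + s)
    dab <- rf_distance(a, b); dba <- rf_distance(b, a)
    expect_equal(dab, dba)
    expect_equal(rf_distance(a, a), 0)
    expect_lte(dab, rf_distance(a, c0) + rf_distance(c0, b) + 1e-12)
  }
})

test_that("replicate support maps onto the reference bipartitions", {
  ref <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  same <- lapply(1:10, function(i) ref)
  sup <- map_support(ref, same)
  labs <- sup$node.label[nzchar(sup$node.label)]
  expect_true(all(labs == "100"))

  alt <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  mixed <- c(lapply(1:50, function(i) ref), lapply(1:50, function(i) alt))
  sup <- map_support(ref, mixed)
  labs <- sup$node.label[nzchar(sup$node.label)]
  expect_true(all(labs == "50"))

  # invariant to replicate order and to re-rooting of replicates
  sup_b <- map_support(ref, rev(mixed))
  expect_equal(sup_b$node.label, sup$node.label)
  rerooted <- lapply(mixed, function(t0) ape::root(t0, "D",
                                                   resolve.root = TRUE))
  sup_c <- map_support(ref, rerooted)
  expect_equal(sup_c$node.label, sup$node.label)

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  sup_star <- map_support(star, mixed)
  expect_false(any(nzchar(sup_star$node.label)))

  bad <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(map_support(ref, list(bad)), "replicate 1")
})

test_that("Newick files round-trip with support labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):1,C:3);", f)
  trees <- read_newick(f)
  expect_length(trees, 1L)
  expect_setequal(trees[[1]]$tip.label, c("A", "B", "C"))
  write_newick(trees[[1]], f)
  again <- read_newick(f)[[1]]
  expect_equal(again$edge.length, trees[[1]]$edge.length)

  writeLines("((A:1,B:1)95:1,C:1,D:1);", f)
  tr <- read_newick(f)[[1]]
  expect_true("95" %in% tr$node.label)

  writeLines("((A,B,(C,D);", f)
  expect_error(read_newick(f), "malformed Newick")
  writeLines("((A,B),C)", f)
  expect_error(read_newick(f), "terminating")
})
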