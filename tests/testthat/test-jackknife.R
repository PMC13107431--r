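test_that("site sampling draws the exact quota without replacement", {
  expect_equal(withr::with_seed(1, sample_sites(50, 1.0)), 1:50)
  for (s in 1:20) {
    got <- withr::with_seed(s, sample_sites(10, 0.5))
    expect_length(got, 5L)
    expect_false(anyDuplicated(got) > 0)
    expect_true(all(got >= 1 & got <= 10))
    expect_false(is.unsorted(got, strictly = TRUE))
  }
  expect_error(sample_sites(10, 0.01), "zero columns")
})

test_that("site sampling is uniform over columns", {
  counts <- integer(20)
  withr::with_seed(2, {
    for (i in 1:10000) {
      got <- sample_sites(20, 0.5)
      counts[got] <- counts[got] + 1L
    }
  })
  freq <- counts / 10000
  # binomial 3-sigma band around 0.5
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 10000) + 3e-3))
})

test_that("block sampling yields contiguous runs of the minimum length", {
  expect_equal(withr::with_seed(3, sample_blocks(120, 1.0)), 1:120)
  for (s in 1:50) {
    got <- withr::with_seed(s, sample_blocks(100, 0.5))
    expect_length(got, 50L)
    sel <- logical(100); sel[got] <- TRUE
    runs <- rle(sel)
    lens <- runs$lengths[runs$values]
    # every selected run >= 10 except possibly one final remainder block
    expect_lte(sum(lens < 10), 1L)
  }
  expect_error(withr::with_seed(1, sample_blocks(15, 0.5)),
               "minimum block length")
})

test_that("block sampling stays feasible at high fractions", {
  for (s in 1:25) {
    got <- withr::with_seed(s, sample_blocks(173, 0.9))
    expect_length(got, round(0.9 * 173))
  }
})

test_that("full-fraction jackknife is a fixed point with full support", {
  sc <- toy_score_matrix()
  ref <- toy_score_tree()
  for (mode in c("site", "block")) {
    jk <- jackknife_support(sc, jackknife_config(fraction = 1,
                                                 replicates = 10,
                                                 mode = mode, seed = 4))
    rf <- vapply(jk$replicates, function(t0) rf_distance(ref, t0),
                 numeric(1))
    expect_equal(rf, rep(0, 10))
    labs <- jk$tree$node.label[nzchar(jk$tree$node.label)]
    expect_true(all(labs == "100"))
  }
})

test_that("resampling is deterministic given the seed", {
  sc <- toy_score_matrix()
  a <- jackknife_support(sc, jackknife_config(replicates = 20, seed = 9))
  b <- jackknife_support(sc, jackknife_config(replicates = 20, seed = 9))
  expect_identical(lapply(a$replicates, ape::write.tree),
                   lapply(b$replicates, ape::write.tree))
  expect_identical(a$tree$node.label, b$tree$node.label)
  c0 <- jackknife_support(sc, jackknife_config(replicates = 20, seed = 10))
  expect_false(identical(lapply(a$replicates, ape::write.tree),
                         lapply(c0$replicates, ape::write.tree)))
})

test_that("support values are percentages bounded by replicate counts", {
  fx <- hetero8()
  jk <- jackknife_support(fx$scores, jackknife_config(replicates = 50,
                                                      seed = 6))
  labs <- as.numeric(jk$tree$node.label[nzchar(jk$tree$node.label)])
  expect_true(all(labs >= 0 & labs <= 100))
  expect_length(labs, ape::Ntip(jk$tree) - 3L)
})

test_that("a noisy leaf erodes support near itself more than far away", {
  fx <- lownoise6()
  models <- fx$models
  noisy_id <- names(models)[1]
  m <- models[[noisy_id]]
  m$xyz <- m$xyz + strucphylo:::correlated_noise(n_residues(m), 2.5, 5)
  models[[noisy_id]] <- m
  built <- suppressWarnings(build_core(models))
  jk <- jackknife_support(built$scores,
                          jackknife_config(replicates = 60, seed = 8))
  tr <- jk$tree
  ntip <- ape::Ntip(tr)
  noisy_tip <- match(noisy_id, tr$tip.label)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # distance (in edges) from each internal node to the noisy leaf
  dd <- ape::dist.nodes(ape::compute.brlen(tr, 1))[noisy_tip, ]
  internal <- which(!is.na(sup)) + ntip
  near <- sup[internal[dd[internal] <= min(dd[internal])] - ntip]
  far <- sup[internal[dd[internal] == max(dd[internal])] - ntip]
  expect_gte(mean(far), mean(near))
})

test_that("mode comparison reports paired site and block summaries", {
  sc <- toy_score_matrix()
  cm <- compare_modes(sc, fraction = 1.0, replicates = 10, seed = 5)
  expect_equal(nrow(cm), 2L)
  expect_setequal(cm$mode, c("site", "block"))
  expect_equal(cm$mean_rf, c(0, 0))
  expect_equal(cm$replicates, c(10L, 10L))
})

test_that("the sweep reports one row per fraction with RF in [0, 1]", {
  sc <- toy_score_matrix()
  sw <- fraction_sweep(sc, fractions = c(0.3, 0.6, 1.0), replicates = 15,
                       mode = "site", seed = 3)
  expect_equal(sw$fraction, c(0.3, 0.6, 1.0))
  expect_true(all(sw$mean_rf >= 0 & sw$mean_rf <= 1))
  expect_equal(sw$mean_rf[3], 0)
  expect_equal(sw$replicates, rep(15L, 3))
  expect_error(fraction_sweep(sc, fractions = c(0.5, 0.4)),
               "strictly increasing")
})
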