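test_that("terminal trimming follows the 15-residue window rule", {
  # no residue fails: unchanged
  clean <- make_qc_fixture(list(c(100, 90)))
  expect_equal(n_residues(trim_termini(clean)), 100L)

  # low-confidence N-terminal run: first qualifying window starts at 21
  tail20 <- make_qc_fixture(list(c(20, 60), c(80, 90)))
  trimmed <- trim_termini(tail20)
  expect_equal(n_residues(trimmed), 80L)
  expect_equal(trimmed$meta$parent_index, 21:100)

  # symmetric C-terminal tail
  ctail <- make_qc_fixture(list(c(80, 90), c(20, 60)))
  expect_equal(trim_termini(ctail)$meta$parent_index, 1:80)

  # no qualifying window anywhere: empty result with a recorded reason
  allbad <- make_qc_fixture(list(c(100, 60)))
  out <- trim_termini(allbad)
  expect_equal(n_residues(out), 0L)
  expect_match(attr(out, "reason"), "no qualifying window")

  # an interior dip shorter than the window still blocks those windows
  dip <- make_qc_fixture(list(c(10, 90), c(5, 60), c(85, 90)))
  expect_equal(trim_termini(dip)$meta$parent_index, 16:100)

  # threshold is strict: exactly 70 does not qualify
  at70 <- make_qc_fixture(list(c(15, 70), c(85, 90)))
  expect_equal(trim_termini(at70)$meta$parent_index, 16:100)

  expect_error(trim_termini(make_qc_fixture(list(c(10, 90)))),
               "too short for window")
})

test_that("terminal trimming is idempotent", {
  for (s in 1:5) {
    profile <- withr::with_seed(s, {
      k <- sample(3:6, 1)
      cbind(sample(10:40, k, replace = TRUE),
            sample(c(40, 60, 65, 75, 90), k, replace = TRUE))
    })
    m <- make_qc_fixture(profile, seed = s)
    if (n_residues(m) < 15) next
    once <- trim_termini(m)
    if (n_residues(once) < 15) next
    twice <- trim_termini(once)
    expect_equal(twice$xyz, once$xyz)
    expect_equal(twice$plddt, once$plddt)
  }
})

test_that("fraction filter applies strict 5%/10% thresholds", {
  fail50 <- make_qc_fixture(list(c(6, 40), c(94, 90)))
  r <- qc_filter(fail50)
  expect_false(r$passed)
  expect_equal(r$frac_below_50, 0.06)

  boundary <- make_qc_fixture(list(c(5, 40), c(5, 60), c(90, 90)))
  r <- qc_filter(boundary)
  expect_true(r$passed)   # 'higher than' is strict: 5% and 10% exactly pass
  expect_equal(r$frac_below_50, 0.05)
  expect_equal(r$frac_below_70, 0.10)

  fail70 <- make_qc_fixture(list(c(21, 65), c(179, 90)))
  r <- qc_filter(fail70)
  expect_false(r$passed)
  expect_equal(r$frac_below_70, 0.105)

  empty <- subset_residues(make_qc_fixture(list(c(60, 90))), integer(0))
  r <- qc_filter(empty)
  expect_false(r$passed)
  expect_match(r$reasons, "empty after trimming")

  # fractions are nested by construction
  expect_true(r$frac_below_50 <= r$frac_below_70 || is.na(r$frac_below_50))
})

test_that("raising any residue's pLDDT never flips a pass to a fail", {
  for (s in 1:10) {
    m <- make_qc_fixture(withr::with_seed(s, cbind(
      sample(5:30, 4, replace = TRUE),
      sample(c(45, 60, 80, 95), 4, replace = TRUE))), seed = s)
    before <- qc_filter(m)$passed
    up <- m
    idx <- withr::with_seed(s + 100, sample(n_residues(m), 3))
    up$plddt[idx] <- pmin(up$plddt[idx] + 30, 100)
    after <- qc_filter(up)$passed
    expect_false(before && !after)
  }
})

test_that("low-confidence removal is strict and order-preserving", {
  m <- make_qc_fixture(list(c(1, 90), c(1, 45), c(1, 88)))
  kept <- drop_low_confidence(m)
  expect_equal(kept$plddt, c(90, 88))
  expect_equal(kept$meta$parent_index, c(1L, 3L))

  at50 <- make_qc_fixture(list(c(3, 50), c(60, 90)))
  expect_equal(n_residues(drop_low_confidence(at50)), 63L)

  expect_error(drop_low_confidence(make_qc_fixture(list(c(60, 40)))),
               "no residues")

  for (s in 1:5) {
    m <- make_qc_fixture(withr::with_seed(s, cbind(
      sample(5:20, 5, replace = TRUE),
      sample(c(30, 49, 50, 51, 90), 5))), seed = s)
    out <- drop_low_confidence(m)
    expect_true(all(out$plddt >= 50))
    expect_equal(sum(m$plddt >= 50), n_residues(out))
  }
})

test_that("region trimming adds a 200-residue margin on both sides", {
  m1000 <- make_qc_fixture(list(c(1000, 90)))
  out <- trim_to_region(m1000, 400, 600)
  expect_equal(n_residues(out), 601L)
  expect_equal(out$meta$parent_index, 200:800)

  m500 <- make_qc_fixture(list(c(500, 90)))
  expect_identical(trim_to_region(m500, 100, 450), m500)

  expect_error(trim_to_region(m500, 300, 200), "invalid region")
  expect_error(trim_to_region(m500, 0, 10), "invalid region")
})

test_that("a fully confident model passes the whole QC chain unchanged", {
  m <- make_template(100, seed = 3)
  out <- qc_batch(list(m))
  expect_true(out$report$passed)
  expect_equal(out$models[[1]]$xyz, m$xyz)
  expect_equal(out$models[[1]]$plddt, m$plddt)
})

test_that("batch QC reports every model and composes the three rules", {
  clean <- make_qc_fixture(list(c(100, 90)), model_id = "clean")
  tails <- make_qc_fixture(list(c(20, 60), c(80, 90), c(20, 60)),
                           model_id = "tails")
  # interior low-confidence run: survives terminal trimming, fails the
  # fraction filter
  bad <- make_qc_fixture(list(c(40, 90), c(10, 40), c(50, 90)),
                         model_id = "bad")
  out <- qc_batch(list(clean, tails, bad))
  expect_equal(nrow(out$report), 3L)
  expect_setequal(names(out$models), c("clean", "tails"))
  expect_equal(out$report$passed[out$report$model_id == "bad"], FALSE)
  expect_equal(out$report$n_after_terminal_trim[
    out$report$model_id == "tails"], 80L)

  empty <- qc_batch(list())
  expect_equal(length(empty$models), 0L)
  expect_equal(nrow(empty$report), 0L)

  dup <- list(clean, make_qc_fixture(list(c(60, 90)), model_id = "clean"))
  expect_error(qc_batch(dup), "duplicate model_id")
})
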