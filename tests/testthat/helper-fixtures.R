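# shared fixtures; expensive objects are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# hand-written 3-residue PDB (B-factors carry pLDDT 90/80/70)
fixture_pdb_lines <- function() {
  c(sprintf("ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1:3, c("ALA", "GLY", "TRP"), 1:3,
            c(1.0, 4.8, 8.6), c(2.0, 2.0, 2.0), c(3.0, 3.0, 3.0),
            1.0, c(90, 80, 70)),
    "END")
}

# the same three residues as a minimal mmCIF atom_site loop
fixture_cif_lines <- function() {
  c("data_fixture", "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    sprintf("ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s A CA 1",
            1:3, c("ALA", "GLY", "TRP"), 1:3,
            c(1.0, 4.8, 8.6), c(2.0, 2.0, 2.0), c(3.0, 3.0, 3.0),
            c(90, 80, 70), 1:3, c("ALA", "GLY", "TRP")),
    "#")
}

# low-noise 6-leaf benchmark with its core and scores (used across files)
lownoise6 <- function() cached("lownoise6", {
  ds <- simulate_dataset(simulation_spec(n_leaves = 6, seed = 101))
  built <- suppressWarnings(build_core(ds$models))
  c(ds, built)
})

# heterogeneous-branch 8-leaf dataset with intermediate support
hetero8 <- function() cached("hetero8", {
  ds <- simulate_dataset(simulation_spec(
    n_leaves = 8, noise_per_unit_branch = 1.0,
    branch_length_range = c(0.05, 0.6), seed = 13))
  built <- suppressWarnings(build_core(ds$models))
  c(ds, built)
})

# small hand-built score matrix whose implied distances are additive on a
# known 6-taxon tree; cheap stand-in for jackknife determinism tests
toy_score_matrix <- function(ncols = 60, seed = 5) {
  tr <- withr::with_seed(seed, {
    t2 <- ape::rtree(6)
    t2$edge.length <- stats::runif(nrow(t2$edge), 0.5, 2)
    t2$tip.label <- paste0("m", 1:6)
    t2
  })
  ids <- sort(tr$tip.label)
  pd <- stats::cophenetic(tr)[ids, ids]
  n <- length(ids)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # per-column contributions: self = 1, pair column share chosen so the
  # column-summed scores reproduce the additive distances exactly
  self_contrib <- matrix(1, n, ncols, dimnames = list(ids, NULL))
  contrib <- matrix(0, nrow(pair_idx), ncols)
  rownames(contrib) <- paste(ids[pair_idx[, 1]], ids[pair_idx[, 2]],
                             sep = "|")
  w <- withr::with_seed(seed + 1L,
                        matrix(stats::runif(nrow(pair_idx) * ncols, 0.5,
                                            1.5),
                               nrow(pair_idx), ncols))
  for (p in seq_len(nrow(pair_idx))) {
    d <- pd[pair_idx[p, 1], pair_idx[p, 2]]
    # column contributions vary, but still sum exactly to ncols - d
    contrib[p, ] <- 1 - d * w[p, ] / sum(w[p, ])
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(S) <- ncols
  for (p in seq_len(nrow(pair_idx)))
    S[pair_idx[p, 1], pair_idx[p, 2]] <-
      S[pair_idx[p, 2], pair_idx[p, 1]] <- sum(contrib[p, ])
  structure(list(ids = ids, S = S, contrib = contrib,
                 self_contrib = self_contrib, pair_idx = pair_idx,
                 params = align_params()),
            class = "score_matrix")
}

toy_score_tree <- function(...) {
  suppressMessages(neighbor_joining(score_to_distance(toy_score_matrix(...))))
}

# independent RMSD oracle: numerical minimisation over Euler angles
brute_force_rmsd <- function(A, B, n_starts = 12) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A - B %*% t(rot(ang)))^2)))
  best <- Inf
  grid <- withr::with_seed(99, matrix(stats::runif(3 * n_starts, 0, 2 * pi),
                                      ncol = 3))
  for (g in seq_len(nrow(grid))) {
    fit <- stats::optim(grid[g, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# random unrooted binary tree over n labelled leaves
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- paste0("L", seq_len(n))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
    tr
  })
}

# exhaustive-topology oracle: the unrooted topology whose ordinary
# least-squares branch fit reproduces an additive matrix with ~zero
# residual (unique for additive D)
best_topology_by_ols <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  all_t <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(utils::combn(n, 2))
  d <- D[pairs]
  best <- NULL
  for (k in seq_along(all_t)) {
    tr <- all_t[[k]]   # [[ restores the multiPhylo's compressed tip labels
    # indicator: pair crosses edge iff the tips lie on opposite sides
    post <- ape::reorder.phylo(tr, "postorder")
    ntip <- n
    below <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) below[[i]] <- i
    for (e in seq_len(nrow(post$edge)))
      below[[post$edge[e, 1]]] <- c(below[[post$edge[e, 1]]],
                                    below[[post$edge[e, 2]]])
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (e in seq_len(nrow(tr$edge))) {
      side <- seq_len(ntip) %in% below[[tr$edge[e, 2]]]
      X[, e] <- side[pairs[, 1]] != side[pairs[, 2]]
    }
    fit <- stats::lm.fit(X, d)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) best <- list(tree = tr, rss = rss)
  }
  best$tree
}
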