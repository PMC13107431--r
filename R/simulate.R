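#' Specification for a synthetic structure dataset
#'
#' Describes a benchmark dataset: a random tree over `n_leaves` taxa and
#' one C-alpha structure per leaf, derived from a common template by
#' accumulating spatially correlated coordinate noise along the branches.
#' Defaults describe a clean, low-divergence dataset (0.5 A of noise per
#' unit branch length, correlation length 5 residues, no indels, no
#' low-confidence tails); tests and benchmarks override individual
#' fields.
#'
#' @param n_leaves Number of leaves (>= 3; default 8).
#' @param template_len Template length in residues (>= 60; default 250).
#' @param tree_model `"yule"` (random birth tree), `"balanced"` or
#'   `"caterpillar"`.
#' @param noise_per_unit_branch Per-residue coordinate displacement sd, in
#'   Angstrom per unit branch length (default 0.5).
#' @param spatial_correlation_length Smoothing window (residues) of the
#'   along-chain moving average applied to the displacement field
#'   (default 5).
#' @param branch_length_range Bounds of the uniform branch-length draw
#'   (default `c(0.4, 0.6)`, a balanced benchmark tree; widen the lower
#'   bound down to ~0.05 to create weakly supported deep splits).
#' @param indel_rate Per-residue, per-unit-branch probability of an indel
#'   event (default 0).
#' @param tail_len Length of appended low-confidence terminal tails
#'   (default 0).
#' @param tail_plddt pLDDT assigned to tail residues (default 55).
#' @param core_plddt pLDDT assigned to non-tail residues (default 90).
#' @param seed Integer seed (default 1).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_leaves = 8L, template_len = 250L,
                            tree_model = c("yule", "balanced",
                                           "caterpillar"),
                            noise_per_unit_branch = 0.5,
                            spatial_correlation_length = 5L,
                            branch_length_range = c(0.4, 0.6),
                            indel_rate = 0, tail_len = 0L,
                            tail_plddt = 55, core_plddt = 90, seed = 1L) {
  tree_model <- match.arg(tree_model)
  if (n_leaves < 3L) stop("n_leaves must be >= 3")
  if (template_len < 60L) stop("template_len must be >= 60")
  stopifnot(noise_per_unit_branch >= 0, indel_rate >= 0, tail_len >= 0)
  structure(list(n_leaves = as.integer(n_leaves),
                 template_len = as.integer(template_len),
                 tree_model = tree_model,
                 noise_per_unit_branch = noise_per_unit_branch,
                 spatial_correlation_length =
                   as.integer(spatial_correlation_length),
                 branch_length_range = as.numeric(branch_length_range),
                 indel_rate = indel_rate, tail_len = as.integer(tail_len),
                 tail_plddt = tail_plddt, core_plddt = core_plddt,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a random tree for simulation
#'
#' Yule-style random topologies come from `ape::rtree`; balanced and
#' caterpillar shapes from `ape::stree`. Branch lengths are redrawn
#' uniformly in `[0.4, 0.6]` so every branch carries comparable signal and
#' no internal branch is unresolvably short. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [simulation_spec].
#' @return An unrooted `phylo` tree with positive branch lengths.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    tr <- switch(spec$tree_model,
      yule = ape::rtree(spec$n_leaves),
      balanced = ape::stree(spec$n_leaves, "balanced"),
      caterpillar = ape::stree(spec$n_leaves, "left"))
    tr <- ape::multi2di(tr)
    tr$edge.length <- stats::runif(nrow(tr$edge),
                                   spec$branch_length_range[1],
                                   spec$branch_length_range[2])
    tr$tip.label <- paste0("t", seq_len(spec$n_leaves))
    tr
  })
}

#' Build an idealized C-alpha template
#'
#' Constructs a self-avoiding C-alpha trace from idealized alpha-helix
#' and beta-strand segments laid out in an antiparallel "snake": each
#' secondary-structure segment runs along +/-x in its own row, rows are
#' spaced far enough apart that non-consecutive residues never clash, and
#' short turn segments connect the rows. Consecutive C-alpha spacing is
#' 3.8 +/- 0.1 A. All pLDDT values are 100. Deterministic given `seed`.
#'
#' @param template_len Number of residues (>= 60).
#' @param seed Integer seed for segment-length draws and sequence.
#' @return A [structure_model] named `"template"`.
#' @export
make_template <- function(template_len, seed = 1L) {
  if (template_len < 60L) stop("template_len must be >= 60")
  withr::with_seed(seed, {
    # each secondary-structure segment occupies its own row of an
    # antiparallel snake; rows are kept 11 A apart in y (minus the <= 4.6 A
    # in-segment oscillation this leaves > 6 A clearance), and variable-
    # length turn segments bridge exactly back to the next row baseline,
    # so consecutive steps stay near 3.8 A and rows never clash
    coords <- matrix(c(0, 0, 0), 1, 3)
    base_y <- 0
    dirx <- 1
    helix_next <- TRUE
    while (nrow(coords) < template_len) {
      seg_len <- if (helix_next) sample(10:16, 1) else sample(6:9, 1)
      seg_len <- min(seg_len, template_len - nrow(coords))
      t <- seq_len(seg_len)
      local <- if (helix_next) {
        cbind(1.52 * t, 2.3 * (cos(t * 100 * pi / 180) - 1),
              2.3 * sin(t * 100 * pi / 180))
      } else {
        cbind(3.63 * t, 0.6 * ((-1)^t - 1), 0)
      }
      local[, 1] <- dirx * local[, 1]
      coords <- rbind(coords,
                      sweep(local, 2, coords[nrow(coords), ], "+"))
      helix_next <- !helix_next
      remain <- template_len - nrow(coords)
      if (remain > 0) {
        # semicircular arc to the next row: smooth u-turn, step ~3.7 A
        end <- coords[nrow(coords), ]
        dy <- (base_y + 11) - end[2]
        r <- dy / 2
        n_turn <- ceiling(pi * r / 3.8)
        if (2 * r * sin(pi / (2 * n_turn)) < 3.5)
          r <- 3.7 / (2 * sin(pi / (2 * n_turn)))   # overshoot is safe
        k <- seq_len(min(n_turn, remain))
        theta <- k * pi / n_turn
        arc <- cbind(end[1] + dirx * r * sin(theta),
                     end[2] + r * (1 - cos(theta)),
                     end[3])
        coords <- rbind(coords, arc)
        base_y <- end[2] + 2 * r
        dirx <- -dirx
      }
    }
    coords <- coords[seq_len(template_len), , drop = FALSE]
    aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 template_len, replace = TRUE)
    structure_model("template", coords, aa, rep(100, template_len))
  })
}

# along-chain moving-average smoothing preserving per-residue sd
correlated_noise <- function(n, sd, window) {
  if (sd == 0) return(matrix(0, n, 3))
  window <- max(1L, as.integer(window))
  raw <- matrix(stats::rnorm(n * 3), n, 3)
  if (window == 1L) return(sd * raw)
  half <- window %/% 2
  sm <- apply(raw, 2, function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    m * sqrt(hi - lo + 1L)   # restore unit per-residue sd
  })
  sd * sm
}

# extend a trace from one end with a smooth 3.8 A-step random walk
random_tail <- function(anchor, direction, len) {
  if (len == 0L) return(matrix(NA_real_, 0, 3))
  pts <- matrix(NA_real_, len, 3)
  d <- direction / sqrt(sum(direction^2))
  pos <- anchor
  for (k in seq_len(len)) {
    d <- d + stats::rnorm(3, sd = 0.3)
    d <- d / sqrt(sum(d^2))
    pos <- pos + 3.8 * d
    pts[k, ] <- pos
  }
  pts
}

#' Evolve structures along a tree
#'
#' Starting from the template at the root, each branch adds a Gaussian
#' coordinate displacement with per-residue standard deviation
#' `noise_per_unit_branch * branch_length`, smoothed along the chain with
#' a moving average of width `spatial_correlation_length` (so
#' neighbouring residues deviate together, as real structural divergence
#' does). Indel events (rate `indel_rate` per residue per unit branch)
#' delete residues or insert locally generated segments. Leaves receive a
#' random rigid motion, optional low-confidence terminal tails, and a
#' ground-truth correspondence to template residues in `meta$truth`
#' (`NA` for inserted or tail residues).
#'
#' @param template A [structure_model] (e.g. from [make_template]).
#' @param tree A `phylo` tree whose tip labels name the leaves.
#' @param spec A [simulation_spec].
#' @return Named list of [structure_model] objects, one per leaf.
#' @export
evolve_structures <- function(template, tree, spec) {
  stopifnot(inherits(template, "structure_model"), inherits(tree, "phylo"),
            inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed + 1L, {
    ntip <- ape::Ntip(tree)
    rtree <- if (ape::is.rooted(tree)) tree else
      ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    n_nodes <- ntip + rtree$Nnode
    root <- ntip + 1L
    states <- vector("list", n_nodes)
    states[[root]] <- list(xyz = template$xyz, aa = template$aa,
                           truth = seq_len(n_residues(template)))
    pre <- ape::reorder.phylo(rtree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
      bl <- pre$edge.length[e]
      st <- states[[parent]]
      n <- nrow(st$xyz)
      xyz <- st$xyz + correlated_noise(n, spec$noise_per_unit_branch * bl,
                                       spec$spatial_correlation_length)
      aa <- st$aa; truth <- st$truth
      if (spec$indel_rate > 0) {
        p_event <- min(1, spec$indel_rate * bl)
        events <- which(stats::runif(n) < p_event)
        for (pos in rev(events)) {
          if (stats::runif(1) < 0.5) {        # deletion of a short run
            del_len <- sample(1:5, 1)
            del <- pos:min(pos + del_len - 1L, nrow(xyz))
            xyz <- xyz[-del, , drop = FALSE]
            aa <- aa[-del]; truth <- truth[-del]
          } else {                            # insertion of a local segment
            ins_len <- sample(3:10, 1)
            anchor <- xyz[pos, ]
            dirv <- if (pos < nrow(xyz)) xyz[pos + 1, ] - anchor else
              anchor - xyz[pos - 1, ]
            seg <- random_tail(anchor, dirv + stats::rnorm(3, sd = 1),
                               ins_len)
            xyz <- rbind(xyz[seq_len(pos), , drop = FALSE], seg,
                         xyz[-seq_len(pos), , drop = FALSE])
            aa <- c(aa[seq_len(pos)],
                    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                           ins_len, replace = TRUE),
                    aa[-seq_len(pos)])
            truth <- c(truth[seq_len(pos)], rep(NA_integer_, ins_len),
                       truth[-seq_len(pos)])
          }
        }
      }
      states[[child]] <- list(xyz = xyz, aa = aa, truth = truth)
    }
    models <- vector("list", ntip)
    for (tip in seq_len(ntip)) {
      st <- states[[tip]]
      xyz <- st$xyz; aa <- st$aa; truth <- st$truth
      plddt <- rep(spec$core_plddt, nrow(xyz))
      if (spec$tail_len > 0) {
        nt <- random_tail(xyz[1, ], xyz[1, ] - xyz[2, ], spec$tail_len)
        ct <- random_tail(xyz[nrow(xyz), ],
                          xyz[nrow(xyz), ] - xyz[nrow(xyz) - 1, ],
                          spec$tail_len)
        xyz <- rbind(nt[rev(seq_len(spec$tail_len)), , drop = FALSE], xyz,
                     ct)
        tails_aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                           2L * spec$tail_len, replace = TRUE)
        aa <- c(tails_aa[seq_len(spec$tail_len)], aa,
                tails_aa[-seq_len(spec$tail_len)])
        truth <- c(rep(NA_integer_, spec$tail_len), truth,
                   rep(NA_integer_, spec$tail_len))
        plddt <- c(rep(spec$tail_plddt, spec$tail_len), plddt,
                   rep(spec$tail_plddt, spec$tail_len))
      }
      # random rigid motion so superposition is non-trivial
      R <- random_rotation()
      xyz <- sweep(xyz %*% t(R), 2, stats::runif(3, -20, 20), "+")
      id <- rtree$tip.label[tip]
      models[[tip]] <- structure_model(id, xyz, aa, plddt,
                                       meta = list(truth = truth))
    }
    names(models) <- rtree$tip.label
    models
  })
}

#' Build a structure with a prescribed pLDDT profile
#'
#' Lays the given run-length pLDDT profile on an idealized template
#' backbone — the standard way to construct quality-control fixtures.
#'
#' @param profile A list of `c(run_length, plddt)` pairs, or a two-column
#'   matrix.
#' @param seed Seed passed to [make_template].
#' @param model_id Identifier for the fixture.
#' @return A [structure_model] whose length is the sum of run lengths.
#' @export
make_qc_fixture <- function(profile, seed = 1L, model_id = "qc_fixture") {
  if (is.list(profile)) profile <- do.call(rbind, profile)
  profile <- as.matrix(profile)
  stopifnot(ncol(profile) == 2, all(profile[, 1] >= 1))
  total <- sum(profile[, 1])
  tmpl <- make_template(max(total, 60L), seed = seed)
  m <- subset_residues(tmpl, seq_len(total))
  m$plddt <- rep(profile[, 2], times = profile[, 1])
  m$model_id <- model_id
  m$label <- model_id
  m
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: template + tree + evolved leaf structures.
#'
#' @param spec A [simulation_spec].
#' @return A list with `spec`, `template`, `tree` (the generating tree)
#'   and `models` (named list of leaf structures).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  template <- make_template(spec$template_len, seed = spec$seed)
  tree <- generate_tree(spec)
  models <- evolve_structures(template, tree, spec)
  list(spec = spec, template = template, tree = tree, models = models)
}

#' Write a simulated dataset to disk
#'
#' Emits one PDB file per leaf (through the package's own writer, so
#' tests exercise real I/O), the generating tree as `truth.nwk`, and the
#' ground-truth residue correspondences as `truth_map.tsv`.
#'
#' @param dataset Result of [simulate_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in dataset$models)
    write_structure(m, file.path(dir, paste0(m$model_id, ".pdb")))
  write_newick(dataset$tree, file.path(dir, "truth.nwk"))
  rows <- do.call(rbind, lapply(dataset$models, function(m)
    data.frame(model_id = m$model_id, residue = m$seq_index,
               template_residue = if (is.null(m$meta$truth))
                 NA_integer_ else m$meta$truth)))
  utils::write.table(rows, file.path(dir, "truth_map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
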