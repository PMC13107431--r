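#' Build the common structural core of a set of models
#'
#' Progressive agglomeration in the style of structural-core aligners:
#' all pairwise alignments are computed, then the two most similar groups
#' are merged repeatedly. Merging intersects the groups' residue
#' correspondences via the highest-scoring cross pair, so every surviving
#' column holds exactly one residue of every member; merging continues
#' until one group (the common core) remains. Group-to-group similarity is
#' the mean of the member pairwise alignment scores; ties break
#' lexicographically on model_id.
#'
#' The returned score matrix is computed over the final core columns:
#' for every model pair the core coordinates are Kabsch-superposed and
#' per-column score contributions are stored, making the total score
#' column-additive (the basis of jackknife rescoring via
#' [restrict_scores]).
#'
#' @param models List of at least 3 QC-passed [structure_model] objects.
#' @param params An [align_params] list.
#' @param strict If `TRUE`, a model that cannot be aligned to the rest
#'   (shares fewer than `min_core_len` columns) aborts the run; otherwise
#'   it is excluded with a warning.
#' @return A list with `core` (a `core_alignment`: `model_ids`, `columns`
#'   matrix of residue positions with one column per model, `spread`,
#'   `avg_rmsd`) and `scores` (a `score_matrix`: `ids`, symmetric `S` with
#'   self-scores on the diagonal, per-column contribution matrices
#'   `contrib` and `self_contrib`).
#' @export
build_core <- function(models, params = align_params(), strict = FALSE) {
  ids <- check_unique_ids(models)
  names(models) <- ids
  n <- length(models)
  if (n < 3L) stop("at least 3 models are required")

  # all pairwise alignments
  pw_score <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pw_pairs <- vector("list", n * n)
  dim(pw_pairs) <- c(n, n)
  failed <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- tryCatch(align_pair(models[[i]], models[[j]], params),
                   error = function(e) e)
    if (inherits(al, "error")) {
      if (strict) stop(conditionMessage(al))
      next
    }
    pw_score[i, j] <- pw_score[j, i] <- al$score
    pw_pairs[[i, j]] <- al$pairs
    pw_pairs[[j, i]] <- al$pairs[, 2:1, drop = FALSE]
  }
  # exclude models with no usable alignment to the rest
  usable <- which(rowSums(!is.na(pw_score)) >= 1L)
  excluded <- setdiff(ids, ids[usable])
  if (length(excluded)) {
    msg <- paste("excluding models that align to nothing:",
                 paste(excluded, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  active <- ids[usable]
  if (length(active) < 3L)
    stop("fewer than 3 alignable models remain")

  # each group: character vector of members + columns matrix (cols x members)
  groups <- lapply(active, function(id) {
    cols <- matrix(seq_len(n_residues(models[[id]])), ncol = 1,
                   dimnames = list(NULL, id))
    list(members = id, cols = cols)
  })

  group_link <- function(g1, g2) {
    s <- pw_score[g1$members, g2$members, drop = FALSE]
    if (all(is.na(s))) return(NA_real_)
    mean(s, na.rm = TRUE)
  }

  while (length(groups) > 1L) {
    m <- length(groups)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      s <- group_link(groups[[i]], groups[[j]])
      if (is.na(s)) next
      key <- paste(sort(c(groups[[i]]$members[1], groups[[j]]$members[1])),
                   collapse = "|")
      if (is.null(best) || s > best$s ||
          (s == best$s && key < best$key))
        best <- list(i = i, j = j, s = s, key = key)
    }
    if (is.null(best)) {
      # remaining groups share no alignment; drop the smallest
      sizes <- vapply(groups, function(g) length(g$members), integer(1))
      drop_i <- which.min(sizes)
      dropped <- groups[[drop_i]]$members
      excluded <- c(excluded, dropped)
      msg <- paste("excluding unalignable group:",
                   paste(dropped, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      groups <- groups[-drop_i]
      next
    }
    g1 <- groups[[best$i]]; g2 <- groups[[best$j]]
    merged <- merge_groups(g1, g2, pw_score, pw_pairs, ids)
    if (nrow(merged$cols) < params$min_core_len) {
      # the smaller group cannot join the core
      drop_g <- if (length(g1$members) <= length(g2$members)) best$i else
        best$j
      dropped <- groups[[drop_g]]$members
      excluded <- c(excluded, dropped)
      msg <- paste("excluding models sharing <", params$min_core_len,
                   "core columns:", paste(dropped, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      groups <- groups[-drop_g]
      next
    }
    groups[[best$i]] <- merged
    groups <- groups[-best$j]
    if (length(groups) == 1L && length(groups[[1]]$members) < 3L)
      stop("fewer than 3 models remain in the core")
  }

  g <- groups[[1]]
  if (length(g$members) < 3L) stop("fewer than 3 models remain in the core")
  core_models <- models[g$members]
  cols <- g$cols[, g$members, drop = FALSE]
  core_score_matrix(core_models, cols, params, excluded)
}

# intersect two groups' correspondences through the best cross pair
merge_groups <- function(g1, g2, pw_score, pw_pairs, ids) {
  cross <- pw_score[g1$members, g2$members, drop = FALSE]
  k <- which(cross == max(cross, na.rm = TRUE), arr.ind = TRUE)[1, ]
  rep1 <- g1$members[k[1]]; rep2 <- g2$members[k[2]]
  pairs <- pw_pairs[[match(rep1, ids), match(rep2, ids)]]
  map <- integer(0)
  map[pairs[, 1]] <- pairs[, 2]                 # rep1 residue -> rep2 residue
  r1 <- g1$cols[, rep1]
  partner <- rep(NA_integer_, length(r1))
  has <- r1 <= length(map)
  partner[has] <- map[r1[has]]
  row2 <- match(partner, g2$cols[, rep2])       # matching column in g2
  keep <- which(!is.na(row2))
  cols <- cbind(g1$cols[keep, , drop = FALSE],
                g2$cols[row2[keep], , drop = FALSE])
  list(members = c(g1$members, g2$members), cols = cols)
}

# score matrix + geometry summaries over the final core columns
core_score_matrix <- function(models, cols, params, excluded) {
  ids <- names(models)
  n <- length(ids)
  ncols <- nrow(cols)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  contrib <- matrix(0, nrow(pair_idx), ncols)
  rownames(contrib) <- paste(ids[pair_idx[, 1]], ids[pair_idx[, 2]],
                             sep = "|")
  self_contrib <- matrix(0, n, ncols, dimnames = list(ids, NULL))
  for (i in seq_len(n))
    self_contrib[i, ] <- self_column_scores(models[[i]]$aa[cols[, i]],
                                            params)
  rmsds <- numeric(nrow(pair_idx))
  for (p in seq_len(nrow(pair_idx))) {
    i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
    Ai <- models[[i]]$xyz[cols[, i], , drop = FALSE]
    Aj <- models[[j]]$xyz[cols[, j], , drop = FALSE]
    sp <- kabsch_superpose(Ai, Aj)
    d <- sqrt(rowSums((Ai - apply_superposition(sp, Aj))^2))
    contrib[p, ] <- column_scores(d, models[[i]]$aa[cols[, i]],
                                  models[[j]]$aa[cols[, j]], params)
    rmsds[p] <- sp$rmsd
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(S) <- rowSums(self_contrib)
  for (p in seq_len(nrow(pair_idx))) {
    i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
    S[i, j] <- S[j, i] <- sum(contrib[p, ])
  }
  scores <- structure(list(ids = ids, S = S, contrib = contrib,
                           self_contrib = self_contrib,
                           pair_idx = pair_idx, params = params),
                      class = "score_matrix")
  spread <- column_spread(models, cols)
  core <- structure(list(model_ids = ids, columns = cols, spread = spread,
                         avg_rmsd = mean(rmsds), excluded = excluded),
                    class = "core_alignment")
  list(core = core, scores = scores)
}

# RMS pairwise C-alpha distance within each column after joint
# superposition of every model onto the medoid (highest mean score)
column_spread <- function(models, cols) {
  ids <- names(models)
  n <- length(ids)
  ncols <- nrow(cols)
  coords <- array(NA_real_, c(ncols, 3, n))
  # medoid by mean pairwise RMSD proxy: use first model as reference is
  # not frame-free; pick the model minimising summed RMSD to the others
  rms_to <- numeric(n)
  mats <- lapply(seq_len(n), function(i)
    models[[i]]$xyz[cols[, i], , drop = FALSE])
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    rms_to[i] <- rms_to[i] + kabsch_superpose(mats[[i]], mats[[j]])$rmsd
  med <- which.min(rms_to)
  for (i in seq_len(n)) {
    if (i == med) coords[, , i] <- mats[[i]]
    else {
      sp <- kabsch_superpose(mats[[med]], mats[[i]])
      coords[, , i] <- apply_superposition(sp, mats[[i]])
    }
  }
  vapply(seq_len(ncols), function(c0) {
    pts <- t(coords[c0, , ])
    dd <- stats::dist(pts)
    sqrt(mean(dd^2))
  }, numeric(1))
}

#' Average pairwise core RMSD
#'
#' The mean, over all model pairs, of the Kabsch RMSD computed on the core
#' columns — the headline "average RMSD" of a common structural core.
#'
#' @param core A `core_alignment` from [build_core].
#' @param models The member models (list named by model_id, or in
#'   `core$model_ids` order).
#' @return Mean pairwise RMSD in Angstrom.
#' @export
core_rmsd <- function(core, models) {
  stopifnot(inherits(core, "core_alignment"))
  models <- models_in_core_order(core, models)
  ids <- core$model_ids
  n <- length(ids)
  if (nrow(core$columns) == 0L) stop("empty core")
  rmsds <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- kabsch_superpose(
      models[[i]]$xyz[core$columns[, i], , drop = FALSE],
      models[[j]]$xyz[core$columns[, j], , drop = FALSE])
    rmsds <- c(rmsds, sp$rmsd)
  }
  mean(rmsds)
}

models_in_core_order <- function(core, models) {
  if (!is.null(names(models))) {
    missing <- setdiff(core$model_ids, names(models))
    if (length(missing))
      stop("models missing for: ", paste(missing, collapse = ", "))
    models[core$model_ids]
  } else {
    ids <- vapply(models, function(m) m$model_id, character(1))
    models[match(core$model_ids, ids)]
  }
}

#' Restrict a score matrix to a subset of core columns
#'
#' Re-sums the stored per-column score contributions (pair scores and
#' self-scores) over the selected columns. Because the score is
#' column-additive, restricting to all columns reproduces the full matrix
#' exactly.
#'
#' @param scores A `score_matrix` from [build_core].
#' @param columns Non-empty integer vector of core column indices.
#' @return A `score_matrix` over the selected columns.
#' @export
restrict_scores <- function(scores, columns) {
  stopifnot(inherits(scores, "score_matrix"))
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("empty column subset")
  if (min(columns) < 1L || max(columns) > ncol(scores$contrib))
    stop("column indices out of range")
  n <- length(scores$ids)
  S <- matrix(0, n, n, dimnames = list(scores$ids, scores$ids))
  diag(S) <- rowSums(scores$self_contrib[, columns, drop = FALSE])
  pi_ <- scores$pair_idx
  ssum <- rowSums(scores$contrib[, columns, drop = FALSE])
  for (p in seq_len(nrow(pi_)))
    S[pi_[p, 1], pi_[p, 2]] <- S[pi_[p, 2], pi_[p, 1]] <- ssum[p]
  structure(list(ids = scores$ids, S = S,
                 contrib = scores$contrib[, columns, drop = FALSE],
                 self_contrib = scores$self_contrib[, columns, drop = FALSE],
                 pair_idx = pi_, params = scores$params),
            class = "score_matrix")
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("core_alignment: %d columns across %d models (avg RMSD %.2f A)\n",
              nrow(x$columns), length(x$model_ids), x$avg_rmsd))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix over %d models, %d core columns\n",
              length(x$ids), ncol(x$contrib)))
  print(round(x$S, 2))
  invisible(x)
}
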