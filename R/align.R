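#' Alignment parameters for pairwise and progressive structural alignment
#'
#' Collects the tunable constants of the structural aligner. The aligner
#' is sequence-order independent: residue correspondences are found purely
#' in space, so circularly permuted chains align correctly.
#'
#' @param min_core_len Minimum acceptable correspondence length (residues).
#' @param frag_len Length of the gapless seed fragments (residues).
#' @param frag_stride Stride between seed fragment start positions.
#' @param seed_rmsd_max Keep a seed only if its fragment RMSD is below
#'   this (Angstrom).
#' @param max_seeds Maximum number of seeds extended per pair (best
#'   fragment RMSDs first).
#' @param pair_cutoff Distance below which two transformed C-alphas may be
#'   paired (Angstrom).
#' @param max_iter Iteration cap for the superpose/re-pair loop.
#' @param sigma_s Width of the Gaussian geometric score term (Angstrom).
#' @param w_geo,w_aa Weights of the geometric and amino-acid similarity
#'   score terms.
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_core_len = 30L, frag_len = 12L,
                         frag_stride = 8L, seed_rmsd_max = 2,
                         max_seeds = 32L, pair_cutoff = 4.5,
                         max_iter = 50L, sigma_s = 2, w_geo = 1,
                         w_aa = 0.5) {
  structure(list(min_core_len = as.integer(min_core_len),
                 frag_len = as.integer(frag_len),
                 frag_stride = as.integer(frag_stride),
                 seed_rmsd_max = seed_rmsd_max,
                 max_seeds = as.integer(max_seeds),
                 pair_cutoff = pair_cutoff, max_iter = as.integer(max_iter),
                 sigma_s = sigma_s, w_geo = w_geo, w_aa = w_aa),
            class = "align_params")
}

# amino-acid similarity in [0, 1]: BLOSUM62 affinely rescaled.
# BLOSUM62 is diagonally dominant, so sim(a, b) <= min(sim(a, a),
# sim(b, b)) — this guarantees self-score dominance of the column score.
aa_similarity_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    b <- e$BLOSUM62[c(letters20, "X"), c(letters20, "X")]
    cache <<- (b - min(b)) / (max(b) - min(b))
    cache
  }
})

# per-column score contributions given inter-CA distances and aa codes
column_scores <- function(d, aa_a, aa_b, params) {
  sim <- aa_similarity_matrix()
  aa_a <- ifelse(aa_a %in% rownames(sim), aa_a, "X")
  aa_b <- ifelse(aa_b %in% rownames(sim), aa_b, "X")
  params$w_geo * exp(-d^2 / (2 * params$sigma_s^2)) +
    params$w_aa * sim[cbind(aa_a, aa_b)]
}

# self-score contribution of each residue (identity correspondence, d = 0)
self_column_scores <- function(aa, params) {
  column_scores(rep(0, length(aa)), aa, aa, params)
}

# greedy one-to-one matching of rows/cols of a distance matrix below a
# cutoff; smallest distance first, ties by lower (row, col) index pair
greedy_match <- function(dmat, cutoff) {
  idx <- which(dmat < cutoff)
  if (length(idx) == 0L)
    return(matrix(integer(0), 0, 2))
  nr <- nrow(dmat)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  o <- order(dmat[idx], ri, ci)
  ri <- ri[o]; ci <- ci[o]
  used_r <- logical(nr); used_c <- logical(ncol(dmat))
  keep <- logical(length(ri))
  for (k in seq_along(ri)) {
    if (!used_r[ri[k]] && !used_c[ci[k]]) {
      keep[k] <- TRUE
      used_r[ri[k]] <- TRUE
      used_c[ci[k]] <- TRUE
    }
  }
  cbind(ri[keep], ci[keep])
}

#' Align two structure models in space
#'
#' Finds a one-to-one residue correspondence between two C-alpha traces by
#' seeded iterative closest-residue superposition: gapless fragments of
#' `frag_len` residues are superposed in all stride-sampled combinations,
#' low-RMSD seeds are extended by alternating greedy spatial pairing
#' (within `pair_cutoff`) and Kabsch re-superposition until the pair set
#' is stable, and the seed with the highest total score wins. The
#' correspondence search is blind to sequence order, so permuted domains
#' are handled.
#'
#' The score is column-additive: each matched pair contributes
#' `w_geo * exp(-d^2 / (2 sigma_s^2)) + w_aa * aa_sim`, with `d` the
#' inter-C-alpha distance after superposition and `aa_sim` a BLOSUM62
#' similarity rescaled to `[0, 1]`. The self-score `S(a, a)` is this score
#' on the identity correspondence, which is the attainable maximum.
#'
#' @param a,b [structure_model] objects with at least `min_core_len`
#'   residues.
#' @param params An [align_params] list.
#' @return A list with `pairs` (m x 2 matrix of residue positions in `a`
#'   and `b`), `score` (S(a, b)), `rmsd` (Angstrom over matched pairs),
#'   `self_a`, `self_b` (self-scores over all residues) and
#'   `superposition`.
#' @export
align_pair <- function(a, b, params = align_params()) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  na <- n_residues(a); nb <- n_residues(b)
  if (na < params$min_core_len || nb < params$min_core_len)
    stop("models shorter than min_core_len (", params$min_core_len, ")")
  A <- a$xyz; B <- b$xyz
  fl <- params$frag_len
  sa <- seq(1L, na - fl + 1L, by = params$frag_stride)
  sb <- seq(1L, nb - fl + 1L, by = params$frag_stride)
  seeds <- expand.grid(ia = sa, ib = sb)
  frag_rmsd <- vapply(seq_len(nrow(seeds)), function(k) {
    i <- seeds$ia[k]; j <- seeds$ib[k]
    kabsch_superpose(A[i:(i + fl - 1L), ], B[j:(j + fl - 1L), ])$rmsd
  }, numeric(1))
  keep <- which(frag_rmsd < params$seed_rmsd_max)
  keep <- keep[order(frag_rmsd[keep])]
  if (length(keep) > params$max_seeds) keep <- keep[seq_len(params$max_seeds)]
  if (length(keep) == 0L)
    stop("alignment failure: no seed fragment below ",
         params$seed_rmsd_max, " A between '", a$model_id, "' and '",
         b$model_id, "'")

  best <- NULL
  for (k in keep) {
    i <- seeds$ia[k]; j <- seeds$ib[k]
    sp <- kabsch_superpose(A[i:(i + fl - 1L), ], B[j:(j + fl - 1L), ])
    pairs_prev <- NULL
    pairs <- cbind(i:(i + fl - 1L), j:(j + fl - 1L))
    for (it in seq_len(params$max_iter)) {
      Bt <- apply_superposition(sp, B)
      pairs <- greedy_match(cross_dist(A, Bt), params$pair_cutoff)
      if (nrow(pairs) < 3L) { pairs <- NULL; break }
      if (!is.null(pairs_prev) && identical(pairs, pairs_prev)) break
      pairs_prev <- pairs
      sp <- kabsch_superpose(A[pairs[, 1], , drop = FALSE],
                             B[pairs[, 2], , drop = FALSE])
    }
    if (is.null(pairs)) next
    sp <- kabsch_superpose(A[pairs[, 1], , drop = FALSE],
                           B[pairs[, 2], , drop = FALSE])
    Bt <- apply_superposition(sp, B)
    d <- sqrt(rowSums((A[pairs[, 1], , drop = FALSE] -
                         Bt[pairs[, 2], , drop = FALSE])^2))
    score <- sum(column_scores(d, a$aa[pairs[, 1]], b$aa[pairs[, 2]],
                               params))
    if (is.null(best) || score > best$score)
      best <- list(pairs = pairs, score = score, rmsd = sp$rmsd,
                   superposition = sp)
  }
  if (is.null(best) || nrow(best$pairs) < params$min_core_len)
    stop("alignment failure: no correspondence of >= ",
         params$min_core_len, " residues between '", a$model_id,
         "' and '", b$model_id, "'")
  # order pairs by position in a for reproducible downstream merging
  o <- order(best$pairs[, 1])
  best$pairs <- best$pairs[o, , drop = FALSE]
  best$self_a <- sum(self_column_scores(a$aa, params))
  best$self_b <- sum(self_column_scores(b$aa, params))
  best
}
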