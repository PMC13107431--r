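#' Jackknife configuration
#'
#' @param fraction Fraction of core columns sampled per replicate, in
#'   `(0, 1]` (default 0.5, the calibrated sampling level).
#' @param replicates Number of replicates (default 100).
#' @param mode `"block"` (contiguous runs of core columns, default) or
#'   `"site"` (independent random columns).
#' @param min_block Minimum block length in columns (default 10).
#' @param seed Integer seed driving all resampling.
#' @return A list of class `jackknife_config`.
#' @export
jackknife_config <- function(fraction = 0.5, replicates = 100L,
                             mode = c("block", "site"), min_block = 10L,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  structure(list(fraction = fraction, replicates = as.integer(replicates),
                 mode = mode, min_block = as.integer(min_block),
                 seed = as.integer(seed)),
            class = "jackknife_config")
}

#' Sample individual core columns at random
#'
#' Draws `round(fraction * core_len)` distinct column indices uniformly
#' without replacement.
#'
#' @param core_len Number of core columns.
#' @param fraction Sampling fraction in `(0, 1]`.
#' @return Sorted integer vector of column indices.
#' @export
sample_sites <- function(core_len, fraction) {
  k <- round(fraction * core_len)
  if (k < 1) stop("sampling fraction selects zero columns")
  if (k > core_len) stop("fraction exceeds 1")
  sort(sample.int(core_len, k))
}

#' Sample contiguous blocks of core columns
#'
#' Selects `round(fraction * core_len)` columns as a union of
#' non-overlapping contiguous blocks. Block lengths are drawn uniformly
#' between `min_block` and the remaining quota; when the final remaining
#' quota is smaller than `min_block`, one final block of exactly that
#' remainder is placed so the sampled cardinality is exact. Start
#' positions are uniform over the placements that fit the unselected
#' gaps; a dead-ended configuration is restarted, up to `max_tries`
#' attempts.
#'
#' @param core_len Number of core columns.
#' @param fraction Sampling fraction; `round(fraction * core_len)` must be
#'   at least `min_block`.
#' @param min_block Minimum block length (default 10).
#' @param max_tries Restart budget before giving up (default 1000).
#' @return Sorted integer vector of column indices.
#' @export
sample_blocks <- function(core_len, fraction, min_block = 10L,
                          max_tries = 1000L) {
  k <- round(fraction * core_len)
  if (k > core_len) stop("fraction exceeds 1")
  if (k < min_block)
    stop("quota ", k, " is below the minimum block length ", min_block,
         "; lower min_block or raise the fraction")
  if (k == core_len) return(seq_len(core_len))
  for (try in seq_len(max_tries)) {
    sel <- logical(core_len)
    quota <- k
    ok <- TRUE
    while (quota > 0L) {
      L <- if (quota < min_block) quota else
        sample.int(quota - min_block + 1L, 1L) + min_block - 1L
      # legal starts: block of length L fits an unselected gap
      runs <- rle(!sel)
      ends <- cumsum(runs$lengths)
      starts_gap <- ends - runs$lengths + 1L
      gap_i <- which(runs$values & runs$lengths >= L)
      if (length(gap_i) == 0L) { ok <- FALSE; break }
      legal <- unlist(lapply(gap_i, function(g)
        starts_gap[g]:(ends[g] - L + 1L)))
      s <- legal[sample.int(length(legal), 1L)]
      sel[s:(s + L - 1L)] <- TRUE
      quota <- quota - L
    }
    if (ok) return(which(sel))
  }
  stop("could not place blocks after ", max_tries,
       " attempts; try a lower sampling fraction")
}

# derive independent replicate seeds from the run seed
replicate_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# one replicate: sample columns, rescore, distance, NJ
jackknife_replicate <- function(scores, core_len, config, rep_seed) {
  cols <- withr::with_seed(rep_seed, {
    if (config$mode == "site") sample_sites(core_len, config$fraction)
    else sample_blocks(core_len, config$fraction, config$min_block)
  })
  S <- restrict_scores(scores, cols)
  D <- score_to_distance(S)
  suppressMessages(neighbor_joining(D))
}

#' Jackknife branch support for a structure-based tree
#'
#' Resamples the core columns `replicates` times (per `config$mode`),
#' recomputes the score matrix, distances and neighbor-joining tree for
#' each replicate, and maps the replicate agreement onto the reference
#' tree (built from the full core) as percentage support per internal
#' edge. Deterministic given `config$seed`.
#'
#' @param scores A `score_matrix` from [build_core].
#' @param config A [jackknife_config].
#' @param reference Optional reference `phylo`; defaults to the NJ tree
#'   of the full score matrix.
#' @return A list with `tree` (reference with supports), `replicates`
#'   (list of `phylo`) and `config`.
#' @export
jackknife_support <- function(scores, config = jackknife_config(),
                              reference = NULL) {
  stopifnot(inherits(scores, "score_matrix"),
            inherits(config, "jackknife_config"))
  core_len <- ncol(scores$contrib)
  if (is.null(reference))
    reference <- suppressMessages(neighbor_joining(score_to_distance(scores)))
  seeds <- replicate_seeds(config$seed, config$replicates)
  reps <- lapply(seeds, function(s)
    jackknife_replicate(scores, core_len, config, s))
  list(tree = map_support(reference, reps), replicates = reps,
       config = config)
}

#' Sampling-fraction sweep
#'
#' For each sampling fraction, generates `replicates` jackknife replicate
#' trees and reports the mean and standard deviation of their normalized
#' Robinson-Foulds distance to the reference tree. Used to locate the
#' fraction beyond which the topology stops changing appreciably; the
#' smallest fraction whose mean RF changes by less than `stable_tol` to
#' the next fraction is reported as `stable_fraction` (advisory).
#'
#' @param scores A `score_matrix` from [build_core].
#' @param fractions Increasing fractions to evaluate (default 0.1-0.9 by
#'   0.1).
#' @param replicates Replicates per fraction (default 100).
#' @param mode `"site"` or `"block"`.
#' @param min_block Minimum block length for block mode.
#' @param seed Run seed.
#' @param stable_tol Advisory stabilization tolerance on `|delta mean RF|`
#'   (default 0.02).
#' @return A `data.frame` with columns `fraction`, `mean_rf`, `sd_rf`,
#'   `replicates`, plus attribute `stable_fraction`.
#' @export
fraction_sweep <- function(scores, fractions = seq(0.1, 0.9, by = 0.1),
                           replicates = 100L, mode = c("site", "block"),
                           min_block = 10L, seed = 1L, stable_tol = 0.02) {
  stopifnot(inherits(scores, "score_matrix"))
  mode <- match.arg(mode)
  if (is.unsorted(fractions, strictly = TRUE))
    stop("fractions must be strictly increasing")
  reference <- suppressMessages(neighbor_joining(score_to_distance(scores)))
  core_len <- ncol(scores$contrib)
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    config <- jackknife_config(fraction = f, replicates = replicates,
                               mode = mode, min_block = min_block,
                               seed = seed)
    # distinct substream per fraction, common across modes for pairing
    seeds <- replicate_seeds(seed + 7919L * fi, replicates)
    rf <- vapply(seeds, function(s) {
      tr <- jackknife_replicate(scores, core_len, config, s)
      rf_distance(reference, tr, normalized = TRUE)
    }, numeric(1))
    data.frame(fraction = f, mean_rf = mean(rf), sd_rf = stats::sd(rf),
               replicates = replicates)
  })
  out <- do.call(rbind, rows)
  stable <- NA_real_
  if (nrow(out) > 1) {
    deltas <- abs(diff(out$mean_rf))
    hit <- which(deltas < stable_tol)
    if (length(hit)) stable <- out$fraction[hit[1]]
  }
  attr(out, "stable_fraction") <- stable
  out
}

#' Compare site and block jackknife at one fraction
#'
#' Runs both sampling modes with common replicate seeds (paired for
#' variance reduction) and reports the mean and sd of the normalized
#' Robinson-Foulds distance to the reference for each mode. Block
#' sampling removes contiguous, spatially correlated stretches of the
#' core and so perturbs the structural signal more strongly than
#' independent site removal.
#'
#' @param scores A `score_matrix` from [build_core].
#' @param fraction Sampling fraction (default 0.5).
#' @param replicates Replicates per mode (default 100).
#' @param min_block Minimum block length (default 10).
#' @param seed Run seed.
#' @return A two-row `data.frame` with columns `mode`, `mean_rf`,
#'   `sd_rf`, `replicates`.
#' @export
compare_modes <- function(scores, fraction = 0.5, replicates = 100L,
                          min_block = 10L, seed = 1L) {
  stopifnot(inherits(scores, "score_matrix"))
  reference <- suppressMessages(neighbor_joining(score_to_distance(scores)))
  core_len <- ncol(scores$contrib)
  seeds <- replicate_seeds(seed, replicates)
  one_mode <- function(mode) {
    config <- jackknife_config(fraction = fraction, replicates = replicates,
                               mode = mode, min_block = min_block,
                               seed = seed)
    rf <- vapply(seeds, function(s) {
      tr <- jackknife_replicate(scores, core_len, config, s)
      rf_distance(reference, tr, normalized = TRUE)
    }, numeric(1))
    data.frame(mode = mode, mean_rf = mean(rf), sd_rf = stats::sd(rf),
               replicates = replicates, stringsAsFactors = FALSE)
  }
  rbind(one_mode("site"), one_mode("block"))
}
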