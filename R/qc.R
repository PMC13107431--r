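#' Trim low-confidence termini with a sliding window
#'
#' Scans from each end of the chain with a window of `window` residues and
#' keeps the span from the first position where every residue in the
#' window has pLDDT strictly above `threshold`, through the last such
#' position at the C-terminus. This removes disordered terminal tails that
#' AlphaFold typically models with low confidence. If no window qualifies
#' the returned model is empty and carries the rejection reason in
#' `attr(, "reason")`.
#'
#' @param model A [structure_model] with at least `window` residues.
#' @param window Window length in residues (default 15).
#' @param threshold pLDDT threshold; a window qualifies when all its
#'   residues are strictly above it (default 70).
#' @return The trimmed [structure_model].
#' @export
trim_termini <- function(model, window = 15L, threshold = 70) {
  stopifnot(inherits(model, "structure_model"))
  n <- n_residues(model)
  if (n < window)
    stop("too short for window: model '", model$model_id, "' has ", n,
         " residues < window ", window)
  ok <- model$plddt > threshold
  # window starting at p qualifies iff all of ok[p..p+window-1]
  run <- stats::filter(as.numeric(ok), rep(1, window), sides = 1)
  starts <- which(run[window:n] == window)  # qualifying window start positions
  if (length(starts) == 0L) {
    out <- subset_residues(model, integer(0))
    attr(out, "reason") <- "no qualifying window"
    return(out)
  }
  p <- starts[1]
  q <- starts[length(starts)] + window - 1L
  subset_residues(model, p:q)
}

#' Confidence-fraction quality filter
#'
#' Computes, on a terminally trimmed model, the fraction of residues with
#' pLDDT below `low` and below `mid`. The model passes unless either
#' fraction strictly exceeds its maximum (the thresholds are read as
#' "higher than", so exact boundary values pass).
#'
#' @param model A [structure_model], normally the output of [trim_termini].
#' @param low,mid pLDDT cutoffs (defaults 50 and 70).
#' @param max_low_frac,max_mid_frac Maximum tolerated fractions below
#'   `low` and `mid` (defaults 0.05 and 0.10).
#' @return A one-row `data.frame` (class `qc_report`) with columns
#'   `model_id`, `n_before`, `n_after_terminal_trim`, `frac_below_50`,
#'   `frac_below_70`, `passed`, `n_removed_low`, `reasons`.
#' @export
qc_filter <- function(model, low = 50, mid = 70,
                      max_low_frac = 0.05, max_mid_frac = 0.10) {
  stopifnot(inherits(model, "structure_model"))
  n <- n_residues(model)
  if (n == 0L) {
    return(qc_report_row(model$model_id, 0L, 0L, NA_real_, NA_real_,
                         FALSE, 0L, "empty after trimming"))
  }
  f_low <- mean(model$plddt < low)
  f_mid <- mean(model$plddt < mid)
  passed <- (f_low <= max_low_frac) && (f_mid <= max_mid_frac)
  reasons <- character()
  if (f_low > max_low_frac)
    reasons <- c(reasons, sprintf("frac pLDDT<%g = %.3f > %.3f",
                                  low, f_low, max_low_frac))
  if (f_mid > max_mid_frac)
    reasons <- c(reasons, sprintf("frac pLDDT<%g = %.3f > %.3f",
                                  mid, f_mid, max_mid_frac))
  qc_report_row(model$model_id, n, n, f_low, f_mid, passed, 0L,
                paste(reasons, collapse = "; "))
}

qc_report_row <- function(model_id, n_before, n_after, f50, f70, passed,
                          n_removed, reasons) {
  out <- data.frame(
    model_id = model_id, n_before = n_before,
    n_after_terminal_trim = n_after,
    frac_below_50 = f50, frac_below_70 = f70,
    passed = passed, n_removed_low = n_removed,
    reasons = reasons, stringsAsFactors = FALSE
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Remove residues below a pLDDT cutoff
#'
#' Drops every residue with pLDDT strictly below `cutoff` (default 50),
#' preserving the order of the survivors. Interior removals leave a gapped
#' C-alpha trace; downstream alignment is sequence-order independent and
#' accepts such gaps.
#'
#' @param model A [structure_model] that passed [qc_filter].
#' @param cutoff pLDDT removal cutoff (default 50; strictly below).
#' @return The filtered [structure_model].
#' @export
drop_low_confidence <- function(model, cutoff = 50) {
  stopifnot(inherits(model, "structure_model"))
  keep <- which(model$plddt >= cutoff)
  if (length(keep) == 0L)
    stop("model '", model$model_id, "' has no residues with pLDDT >= ",
         cutoff)
  if (length(keep) == n_residues(model)) return(model)
  subset_residues(model, keep)
}

#' Trim a model to an annotated region plus a margin
#'
#' Retains residues in `[max(1, start - margin), min(N, end + margin)]`,
#' the rule used to restrict very large models to the domain of interest
#' (e.g. an annotated polymerase region) with a generous flank.
#'
#' @param model A [structure_model].
#' @param start,end Region bounds in internal numbering, `1 <= start <=
#'   end <= N`.
#' @param margin Residues added on both sides (default 200).
#' @return The trimmed [structure_model] (unchanged when the window covers
#'   the whole model).
#' @export
trim_to_region <- function(model, start, end, margin = 200L) {
  stopifnot(inherits(model, "structure_model"))
  n <- n_residues(model)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end)
    stop("invalid region [", start, ", ", end, "] for model of length ", n)
  lo <- max(1L, start - margin)
  hi <- min(n, end + margin)
  if (lo == 1L && hi == n) return(model)
  subset_residues(model, lo:hi)
}

#' Run the full quality-control chain on a set of models
#'
#' Applies, per model: [trim_termini] then [qc_filter] then (for passing
#' models) [drop_low_confidence]. A report row is produced for every input
#' model, including those rejected; failures never abort the batch.
#'
#' @param models List of [structure_model] objects with unique `model_id`s.
#' @param window,threshold Passed to [trim_termini].
#' @param low,mid,max_low_frac,max_mid_frac Passed to [qc_filter];
#'   `low` is also the [drop_low_confidence] cutoff.
#' @return A list with `models` (passing models after residue removal,
#'   named by `model_id`) and `report` (a `qc_report` data frame, one row
#'   per input).
#' @export
qc_batch <- function(models, window = 15L, threshold = 70, low = 50,
                     mid = 70, max_low_frac = 0.05, max_mid_frac = 0.10) {
  if (length(models) == 0L)
    return(list(models = list(),
                report = qc_report_row(character(0), integer(0), integer(0),
                                       numeric(0), numeric(0), logical(0),
                                       integer(0), character(0))))
  check_unique_ids(models)
  rows <- vector("list", length(models))
  passed <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    n0 <- n_residues(m)
    trimmed <- tryCatch(trim_termini(m, window, threshold),
                        error = function(e) e)
    if (inherits(trimmed, "error")) {
      rows[[i]] <- qc_report_row(m$model_id, n0, 0L, NA_real_, NA_real_,
                                 FALSE, 0L, "too short for window")
      next
    }
    rep <- qc_filter(trimmed, low, mid, max_low_frac, max_mid_frac)
    rep$n_before <- n0
    rep$n_after_terminal_trim <- n_residues(trimmed)
    if (!is.null(attr(trimmed, "reason")) && !nzchar(rep$reasons))
      rep$reasons <- attr(trimmed, "reason")
    if (rep$passed) {
      final <- tryCatch(drop_low_confidence(trimmed, cutoff = low),
                        error = function(e) e)
      if (inherits(final, "error")) {
        rep$passed <- FALSE
        rep$reasons <- "empty after low-confidence removal"
      } else {
        rep$n_removed_low <- n_residues(trimmed) - n_residues(final)
        passed[[m$model_id]] <- final
      }
    }
    rows[[i]] <- rep
  }
  list(models = passed, report = do.call(rbind, rows))
}
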