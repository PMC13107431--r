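#' Construct a structure model (ordered C-alpha trace with confidence)
#'
#' A `structure_model` is the basic unit of this package: one polypeptide
#' chain reduced to its C-alpha trace, with a per-residue confidence score
#' (pLDDT, on the AlphaFold 0-100 scale) and one-letter amino-acid codes.
#' Residues are numbered internally 1..N in chain order; any original
#' author numbering is kept in `meta`.
#'
#' @param model_id Unique identifier within a dataset (non-empty string).
#' @param xyz Numeric matrix, N x 3, C-alpha coordinates in Angstrom.
#' @param aa Character vector of N one-letter amino-acid codes (`"X"` for
#'   unknown residues).
#' @param plddt Numeric vector of N confidence scores in `[0, 100]`.
#' @param label Display/taxon label; defaults to `model_id`.
#' @param meta Named list of free-form metadata (e.g. original residue
#'   numbering, taxonomy, ground-truth correspondences for simulated data).
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, xyz, aa, plddt, label = model_id,
                            meta = list()) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("'xyz' must be an N x 3 coordinate matrix")
  n <- nrow(xyz)
  aa <- as.character(aa)
  plddt <- as.numeric(plddt)
  if (length(aa) != n || length(plddt) != n)
    stop("'aa' and 'plddt' must match the number of coordinate rows")
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id))
    stop("'model_id' must be a non-empty string")
  if (n > 0 && (any(!is.finite(xyz))))
    stop("coordinates must be finite")
  if (n > 0 && (any(plddt < 0) || any(plddt > 100)))
    stop("pLDDT values must lie in [0, 100]")
  dimnames(xyz) <- NULL
  structure(
    list(model_id = model_id, label = label, xyz = xyz, aa = aa,
         plddt = plddt, seq_index = seq_len(n), meta = meta),
    class = "structure_model"
  )
}

#' Number of residues in a structure model
#' @param x A `structure_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "structure_model"))
  nrow(x$xyz)
}

#' Subset a structure model by residue positions
#'
#' Positions refer to the current internal numbering (1..N); the result is
#' renumbered 1..length(keep) and remembers the positions kept relative to
#' the object it was subset from in `meta$parent_index`.
#'
#' @param x A `structure_model`.
#' @param keep Integer vector of positions to retain, in increasing order.
#' @return A `structure_model` with the selected residues.
#' @export
subset_residues <- function(x, keep) {
  stopifnot(inherits(x, "structure_model"))
  keep <- as.integer(keep)
  if (length(keep) && (min(keep) < 1L || max(keep) > n_residues(x)))
    stop("positions out of range")
  if (is.unsorted(keep, strictly = TRUE))
    stop("'keep' must be strictly increasing")
  meta <- x$meta
  # compose with any previous subsetting so meta always maps to the
  # residues of the originally read model
  meta$parent_index <- if (is.null(meta$parent_index)) keep else
    meta$parent_index[keep]
  if (!is.null(meta$truth)) meta$truth <- meta$truth[keep]
  if (!is.null(meta$auth_resno)) meta$auth_resno <- meta$auth_resno[keep]
  structure_model(x$model_id, x$xyz[keep, , drop = FALSE], x$aa[keep],
                  x$plddt[keep], label = x$label, meta = meta)
}

#' @export
print.structure_model <- function(x, ...) {
  n <- n_residues(x)
  cat(sprintf("structure_model '%s' (%s): %d residues\n",
              x$model_id, x$label, n))
  if (n > 0) {
    cat(sprintf("  pLDDT: min %.1f / mean %.1f / max %.1f\n",
                min(x$plddt), mean(x$plddt), max(x$plddt)))
    cat(sprintf("  sequence: %s%s\n",
                paste(utils::head(x$aa, 40), collapse = ""),
                if (n > 40) "..." else ""))
  }
  invisible(x)
}

# internal: stop unless every model_id is unique
check_unique_ids <- function(models) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate model_id in dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}
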