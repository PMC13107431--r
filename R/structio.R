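#' Read a structure model from a PDB or mmCIF file
#'
#' Reads one polypeptide chain as a C-alpha trace. Per-residue confidence
#' (pLDDT) is taken from the B-factor column, following the AlphaFold
#' convention of storing pLDDT there. Residues are renumbered internally
#' 1..N in file order; the original author numbering is kept in
#' `meta$auth_resno`. Only the first-listed alternate conformer of each
#' residue is used. Residues without a C-alpha atom are skipped with a
#' warning.
#'
#' If every B-factor is zero the file is assumed to be an experimental
#' structure without pLDDT; all confidences are set to 100 (so quality
#' control becomes a no-op) and a warning is issued.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier. May be omitted when the file contains
#'   exactly one chain; with several chains an omitted `chain` is an error.
#' @param model_id Identifier for the model; defaults to the file stem.
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) {
      suppressWarnings(bio3d::read.cif(path))
    } else {
      bio3d::read.pdb(path)
    },
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM") & atoms$elety == "CA" &
                   !is.na(atoms$x), , drop = FALSE]
  # drop calcium ions that also carry atom name CA
  atoms <- atoms[atoms$resid != "CA", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("file contains chains ", paste(chains, collapse = ", "),
           "; specify 'chain'")
    chain <- chains
  }
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  # first-listed altloc only
  if ("alt" %in% names(atoms) && any(!is.na(atoms$alt) & atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert)
    atoms <- atoms[!duplicated(key), , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("no residues with a C-alpha atom in '", path, "'")

  # count residues present in the full record but lacking a CA
  full <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM") &
                     pdb$atom$chain %in% chain &
                     pdb$atom$resid != "HOH", , drop = FALSE]
  n_res_all <- length(unique(paste(full$resno, full$insert)))
  if (n_res_all > nrow(atoms))
    warning(n_res_all - nrow(atoms),
            " residue(s) without a C-alpha atom skipped in '", path, "'")

  aa <- suppressWarnings(bio3d::aa321(atoms$resid))
  aa[is.na(aa) | !aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])] <- "X"
  plddt <- atoms$b
  if (all(is.na(plddt)) || all(plddt == 0)) {
    warning("all B-factors are zero in '", path,
            "'; assuming experimental structure, setting pLDDT = 100")
    plddt <- rep(100, nrow(atoms))
  }
  plddt[is.na(plddt)] <- 100
  plddt <- pmin(pmax(plddt, 0), 100)
  if (is.null(model_id))
    model_id <- tools::file_path_sans_ext(basename(path))
  structure_model(
    model_id = model_id,
    xyz = as.matrix(atoms[, c("x", "y", "z")]),
    aa = aa, plddt = plddt,
    meta = list(auth_resno = atoms$resno, chain = chain[1], source = path)
  )
}

#' Write a structure model to PDB or mmCIF
#'
#' Emits the C-alpha trace with pLDDT in the B-factor column. PDB output
#' follows the fixed-width ATOM record convention (coordinates to three
#' decimals); mmCIF output writes an `atom_site` loop. A written model
#' reads back with [read_structure] field-for-field (coordinates within
#' PDB precision).
#'
#' @param model A non-empty [structure_model].
#' @param path Output file path.
#' @param format `"pdb"` or `"cif"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  stopifnot(inherits(model, "structure_model"))
  if (n_residues(model) == 0L) stop("cannot write an empty model")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  n <- n_residues(model)
  resid3 <- vapply(model$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || a == "X") "UNK" else r
  }, character(1))
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(model$xyz)),
      resno = model$seq_index,
      resid = resid3,
      elety = rep("CA", n),
      chain = rep("A", n),
      o = rep(1, n),
      b = model$plddt
    )
  } else {
    write_minimal_cif(model, resid3, path)
  }
  invisible(path)
}

# minimal mmCIF atom_site writer (CA trace only); bio3d reads it back
write_minimal_cif <- function(model, resid3, path) {
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_.-]", "_", model$model_id)),
    "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num"))
  )
  n <- n_residues(model)
  rows <- sprintf(
    "ATOM %d C CA . %s A 1 %d ? %s %s %s 1.00 %.2f ? %d %s A CA 1",
    seq_len(n), resid3, model$seq_index,
    format(model$xyz[, 1], trim = TRUE, nsmall = 3, digits = 10),
    format(model$xyz[, 2], trim = TRUE, nsmall = 3, digits = 10),
    format(model$xyz[, 3], trim = TRUE, nsmall = 3, digits = 10),
    model$plddt, model$seq_index, resid3
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows, "#"), con)
  invisible(path)
}

#' Read all structure models in a directory
#'
#' Convenience wrapper over [read_structure] for `.pdb`, `.cif` and
#' `.mmcif` files. Unreadable files are skipped with a warning and listed
#' in the `failed` attribute of the result.
#'
#' @param dir Directory containing structure files.
#' @param chain Optional chain identifier passed to [read_structure].
#' @return A named list of [structure_model] objects.
#' @export
read_structure_dir <- function(dir, chain = NULL) {
  files <- list.files(dir, pattern = "\\.(pdb|cif|mmcif)$",
                      ignore.case = TRUE, full.names = TRUE)
  models <- list()
  failed <- character()
  for (f in sort(files)) {
    m <- tryCatch(read_structure(f, chain = chain), error = function(e) {
      warning("skipping '", f, "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(m)) failed <- c(failed, f) else models[[m$model_id]] <- m
  }
  check_unique_ids(models)
  attr(models, "failed") <- failed
  models
}
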