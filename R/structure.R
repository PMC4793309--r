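# Structure model and PDB input/output.
#
# A `Structure` holds one protein chain set as two flat tables: a residue
# table (one row per polymer residue, with its Calpha position) and an atom
# table (all polymer atoms), plus a list of bound non-polymer groups
# ("ligands"). Coordinates are in Angstrom; author residue numbering from the
# source file is retained.

#' Construct a Structure object
#'
#' Low-level constructor used by [parse_pdb()] and the synthetic-structure
#' generators. Most users never call this directly.
#'
#' @param struct_id Character scalar identifying the structure (PDB ID or
#'   synthetic ID); must be unique within a database.
#' @param residues Data frame with one row per polymer residue and columns
#'   `chain`, `seqno`, `ins`, `resname`.
#' @param atoms Data frame of polymer atoms with columns `res_idx` (row index
#'   into `residues`), `name`, `element`, `x`, `y`, `z`, `is_h`.
#' @param ligands List of ligand groups as returned by [new_ligand()].
#' @return An object of class `Structure` with derived fields `aa1` (per
#'   residue one-letter code) and `sequence`.
#' @export
new_structure <- function(struct_id, residues, atoms, ligands = list()) {
  stopifnot(is.character(struct_id), length(struct_id) == 1L, nzchar(struct_id))
  residues <- as.data.frame(residues)
  atoms <- as.data.frame(atoms)
  if (nrow(residues) == 0L) stop("empty structure: no polymer residues")
  residues$resname <- toupper(residues$resname)
  residues$aa1 <- aa321(residues$resname)
  if (!"ins" %in% names(residues)) residues$ins <- ""
  ca <- ca_table(residues, atoms)
  residues$ca_x <- ca[, 1]
  residues$ca_y <- ca[, 2]
  residues$ca_z <- ca[, 3]
  x <- list(
    struct_id = struct_id,
    residues = residues,
    atoms = atoms,
    ligands = ligands,
    sequence = paste0(residues$aa1, collapse = "")
  )
  class(x) <- "Structure"
  validate_structure(x)
}

validate_structure <- function(x) {
  stopifnot(inherits(x, "Structure"))
  if (nchar(x$sequence) != nrow(x$residues)) {
    stop("sequence length must equal polymer residue count")
  }
  if (nrow(x$atoms) > 0L) {
    bad <- !is.finite(x$atoms$x) | !is.finite(x$atoms$y) | !is.finite(x$atoms$z)
    if (any(bad)) stop("non-finite atom coordinates")
  }
  if (anyNA(x$residues$ca_x)) stop("polymer residue without Calpha")
  x
}

ca_table <- function(residues, atoms) {
  out <- matrix(NA_real_, nrow(residues), 3)
  idx <- which(atoms$name == "CA")
  out[atoms$res_idx[idx], ] <- cbind(atoms$x[idx], atoms$y[idx], atoms$z[idx])
  out
}

#' Construct a ligand group
#'
#' @param resname 3-letter residue code of the group.
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `is_h`.
#' @param chain,seqno Author chain identifier and residue number.
#' @return An object of class `Ligand`.
#' @export
new_ligand <- function(resname, atoms, chain = "A", seqno = 1L) {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) == 0L) stop("ligand with no atoms")
  x <- list(resname = toupper(resname), chain = chain, seqno = as.integer(seqno),
            atoms = atoms)
  class(x) <- "Ligand"
  x
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure %s: %d residues, %d atoms, %d ligand(s)>\n",
              x$struct_id, nrow(x$residues), nrow(x$atoms), length(x$ligands)))
  invisible(x)
}

#' Calpha coordinate matrix of a structure
#'
#' @param structure A `Structure`.
#' @param idx Optional residue indices (default: all residues).
#' @return Numeric n x 3 matrix of Calpha coordinates in Angstrom.
#' @export
ca_coords <- function(structure, idx = NULL) {
  r <- structure$residues
  if (!is.null(idx)) r <- r[idx, , drop = FALSE]
  m <- cbind(r$ca_x, r$ca_y, r$ca_z)
  rownames(m) <- NULL
  m
}

#' Heavy (non-hydrogen) polymer atoms of a structure
#'
#' @param structure A `Structure`.
#' @return Data frame of polymer atoms with `is_h == FALSE`.
#' @export
heavy_atoms <- function(structure) {
  structure$atoms[!structure$atoms$is_h, , drop = FALSE]
}

ligand_heavy_coords <- function(ligand) {
  a <- ligand$atoms[!ligand$atoms$is_h, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

#' Read a protein structure from a PDB file
#'
#' Parses the first model only; alternate locations other than blank/'A' and
#' water molecules are discarded. Polymer residues lacking a Calpha atom are
#' dropped with a warning. Hydrogens are retained in the atom table but
#' flagged (`is_h`), and are excluded from all distance-based operations.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param keep_hetero Keep HETATM groups as ligands (default `TRUE`).
#' @param struct_id Identifier for the structure; defaults to the file base
#'   name.
#' @return A [new_structure()] `Structure`.
#' @export
parse_pdb <- function(path, keep_hetero = TRUE, struct_id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error for ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[!(toupper(at$resid) %in% WATER_NAMES), , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms after water removal in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  is_h <- toupper(at$elesy) == "H" | grepl("^[0-9]*H", toupper(at$elety))

  pol <- at$type == "ATOM"
  if (!any(pol)) stop("empty structure (no polymer ATOM records) in ", path)
  pa <- at[pol, , drop = FALSE]
  key <- paste(pa$chain, pa$resno, pa$insert, pa$resid, sep = "|")
  ukey <- unique(key)
  res_idx <- match(key, ukey)
  first <- !duplicated(key)
  residues <- data.frame(
    chain = pa$chain[first], seqno = as.integer(pa$resno[first]),
    ins = pa$insert[first], resname = toupper(pa$resid[first]),
    stringsAsFactors = FALSE)
  atoms <- data.frame(
    res_idx = res_idx, name = pa$elety, element = toupper(pa$elesy),
    x = pa$x, y = pa$y, z = pa$z, is_h = is_h[pol],
    stringsAsFactors = FALSE)

  # drop polymer residues without a Calpha
  has_ca <- sort(unique(atoms$res_idx[atoms$name == "CA"]))
  if (length(has_ca) < nrow(residues)) {
    dropped <- setdiff(seq_len(nrow(residues)), has_ca)
    warning(sprintf("%s: dropping %d polymer residue(s) without Calpha",
                    basename(path), length(dropped)))
    keep <- atoms$res_idx %in% has_ca
    atoms <- atoms[keep, , drop = FALSE]
    atoms$res_idx <- match(atoms$res_idx, has_ca)
    residues <- residues[has_ca, , drop = FALSE]
    rownames(residues) <- NULL
  }
  if (nrow(residues) == 0L) stop("empty structure (no Calpha residues) in ", path)

  ligands <- list()
  if (keep_hetero && any(!pol)) {
    ha <- at[!pol, , drop = FALSE]
    hh <- is_h[!pol]
    lkey <- paste(ha$chain, ha$resno, ha$insert, ha$resid, sep = "|")
    for (k in unique(lkey)) {
      sel <- lkey == k
      g <- ha[sel, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <- new_ligand(
        resname = g$resid[1], chain = g$chain[1], seqno = g$resno[1],
        atoms = data.frame(name = g$elety, element = toupper(g$elesy),
                           x = g$x, y = g$y, z = g$z, is_h = hh[sel],
                           stringsAsFactors = FALSE))
    }
  }
  new_structure(struct_id %||% sub("\\.(pdb|ent)$", "", basename(path)),
                residues, atoms, ligands)
}

pdb_atom_line <- function(serial, name, resname, chain, seqno, ins, x, y, z,
                          element, het = FALSE) {
  nm <- if (nchar(name) < 4L) paste0(" ", formatC(name, width = -3)) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial %% 100000L, nm, "",
          substr(resname, 1, 3), substr(chain, 1, 1), seqno %% 10000L,
          substr(paste0(ins, " "), 1, 1), x, y, z, 1, 0, element)
}

#' Write a Structure to a PDB file
#'
#' Inverse of [parse_pdb()] up to coordinate rounding at 1e-3 Angstrom; the
#' synthetic-structure generators use it so every module consumes fixtures
#' through the normal reader.
#'
#' @param structure A `Structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- character(0)
  serial <- 0L
  a <- structure$atoms
  r <- structure$residues
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    ri <- a$res_idx[i]
    lines <- c(lines, pdb_atom_line(serial, a$name[i], r$resname[ri],
                                    r$chain[ri], r$seqno[ri], r$ins[ri],
                                    a$x[i], a$y[i], a$z[i], a$element[i]))
  }
  lines <- c(lines, "TER")
  for (lig in structure$ligands) {
    la <- lig$atoms
    for (i in seq_len(nrow(la))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, la$name[i], lig$resname,
                                      lig$chain, lig$seqno, "", la$x[i],
                                      la$y[i], la$z[i], la$element[i],
                                      het = TRUE))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Bundle structures into a searchable database
#'
#' @param structures List of `Structure` objects with unique `struct_id`s.
#' @param meta Optional character provenance note.
#' @return An object of class `StructureDB`.
#' @export
structure_db <- function(structures, meta = NULL) {
  ids <- vapply(structures, function(s) s$struct_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate struct_ids in database")
  x <- list(structures = structures, ids = ids, meta = meta)
  class(x) <- "StructureDB"
  x
}

#' @export
print.StructureDB <- function(x, ...) {
  cat(sprintf("<StructureDB: %d structure(s)>\n", length(x$structures)))
  invisible(x)
}

#' @export
length.StructureDB <- function(x) length(x$structures)

#' Read every PDB file in a directory into a StructureDB
#'
#' @param dir Directory containing `.pdb` files.
#' @param keep_hetero Passed to [parse_pdb()].
#' @return A [structure_db()].
#' @export
read_structure_dir <- function(dir, keep_hetero = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.(pdb|ent)$", full.names = TRUE))
  if (length(files) == 0L) stop("no PDB files found in ", dir)
  structure_db(lapply(files, parse_pdb, keep_hetero = keep_hetero),
               meta = paste("read from", dir))
}

#' Write a database manifest table
#'
#' One row per structure: `struct_id`, `n_residues`, `n_ligands`, `sequence`.
#'
#' @param db A `StructureDB`.
#' @param path Output TSV path (optional).
#' @return The manifest data frame, invisibly if written.
#' @export
db_manifest <- function(db, path = NULL) {
  m <- data.frame(
    struct_id = db$ids,
    n_residues = vapply(db$structures, function(s) nrow(s$residues), integer(1)),
    n_ligands = vapply(db$structures, function(s) length(s$ligands), integer(1)),
    sequence = vapply(db$structures, function(s) s$sequence, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(m))
  }
  m
}
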