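# Ligand binding-site definition and contact matrices.

#' Extract the binding site of a ligand
#'
#' The site is the set of polymer residues having at least one heavy atom
#' within `cutoff` Angstrom of any ligand heavy atom (the 5 Angstrom
#' heavy-atom rule), in chain order. Representative coordinates are Calpha
#' positions by default; a Cbeta mode is available for sensitivity checks
#' (Calpha is used for glycine or when no Cbeta exists).
#'
#' @param structure A `Structure`.
#' @param ligand A `Ligand` (defaults to the structure's first ligand).
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @param site_id Identifier; defaults to `<struct_id>_<ligand resname>`.
#' @param rep_atom `"CA"` (default) or `"CB"`.
#' @return An object of class `BindingSite`: residue table (with
#'   `min_dist` to the ligand), `rep_coords` matrix, one-letter `labels`.
#' @export
extract_site <- function(structure, ligand = NULL, cutoff = 5,
                         site_id = NULL, rep_atom = c("CA", "CB")) {
  rep_atom <- match.arg(rep_atom)
  stopifnot(inherits(structure, "Structure"))
  if (is.null(ligand)) {
    if (length(structure$ligands) == 0L) stop("structure has no ligand")
    ligand <- structure$ligands[[1]]
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  lc <- ligand_heavy_coords(ligand)
  if (nrow(lc) == 0L) stop("ligand has no heavy atoms")
  ha <- heavy_atoms(structure)
  d <- cross_dist(cbind(ha$x, ha$y, ha$z), lc)
  atom_min <- apply(d, 1L, min)
  res_min <- tapply(atom_min, ha$res_idx, min)
  members <- sort(as.integer(names(res_min)[res_min <= cutoff]))
  if (length(members) < 3L) {
    stop(sprintf("binding site too small: %d residue(s) within %.1f A",
                 length(members), cutoff))
  }
  res <- structure$residues[members, , drop = FALSE]
  res$res_idx <- members
  res$min_dist <- as.numeric(res_min[as.character(members)])
  rep_coords <- ca_coords(structure, members)
  if (rep_atom == "CB") {
    for (i in seq_along(members)) {
      sel <- structure$atoms$res_idx == members[i] & structure$atoms$name == "CB"
      if (any(sel)) {
        a <- structure$atoms[which(sel)[1], ]
        rep_coords[i, ] <- c(a$x, a$y, a$z)
      }
    }
  }
  x <- list(
    site_id = site_id %||% paste0(structure$struct_id, "_", ligand$resname),
    source_struct = structure$struct_id,
    ligand_name = ligand$resname,
    residues = res,
    rep_coords = rep_coords,
    labels = res$aa1,
    cutoff = cutoff,
    rep_atom = rep_atom)
  class(x) <- "BindingSite"
  x
}

#' @export
print.BindingSite <- function(x, ...) {
  cat(sprintf("<BindingSite %s: %d residues within %.1f A of %s>\n",
              x$site_id, nrow(x$residues), x$cutoff, x$ligand_name))
  invisible(x)
}

site_size <- function(site) nrow(site$residues)

#' Contact matrix of a binding site
#'
#' All pairwise distances between the site's representative atoms; the object
#' that contact-matrix average deviation (CMAD) compares.
#'
#' @param site A `BindingSite`.
#' @return Object of class `ContactMatrix` with fields `dist` (symmetric,
#'   zero diagonal) and `labels`.
#' @export
contact_matrix <- function(site) {
  stopifnot(inherits(site, "BindingSite"))
  d <- as.matrix(stats::dist(site$rep_coords))
  dimnames(d) <- NULL
  x <- list(dist = d, labels = site$labels)
  class(x) <- "ContactMatrix"
  x
}

#' Export a binding site as a TSV table
#'
#' @param site A `BindingSite`.
#' @param path Output path (optional).
#' @return The site table data frame.
#' @export
site_table <- function(site, path = NULL) {
  r <- site$residues
  out <- data.frame(site_id = site$site_id, struct_id = site$source_struct,
                    chain = r$chain, seq_id = r$seqno, res_name = r$resname,
                    min_dist_to_ligand = round(r$min_dist, 3),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Reduce a list of query complexes to one per family
#'
#' Mirrors the redundancy rule applied to the published aspirin/salicylate
#' query complexes: within each protein family the preferred entry is kept.
#' When an entry carries `keep = TRUE` it wins its family; otherwise the
#' first-listed entry per family is kept. Input order is preserved.
#'
#' @param entries Data frame with columns `struct_id`, `family`, and
#'   optionally `keep` (logical); or a list of such records.
#' @return The kept subset of `entries` (same columns, original order).
#' @export
build_query_set <- function(entries) {
  if (!is.data.frame(entries)) {
    entries <- do.call(rbind, lapply(entries, function(e) {
      data.frame(struct_id = e$struct_id, family = e$family,
                 keep = isTRUE(e$keep), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("struct_id", "family") %in% names(entries)))
  if (anyDuplicated(entries$struct_id)) stop("duplicate struct_ids in query set")
  if (any(!nzchar(entries$family))) stop("every query complex needs a family label")
  if (!"keep" %in% names(entries)) entries$keep <- FALSE
  entries$keep[is.na(entries$keep)] <- FALSE
  chosen <- logical(nrow(entries))
  for (fam in unique(entries$family)) {
    idx <- which(entries$family == fam)
    pref <- idx[entries$keep[idx]]
    chosen[if (length(pref) > 0L) pref[1L] else idx[1L]] <- TRUE
  }
  out <- entries[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a query-set configuration file
#'
#' YAML list of complexes, each with `struct_id`, `ligand`, `family`, and
#' optional `keep`.
#'
#' @param path YAML file path.
#' @return Data frame with one row per configured complex.
#' @export
read_query_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$complexes %||% cfg
  do.call(rbind, lapply(entries, function(e) {
    data.frame(struct_id = e$struct_id, ligand = e$ligand %||% NA_character_,
               family = e$family, keep = isTRUE(e$keep),
               stringsAsFactors = FALSE)
  }))
}
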