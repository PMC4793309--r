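# Template-pose transplantation and the docking gate.
#
# Instead of re-docking the ligand, the query ligand is rigidly carried into
# each matched site by the match transform and accepted or rejected by steric
# and contact criteria. The preserved contract is the per-protein binary
# "docked successfully" decision plus one retained pose for energy scoring.

#' Transplant the query ligand into a matched site
#'
#' Applies the match's rigid transform (query frame to target frame) to the
#' heavy atoms of the template ligand.
#'
#' @param match A `SiteMatch` carrying a valid transform.
#' @param template_ligand The query complex's `Ligand`.
#' @return Object of class `LigandPose` with atoms in the target frame.
#' @export
transplant_pose <- function(match, template_ligand) {
  stopifnot(inherits(match, "SiteMatch"), inherits(template_ligand, "Ligand"))
  a <- template_ligand$atoms[!template_ligand$atoms$is_h, , drop = FALSE]
  xyz <- apply_transform(cbind(a$x, a$y, a$z), match$transform)
  atoms <- data.frame(name = a$name, element = a$element,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      is_h = FALSE, stringsAsFactors = FALSE)
  x <- list(ligand_name = template_ligand$resname, atoms = atoms,
            source_match = match$target_struct,
            query_site_id = match$query_site_id)
  class(x) <- "LigandPose"
  x
}

pose_coords <- function(pose) cbind(pose$atoms$x, pose$atoms$y, pose$atoms$z)

#' Steric/contact screen of a transplanted pose
#'
#' Counts protein heavy atoms closer than `clash_dist` to any ligand atom
#' (clashes) and within `contact_dist` (contacts). The pose passes iff
#' `n_clashes <= max_clashes` and `n_contacts >= min_contacts`. Defaults are
#' chosen so that self-transplants onto the source complex pass while poses
#' overlapping backbone atoms fail.
#'
#' @param pose A `LigandPose`.
#' @param target The target `Structure`.
#' @param clash_dist,contact_dist Distance thresholds in Angstrom (defaults
#'   2.2 and 4.5).
#' @param max_clashes,min_contacts Acceptance bounds (defaults 0 and 3).
#' @return Object of class `ScreenResult` with `passed`, `n_clashes`,
#'   `n_contacts`.
#' @export
steric_screen <- function(pose, target, clash_dist = 2.2, contact_dist = 4.5,
                          max_clashes = 0L, min_contacts = 3L) {
  stopifnot(inherits(pose, "LigandPose"), inherits(target, "Structure"))
  ha <- heavy_atoms(target)
  if (nrow(ha) == 0L) stop("target structure has no heavy atoms")
  d <- cross_dist(cbind(ha$x, ha$y, ha$z), pose_coords(pose))
  amin <- apply(d, 1L, min)
  n_clashes <- sum(amin < clash_dist)
  n_contacts <- sum(amin <= contact_dist)
  x <- list(passed = n_clashes <= max_clashes && n_contacts >= min_contacts,
            n_clashes = n_clashes, n_contacts = n_contacts,
            clash_dist = clash_dist, contact_dist = contact_dist)
  class(x) <- "ScreenResult"
  x
}

#' Detect hydrogen bonds between a pose and the protein
#'
#' Distance-only criterion (deposited and generated structures mostly lack
#' hydrogens): pairs of one ligand polar atom (N/O) and one protein polar
#' atom (N/O) within `d_max` Angstrom.
#'
#' @param pose A `LigandPose`.
#' @param target A `Structure` (or a `BindingSite` via `site`, restricting
#'   the protein atoms scanned to site residues).
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param site Optional `BindingSite` restricting protein atoms to its
#'   residues.
#' @return Data frame with one row per hydrogen bond: ligand atom, protein
#'   atom, residue and distance.
#' @export
detect_hbonds <- function(pose, target, d_max = 3.5, site = NULL) {
  stopifnot(inherits(pose, "LigandPose"), inherits(target, "Structure"))
  lp <- pose$atoms[pose$atoms$element %in% c("N", "O"), , drop = FALSE]
  ha <- heavy_atoms(target)
  if (!is.null(site)) ha <- ha[ha$res_idx %in% site$residues$res_idx, , drop = FALSE]
  pp <- ha[ha$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(ligand_atom = character(0), protein_atom = character(0),
                      chain = character(0), seqno = integer(0),
                      resname = character(0), dist = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(lp) == 0L || nrow(pp) == 0L) return(empty)
  d <- cross_dist(cbind(lp$x, lp$y, lp$z), cbind(pp$x, pp$y, pp$z))
  hit <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  r <- target$residues
  out <- data.frame(
    ligand_atom = lp$name[hit[, 1]],
    protein_atom = pp$name[hit[, 2]],
    chain = r$chain[pp$res_idx[hit[, 2]]],
    seqno = r$seqno[pp$res_idx[hit[, 2]]],
    resname = r$resname[pp$res_idx[hit[, 2]]],
    dist = d[hit], stringsAsFactors = FALSE)
  out[order(out$dist), , drop = FALSE]
}

#' Write a pose as a PDB HETATM block
#'
#' @param pose A `LigandPose`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_pdb <- function(pose, path) {
  a <- pose$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    pdb_atom_line(i, a$name[i], pose$ligand_name, "X", 1L, "", a$x[i],
                  a$y[i], a$z[i], a$element[i], het = TRUE)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
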