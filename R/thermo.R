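# Free-energy bookkeeping, entropy estimation and target classification.
#
# Binding free energy is decomposed end-point style as
#   dG = G_complex - G_receptor - G_ligand - TdS,
# with the enthalpic part dH = G_complex - G_receptor - G_ligand supplied by
# a pluggable scorer, and a single entropy change TdS applied to every
# target, derived once from an experimental binding constant via
#   -RT ln K = dG = dH - TdS  =>  TdS = dH + RT ln K.

#' Thermodynamic constants
#'
#' @param temperature Absolute temperature in Kelvin (default 298.15).
#' @param R Gas constant in kcal/(mol K).
#' @param K_bind Reference binding constant in 1/M (default 1.56e5, the
#'   experimental aspirin/phospholipase A2 constant used to anchor the
#'   entropy estimate).
#' @param t_delta_s_fixed Fixed entropy change TdS in kcal/mol applied to
#'   every target (default 4.728).
#' @return Named list of constants.
#' @export
thermo_constants <- function(temperature = 298.15, R = 1.9872041e-3,
                             K_bind = 1.56e5, t_delta_s_fixed = 4.728) {
  stopifnot(temperature > 0, R > 0, K_bind > 0)
  list(temperature = temperature, R = R, K_bind = K_bind,
       t_delta_s_fixed = t_delta_s_fixed)
}

#' Binding free energy bookkeeping
#'
#' `G_complex - G_receptor - G_ligand`, in kcal/mol.
#'
#' @param g_complex,g_receptor,g_ligand Free energies in kcal/mol.
#' @return Binding free energy difference in kcal/mol.
#' @export
binding_free_energy <- function(g_complex, g_receptor, g_ligand) {
  if (!all(is.finite(c(g_complex, g_receptor, g_ligand)))) {
    stop("free energy terms must be finite")
  }
  g_complex - g_receptor - g_ligand
}

#' Entropy change from a binding constant
#'
#' `TdS = dH + RT ln K`. A precomputed `rt_ln_k` may be supplied instead of
#' `K_bind` (worked-example mode, matching a printed RT ln K value exactly).
#'
#' @param delta_h Enthalpy change in kcal/mol.
#' @param K_bind Binding constant in 1/M.
#' @param consts [thermo_constants()].
#' @param rt_ln_k Optional override for the RT ln K term in kcal/mol.
#' @return TdS in kcal/mol.
#' @export
entropy_from_constant <- function(delta_h, K_bind = NULL,
                                  consts = thermo_constants(),
                                  rt_ln_k = NULL) {
  if (!is_number(delta_h)) stop("delta_h must be a finite number")
  if (is.null(rt_ln_k)) {
    K_bind <- K_bind %||% consts$K_bind
    if (K_bind <= 0) stop("K_bind must be positive")
    rt_ln_k <- consts$R * consts$temperature * log(K_bind)
  }
  delta_h + rt_ln_k
}

#' Build an energy record
#'
#' Enforces the bookkeeping invariants `delta_h = g_complex - g_receptor -
#' g_ligand` and `delta_g = delta_h - t_delta_s`.
#'
#' @param target_id Gene name or struct_id.
#' @param g_complex,g_receptor,g_ligand Eq-terms in kcal/mol.
#' @param t_delta_s Entropy term in kcal/mol (default `NA`; set later by
#'   [apply_entropy_and_filter()]).
#' @param e_mm,d_sol Optional decomposition terms in kcal/mol.
#' @return One-row data frame.
#' @export
energy_record <- function(target_id, g_complex, g_receptor, g_ligand,
                          t_delta_s = NA_real_, e_mm = NA_real_,
                          d_sol = NA_real_) {
  dh <- binding_free_energy(g_complex, g_receptor, g_ligand)
  data.frame(target_id = target_id, g_complex = g_complex,
             g_receptor = g_receptor, g_ligand = g_ligand,
             e_mm = e_mm, d_sol = d_sol, delta_h = dh,
             t_delta_s = t_delta_s,
             delta_g = if (is.na(t_delta_s)) NA_real_ else dh - t_delta_s,
             stringsAsFactors = FALSE)
}

#' Apply the fixed entropy change and keep favourable binders
#'
#' Sets `delta_g = delta_h - t_delta_s_fixed` on every record and keeps only
#' records with `delta_g < 0` (strictly), preserving input order.
#'
#' @param records Data frame with a `delta_h` column (e.g. rows from
#'   [energy_record()]).
#' @param t_delta_s_fixed Entropy change in kcal/mol (default 4.728).
#' @return Filtered data frame with `t_delta_s` and `delta_g` set.
#' @export
apply_entropy_and_filter <- function(records, t_delta_s_fixed = 4.728) {
  stopifnot(is.data.frame(records), "delta_h" %in% names(records))
  if (!is.finite(t_delta_s_fixed)) stop("t_delta_s_fixed must be finite")
  records$t_delta_s <- t_delta_s_fixed
  records$delta_g <- records$delta_h - t_delta_s_fixed
  out <- records[records$delta_g < 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Families of primary (previously known) aspirin targets
#'
#' @return Character vector of family labels as used in the packaged target
#'   table.
#' @export
primary_target_families <- function() {
  c("Phospholipase A2 family", "Prostaglandin G/H synthase family",
    "Chitotriosidase family")
}

#' Classify targets and summarize their binding free energies
#'
#' Targets whose family is in `primary_families` are `primary`, all others
#' `new`; means are computed per category, min/max over all targets.
#'
#' @param records Data frame with columns `family` and `delta_g` (and
#'   typically `gene`, `uniprot`).
#' @param primary_families Character vector (default
#'   [primary_target_families()]).
#' @return Object of class `TargetSummary`: counts, per-category mean
#'   `delta_g`, global min/max, and the classified table (`$records`).
#' @export
classify_and_summarize <- function(records,
                                   primary_families = primary_target_families()) {
  stopifnot(is.data.frame(records),
            all(c("family", "delta_g") %in% names(records)))
  if (nrow(records) == 0L) stop("no target records to summarize")
  records$category <- ifelse(records$family %in% primary_families,
                             "primary", "new")
  prim <- records$delta_g[records$category == "primary"]
  new <- records$delta_g[records$category == "new"]
  x <- list(
    n_total = nrow(records),
    n_primary = length(prim),
    n_new = length(new),
    mean_dg_primary = if (length(prim)) mean(prim) else NA_real_,
    mean_dg_new = if (length(new)) mean(new) else NA_real_,
    min_dg = min(records$delta_g),
    max_dg = max(records$delta_g),
    records = records)
  class(x) <- "TargetSummary"
  x
}

#' @export
print.TargetSummary <- function(x, ...) {
  cat(sprintf(paste0("<TargetSummary: %d targets (%d primary, %d new); ",
                     "dG range [%.1f, %.1f] kcal/mol>\n"),
              x$n_total, x$n_primary, x$n_new, x$min_dg, x$max_dg))
  invisible(x)
}

#' Read / write a target table
#'
#' Tab-separated with columns `gene`, `uniprot`, `family`, `delta_g`. The
#' packaged file `extdata/table1_targets.tsv` is the transcription of the
#' published putative-target table.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_target_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("gene", "uniprot", "family", "delta_g")
  if (!all(need %in% names(out))) {
    stop("target table must have columns: ", paste(need, collapse = ", "))
  }
  out
}

#' @rdname read_target_table
#' @param records Data frame to write.
#' @export
write_target_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# --- demo energy scorer -----------------------------------------------------

#' Parameters for the demo interaction scorer
#'
#' Generic pairwise 12-6 Lennard-Jones (rmin form) plus distance-dependent
#' dielectric Coulomb terms, per element. The well depth is chosen so that
#' pocket-scale ligand-protein interaction enthalpies land on the few-to-tens
#' of kcal/mol scale; this scorer only supplies finite enthalpies for the
#' pipeline, it is not a solvation model.
#'
#' @param epsilon Well depth in kcal/mol (default 0.25).
#' @param rmin Pair distance at the LJ minimum in Angstrom (default 3.8).
#' @param charges Named vector of partial charges per element.
#' @param dielectric_scale Distance-dependent dielectric factor `eps = k r`
#'   (default 4).
#' @param r_floor Distances are clamped below this value (default 1.0 A).
#' @return Named list of parameters.
#' @export
scorer_params <- function(epsilon = 0.25, rmin = 3.8,
                          charges = c(C = 0.05, N = 0.25, O = -0.40,
                                      S = -0.10),
                          dielectric_scale = 4, r_floor = 1.0) {
  list(epsilon = epsilon, rmin = rmin, charges = charges,
       dielectric_scale = dielectric_scale, r_floor = r_floor)
}

#' Score a transplanted pose against its target
#'
#' Computes the ligand-protein interaction enthalpy over all heavy-atom
#' pairs. For a rigid transplant the intramolecular terms of receptor and
#' ligand are unchanged by binding and cancel in the bookkeeping, so the
#' scorer reports `g_receptor = g_ligand = 0` and `g_complex` equal to the
#' interaction energy; `delta_h` is then exactly the interaction energy.
#'
#' @param pose A `LigandPose`.
#' @param target The target `Structure`.
#' @param params [scorer_params()].
#' @return List with `g_complex`, `g_receptor`, `g_ligand`, `e_mm`.
#' @export
score_pose <- function(pose, target, params = scorer_params()) {
  ha <- heavy_atoms(target)
  pc <- pose_coords(pose)
  d <- cross_dist(cbind(ha$x, ha$y, ha$z), pc)
  d[d < params$r_floor] <- params$r_floor
  # only pairs within 9 A contribute appreciably
  sel <- d <= 9
  if (!any(sel)) {
    return(list(g_complex = 0, g_receptor = 0, g_ligand = 0, e_mm = 0))
  }
  r <- d[sel]
  sr6 <- (params$rmin / r)^6
  e_lj <- sum(params$epsilon * (sr6^2 - 2 * sr6))
  qp <- params$charges[ha$element]
  qp[is.na(qp)] <- 0
  ql <- params$charges[pose$atoms$element]
  ql[is.na(ql)] <- 0
  qq <- outer(qp, ql)[sel]
  e_coul <- sum(332.0637 * qq / (params$dielectric_scale * r^2))
  e <- e_lj + e_coul
  list(g_complex = e, g_receptor = 0, g_ligand = 0, e_mm = e)
}
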