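# Synthetic structures with known ground truth.
#
# Decoys are confined self-avoiding Calpha random walks at protein-like
# packing density, decorated with deterministic stub atoms (N, O, CB) so
# that distance-based screens and hydrogen-bond detection have atoms to work
# with. A planted copy of a query binding site (optionally noised and
# mutated within its BLOSUM62 substitution sets) provides positives for
# sensitivity benchmarks; the planted ligand position carves a realistic
# cavity. All generators are pure functions of their seeds.

#' Specification of a planted site
#'
#' @param noise_sigma Per-coordinate Gaussian noise in Angstrom applied to
#'   the planted residue positions (default 0.3).
#' @param n_substitutions Number of BLOSUM62-compatible residue swaps
#'   (default 1).
#' @param seed Integer seed.
#' @return Object of class `PlantSpec`.
#' @export
plant_spec <- function(noise_sigma = 0.3, n_substitutions = 1L, seed = 1L) {
  stopifnot(noise_sigma >= 0, n_substitutions >= 0)
  x <- list(noise_sigma = noise_sigma,
            n_substitutions = as.integer(n_substitutions),
            seed = as.integer(seed))
  class(x) <- "PlantSpec"
  x
}

# Orthonormal frame helpers ---------------------------------------------------

perp_unit <- function(u) {
  e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  unit(c(u[2] * e[3] - u[3] * e[2],
         u[3] * e[1] - u[1] * e[3],
         u[1] * e[2] - u[2] * e[1]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Stub atoms for one residue: CA plus deterministic N, O and (non-glycine)
# CB placed on a local frame. `u_out` points away from the chain/pocket.
residue_stub_atoms <- function(res_idx, resname, ca, u_out, u_aux) {
  cr <- cross3(u_out, u_aux)
  w <- if (vnorm(cr) > 1e-6) unit(cr) else perp_unit(u_out)
  v <- unit(cross3(w, u_out))
  atoms <- data.frame(
    res_idx = res_idx,
    name = c("N", "CA", "O"),
    element = c("N", "C", "O"),
    x = c(ca[1] + 1.3 * w[1], ca[1], ca[1] + 1.3 * v[1]),
    y = c(ca[2] + 1.3 * w[2], ca[2], ca[2] + 1.3 * v[2]),
    z = c(ca[3] + 1.3 * w[3], ca[3], ca[3] + 1.3 * v[3]),
    is_h = FALSE, stringsAsFactors = FALSE)
  if (resname != "GLY") {
    cb <- ca + 1.5 * u_out
    atoms <- rbind(atoms, data.frame(res_idx = res_idx, name = "CB",
                                     element = "C", x = cb[1], y = cb[2],
                                     z = cb[3], is_h = FALSE,
                                     stringsAsFactors = FALSE))
  }
  atoms
}

decoy_atoms <- function(residues, ca) {
  n <- nrow(residues)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ca[max(i - 1L, 1L) + (i == 1L), ]   # neighbour toward N-terminus
    b <- ca[min(i + 1L, n) - (i == n), ]     # neighbour toward C-terminus
    v1 <- unit(a - ca[i, ])
    v2 <- unit(b - ca[i, ])
    bis <- v1 + v2
    u_out <- if (vnorm(bis) > 1e-6) -unit(bis) else perp_unit(v1)
    out[[i]] <- residue_stub_atoms(i, residues$resname[i], ca[i, ], u_out, v1)
  }
  do.call(rbind, out)
}

#' Generate a decoy protein structure
#'
#' Confined self-avoiding Calpha random walk: consecutive Calphas are
#' `step` Angstrom apart, non-adjacent Calphas at least `min_sep` apart, and
#' the whole chain stays within a confinement sphere whose radius scales as
#' `3.0 n^(1/3)` Angstrom (approximately protein packing density). Residue
#' types are drawn uniformly; each residue gets deterministic stub atoms
#' (N, CA, O and, except glycine, CB).
#'
#' @param n_res Number of residues (>= 10).
#' @param seed Integer seed; the structure is a pure function of it.
#' @param step Consecutive Calpha distance in Angstrom (default 3.8).
#' @param min_sep Minimum non-adjacent Calpha distance (default 4.0).
#' @param radius Confinement radius in Angstrom (default `3.0 n^(1/3)`).
#' @param struct_id Identifier (default derived from the seed).
#' @return A `Structure`.
#' @export
make_decoy <- function(n_res, seed, step = 3.8, min_sep = 4.0, radius = NULL,
                       struct_id = NULL) {
  if (n_res < 10L) stop("n_res must be at least 10")
  radius <- radius %||% (3.0 * n_res^(1 / 3))
  ca <- with_seed(seed, {
    for (restart in seq_len(50L)) {
      pos <- matrix(NA_real_, n_res, 3)
      pos[1, ] <- c(0, 0, 0)
      ok <- TRUE
      for (i in 2:n_res) {
        placed <- FALSE
        for (try in seq_len(120L)) {
          dir <- unit(stats::rnorm(3))
          cand <- pos[i - 1L, ] + step * dir
          if (vnorm(cand) > radius) next
          if (i > 2L) {
            prev <- pos[seq_len(i - 2L), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2L, cand)^2)
            if (min(d2) < min_sep^2) next
          }
          pos[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("decoy generation failed for seed ", seed,
                  ": retry budget exhausted")
    pos
  })
  aa <- with_seed(seed + 7L, sample(AA_CODES, n_res, replace = TRUE))
  residues <- data.frame(chain = "A", seqno = seq_len(n_res), ins = "",
                         resname = aa123(aa), stringsAsFactors = FALSE)
  atoms <- decoy_atoms(residues, ca)
  new_structure(struct_id %||% sprintf("DECOY_%d", seed), residues, atoms)
}

#' Plant a copy of a binding site into a decoy
#'
#' Replaces a spatially clustered set of decoy residues with the site's
#' residues: site representative coordinates are rigidly re-posed (random
#' rotation, centroid moved onto the cluster centroid), per-coordinate
#' Gaussian noise of `spec$noise_sigma` is added, and `spec$n_substitutions`
#' residue labels are swapped to a different code within their BLOSUM62
#' (score >= 1) substitution set. When `ligand` is supplied it is carried
#' along by the same rigid transform and a cavity is carved: non-planted
#' residues with atoms within `carve_dist` of the ligand (or overlapping the
#' planted residues) are removed, as in a real pocket.
#'
#' @param decoy A `Structure` from [make_decoy()].
#' @param site The query `BindingSite` to plant.
#' @param spec A [plant_spec()].
#' @param ligand Optional query `Ligand` (used for carving only; the planted
#'   structure does not keep the ligand).
#' @param carve_dist Cavity carving distance in Angstrom (default 3.2,
#'   a realistic van der Waals contact floor).
#' @param struct_id Identifier for the planted structure.
#' @return List with `structure`, `mapping` (query position -> residue index
#'   in the returned structure), `site_labels` (planted one-letter codes)
#'   and `ligand_coords` (planted-frame ligand heavy atoms, or `NULL`).
#' @export
plant_site <- function(decoy, site, spec = plant_spec(), ligand = NULL,
                       carve_dist = 3.2, struct_id = NULL) {
  stopifnot(inherits(decoy, "Structure"), inherits(site, "BindingSite"),
            inherits(spec, "PlantSpec"))
  n <- site_size(site)
  if (spec$n_substitutions > n) stop("more substitutions than site residues")
  nd <- nrow(decoy$residues)
  if (nd < n + 3L) stop("decoy too small to plant the site")
  dca <- ca_coords(decoy)
  D <- as.matrix(stats::dist(dca))
  dens <- rowSums(D <= 8)
  anchor <- which.max(dens)
  cluster <- sort(order(D[anchor, ])[seq_len(n)])

  res <- with_seed(spec$seed, {
    R <- random_rotation()
    c_site <- colMeans(site$rep_coords)
    c_cluster <- colMeans(dca[cluster, , drop = FALSE])
    new_ca <- sweep(sweep(site$rep_coords, 2L, c_site) %*% t(R), 2L,
                    c_cluster, "+")
    if (spec$noise_sigma > 0) {
      new_ca <- new_ca + matrix(stats::rnorm(3 * n, sd = spec$noise_sigma),
                                n, 3)
    }
    labels <- site$labels
    if (spec$n_substitutions > 0L) {
      subs <- substitution_sets(site)
      alt <- lapply(seq_len(n), function(i) setdiff(subs[[i]], labels[i]))
      eligible <- which(vapply(alt, length, integer(1)) > 0L)
      if (length(eligible) < spec$n_substitutions) {
        stop("not enough substitutable site positions")
      }
      pos <- sample(eligible, spec$n_substitutions)
      for (p in pos) labels[p] <- alt[[p]][sample.int(length(alt[[p]]), 1L)]
    }
    lig_xyz <- NULL
    if (!is.null(ligand)) {
      lc <- ligand_heavy_coords(ligand)
      lig_xyz <- sweep(sweep(lc, 2L, c_site) %*% t(R), 2L, c_cluster, "+")
    }
    list(new_ca = new_ca, labels = labels, lig_xyz = lig_xyz,
         pocket_center = c_cluster)
  })

  residues <- decoy$residues[, c("chain", "seqno", "ins", "resname")]
  residues$resname[cluster] <- aa123(res$labels)
  all_ca <- dca
  all_ca[cluster, ] <- res$new_ca

  # rebuild atoms: untouched residues keep their stubs, planted residues get
  # stubs pointing away from the pocket center
  keep_atoms <- decoy$atoms[!decoy$atoms$res_idx %in% cluster, , drop = FALSE]
  center <- if (!is.null(res$lig_xyz)) colMeans(res$lig_xyz) else
    res$pocket_center
  planted_atoms <- do.call(rbind, lapply(seq_len(n), function(j) {
    i <- cluster[j]
    ca <- all_ca[i, ]
    u_out <- unit(ca - center)
    residue_stub_atoms(i, residues$resname[i], ca, u_out, perp_unit(u_out))
  }))
  atoms <- rbind(keep_atoms, planted_atoms)
  atoms <- atoms[order(atoms$res_idx), , drop = FALSE]

  drop <- integer(0)
  if (!is.null(res$lig_xyz)) {
    non_planted <- atoms[!atoms$res_idx %in% cluster, , drop = FALSE]
    if (nrow(non_planted) > 0L) {
      d_lig <- apply(cross_dist(cbind(non_planted$x, non_planted$y,
                                      non_planted$z), res$lig_xyz), 1L, min)
      d_pl <- apply(cross_dist(cbind(non_planted$x, non_planted$y,
                                     non_planted$z),
                               cbind(planted_atoms$x, planted_atoms$y,
                                     planted_atoms$z)), 1L, min)
      drop <- unique(non_planted$res_idx[d_lig < carve_dist | d_pl < 2.5])
    }
  }
  keep_res <- setdiff(seq_len(nrow(residues)), drop)
  residues2 <- residues[keep_res, , drop = FALSE]
  rownames(residues2) <- NULL
  atoms2 <- atoms[atoms$res_idx %in% keep_res, , drop = FALSE]
  atoms2$res_idx <- match(atoms2$res_idx, keep_res)
  st <- new_structure(struct_id %||% paste0(decoy$struct_id, "_planted"),
                      residues2, atoms2)
  list(structure = st,
       mapping = match(cluster, keep_res),
       site_labels = res$labels,
       ligand_coords = res$lig_xyz)
}

#' Assemble a planted-site benchmark database
#'
#' `n_planted` decoys receive a planted copy of the site (per `spec`);
#' `n_decoys` remain clean. The database order is shuffled with a seeded
#' permutation and structures renamed `SYN###`; the ground truth records
#' which ids contain plants and their residue mappings.
#'
#' @param site The query `BindingSite`.
#' @param n_planted,n_decoys Counts (>= 1).
#' @param spec A [plant_spec()]; its seed drives every structure.
#' @param n_res Decoy size in residues (default 80).
#' @param ligand Optional query `Ligand` used to carve cavities in planted
#'   structures.
#' @return List with `db` (a `StructureDB`) and `truth` (class
#'   `BenchmarkTruth`: `planted_ids`, `db_size`, `spec`, `mappings`).
#' @export
make_benchmark <- function(site, n_planted = 10L, n_decoys = 100L,
                           spec = plant_spec(), n_res = 80L, ligand = NULL) {
  stopifnot(n_planted >= 1L, n_decoys >= 1L)
  total <- n_planted + n_decoys
  seeds <- derive_seeds(spec$seed, 2L * n_planted + n_decoys + 1L)
  planted <- vector("list", n_planted)
  mappings <- vector("list", n_planted)
  for (i in seq_len(n_planted)) {
    base <- make_decoy(n_res, seeds[i])
    pl <- plant_site(base, site,
                     plant_spec(spec$noise_sigma, spec$n_substitutions,
                                seeds[n_planted + i]),
                     ligand = ligand)
    planted[[i]] <- pl$structure
    mappings[[i]] <- pl$mapping
  }
  clean <- lapply(seq_len(n_decoys), function(i) {
    make_decoy(n_res, seeds[2L * n_planted + i])
  })
  all_structs <- c(planted, clean)
  is_planted <- c(rep(TRUE, n_planted), rep(FALSE, n_decoys))
  perm <- with_seed(seeds[length(seeds)], sample.int(total))
  all_structs <- all_structs[perm]
  is_planted <- is_planted[perm]
  mappings <- stats::setNames(mappings, NULL)
  map_by_id <- list()
  orig_planted_pos <- match(seq_len(n_planted), perm)  # new position of plant i
  for (k in seq_len(total)) {
    all_structs[[k]]$struct_id <- sprintf("SYN%03d", k)
  }
  for (i in seq_len(n_planted)) {
    map_by_id[[sprintf("SYN%03d", orig_planted_pos[i])]] <- mappings[[i]]
  }
  truth <- list(planted_ids = sprintf("SYN%03d", which(is_planted)),
                db_size = total, spec = spec, mappings = map_by_id)
  class(truth) <- "BenchmarkTruth"
  list(db = structure_db(all_structs, meta = "synthetic benchmark"),
       truth = truth)
}

#' Deterministic aspirin-like toy ligand
#'
#' Fixed-topology 13-heavy-atom ligand (planar aromatic core, a carboxylate
#' and an ester-acetyl arm; 4 oxygen acceptors), with a bond list attached
#' for geometry checks. The geometry is deterministic; `seed` is accepted
#' for generator-API symmetry.
#'
#' @param seed Ignored (the ligand is constant).
#' @return A `Ligand` with a `bonds` element (index pairs).
#' @export
make_toy_ligand <- function(seed = 1L) {
  ring <- t(vapply(0:5, function(k) {
    a <- pi * k / 3
    c(1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  c1 <- ring[1, ]; c2 <- ring[2, ]
  c7 <- c1 + 1.50 * unit(c1)
  o1 <- c7 + 1.25 * c(0.5, 0.866, 0)
  o2 <- c7 + 1.25 * c(0.5, -0.866, 0)
  o3 <- c2 + 1.40 * unit(c2)
  d8 <- c(-0.5, 0.866, 0)
  c8 <- o3 + 1.40 * d8
  o4 <- c8 + 1.23 * c(-0.866, -0.5, 0)
  c9 <- c8 + 1.50 * c(0.5, 0.866, 0)
  xyz <- rbind(ring, c7, o1, o2, o3, c8, o4, c9)
  atoms <- data.frame(
    name = c(paste0("C", 1:6), "C7", "O1", "O2", "O3", "C8", "O4", "C9"),
    element = c(rep("C", 7), "O", "O", "O", "C", "O", "C"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_h = FALSE,
    stringsAsFactors = FALSE)
  lig <- new_ligand("LIG", atoms, chain = "A", seqno = 900L)
  lig$bonds <- rbind(cbind(1:6, c(2:6, 1)),            # ring
                     c(1, 7), c(7, 8), c(7, 9),        # carboxyl
                     c(2, 10), c(10, 11), c(11, 12), c(11, 13))  # ester arm
  lig
}

#' Generate a synthetic query complex
#'
#' Builds a decoy, places the toy ligand at its densest region (random
#' orientation), carves a cavity at `carve_dist`, and extracts the binding
#' site at `cutoff`. The result plays the role of a deposited protein-ligand
#' complex with a known pocket.
#'
#' @param seed Integer seed.
#' @param n_res Decoy size (default 90).
#' @param cutoff Site extraction cutoff in Angstrom (default 5).
#' @param carve_dist Cavity carving distance (default 3.2).
#' @param family Family label for query-set bookkeeping.
#' @return Object of class `QueryComplex`: `struct_id`, `family`,
#'   `structure` (with the ligand attached), `ligand`, `site`.
#' @export
make_query_complex <- function(seed, n_res = 90L, cutoff = 5,
                               carve_dist = 3.2, family = "synthetic") {
  decoy <- make_decoy(n_res, seed, struct_id = sprintf("QRY_%d", seed))
  dca <- ca_coords(decoy)
  D <- as.matrix(stats::dist(dca))
  dens <- rowSums(D <= 8)
  lig0 <- make_toy_ligand()
  lc <- ligand_heavy_coords(lig0)
  R <- with_seed(seed + 13L, random_rotation())
  a <- decoy$atoms
  # try the densest candidate anchors and keep the placement with the
  # largest resulting pocket (a deposited complex has its ligand in a
  # well-formed pocket, not at an arbitrary surface spot)
  best <- NULL
  for (anchor in order(-dens, seq_along(dens))[1:8]) {
    p <- colMeans(dca[order(D[anchor, ])[1:12], , drop = FALSE])
    lc2 <- sweep(sweep(lc, 2L, colMeans(lc)) %*% t(R), 2L, p, "+")
    dmin <- apply(cross_dist(cbind(a$x, a$y, a$z), lc2), 1L, min)
    keep <- setdiff(seq_len(nrow(decoy$residues)),
                    unique(a$res_idx[dmin < carve_dist]))
    residues <- decoy$residues[keep, c("chain", "seqno", "ins", "resname")]
    rownames(residues) <- NULL
    atoms <- a[a$res_idx %in% keep, , drop = FALSE]
    atoms$res_idx <- match(atoms$res_idx, keep)
    lig <- lig0
    lig$atoms$x <- lc2[, 1]; lig$atoms$y <- lc2[, 2]; lig$atoms$z <- lc2[, 3]
    st <- new_structure(decoy$struct_id, residues, atoms, ligands = list(lig))
    site <- tryCatch(extract_site(st, lig, cutoff = cutoff),
                     error = function(e) NULL)
    if (!is.null(site) &&
        (is.null(best) || site_size(site) > site_size(best$site))) {
      best <- list(structure = st, ligand = lig, site = site)
    }
  }
  if (is.null(best)) stop("query-complex generation failed for seed ", seed)
  x <- list(struct_id = decoy$struct_id, family = family,
            structure = best$structure, ligand = best$ligand,
            site = best$site)
  class(x) <- "QueryComplex"
  x
}
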