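# Shared fixtures and independent oracles, all built in code.

# Hand-written minimal PDB text: three residues (ALA, GLY, TRP), optionally
# followed by a 13-heavy-atom aspirin HETATM group (res name AIN).
tiny_pdb_lines <- function(with_ligand = FALSE) {
  fmt <- function(serial, name, res, chain, no, x, y, z, el, het = FALSE) {
    nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", serial, nm, res, chain, no,
            x, y, z, 1, 0, el)
  }
  lines <- c(
    fmt(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    fmt(2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0, "C"),
    fmt(3, "CB", "ALA", "A", 1, 2.0, 1.2, 0.0, "C"),
    fmt(4, "CA", "GLY", "A", 2, 3.8, 1.5, 0.2, "C"),
    fmt(5, "CA", "TRP", "A", 3, 7.0, 3.0, 1.0, "C"),
    fmt(6, "CB", "TRP", "A", 3, 7.5, 4.2, 1.5, "C"))
  if (with_ligand) {
    lig <- make_toy_ligand()
    la <- lig$atoms
    for (i in seq_len(nrow(la))) {
      lines <- c(lines, fmt(100 + i, la$name[i], "AIN", "A", 101,
                            la$x[i] + 3, la$y[i] + 2, la$z[i] + 4,
                            la$element[i], het = TRUE))
    }
  }
  c(lines, "END")
}

write_tiny_pdb <- function(with_ligand = FALSE) {
  f <- tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines(with_ligand), f)
  f
}

# Structure built directly from Calpha coordinates (one CA atom per residue).
toy_structure <- function(ca, aa1, id = "TOY") {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  residues <- data.frame(chain = "A", seqno = seq_len(n), ins = "",
                         resname = sitefish:::aa123(aa1),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_idx = seq_len(n), name = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3], is_h = FALSE,
                      stringsAsFactors = FALSE)
  new_structure(id, residues, atoms)
}

# Ligand from a coordinate matrix.
toy_ligand_at <- function(xyz, elements = NULL, resname = "LIG") {
  xyz <- as.matrix(xyz)
  elements <- elements %||% rep("C", nrow(xyz))
  new_ligand(resname, data.frame(
    name = paste0(elements, seq_len(nrow(xyz))), element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_h = FALSE,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A binding site object built from explicit coordinates and labels.
toy_site <- function(coords, labels, id = "TOYSITE") {
  st <- toy_structure(coords, labels, id = paste0(id, "_SRC"))
  res <- st$residues
  res$res_idx <- seq_len(nrow(res))
  res$min_dist <- NA_real_
  x <- list(site_id = id, source_struct = st$struct_id, ligand_name = "LIG",
            residues = res, rep_coords = as.matrix(coords), labels = labels,
            cutoff = 5, rep_atom = "CA")
  class(x) <- "BindingSite"
  x
}

random_rigid <- function(seed) {
  sitefish:::with_seed(seed, {
    R <- sitefish:::random_rotation()
    list(rotation = R, translation = stats::rnorm(3, sd = 10))
  })
}

transform_structure <- function(structure, tf) {
  a <- structure$atoms
  xyz <- apply_transform(cbind(a$x, a$y, a$z), tf)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  st <- new_structure(structure$struct_id,
                      structure$residues[, c("chain", "seqno", "ins", "resname")],
                      structure$atoms, structure$ligands)
  st
}

transform_ligand <- function(ligand, tf) {
  xyz <- apply_transform(cbind(ligand$atoms$x, ligand$atoms$y,
                               ligand$atoms$z), tf)
  ligand$atoms$x <- xyz[, 1]
  ligand$atoms$y <- xyz[, 2]
  ligand$atoms$z <- xyz[, 3]
  ligand
}

# --- independent oracles ----------------------------------------------------

# Brute-force global alignment by recursion over all gap placements.
# Returns the optimal score and the set of identity counts achieved by
# optimal alignments.
brute_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(matrix(c(0, 0), 1))
    outs <- NULL
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      sub <- rec(i + 1, j + 1)
      outs <- rbind(outs, cbind(sub[, 1] + s,
                                sub[, 2] + as.integer(av[i] == bv[j])))
    }
    if (i <= length(av)) {
      sub <- rec(i + 1, j)
      outs <- rbind(outs, cbind(sub[, 1] + gap, sub[, 2]))
    }
    if (j <= length(bv)) {
      sub <- rec(i, j + 1)
      outs <- rbind(outs, cbind(sub[, 1] + gap, sub[, 2]))
    }
    outs
  }
  all <- rec(1, 1)
  best <- max(all[, 1])
  list(score = best, idents = sort(unique(all[all[, 1] == best, 2])))
}

# Rotation-grid + local-refinement RMSD oracle (independent of SVD).
grid_rmsd_oracle <- function(a, b, coarse = 20) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rotmat(ang)) - B)^2)))
  grid <- seq(0, 2 * pi, by = coarse * pi / 180)
  best <- NULL
  for (ax in grid) for (ay in grid) for (az in grid) {
    v <- obj(c(ax, ay, az))
    if (is.null(best) || v < best$v) best <- list(v = v, ang = c(ax, ay, az))
  }
  opt <- stats::optim(best$ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best$v, opt$value)
}

# Exhaustive candidate enumeration for small targets.
exhaustive_candidates <- function(site, target, subs, pair_tol) {
  n <- nrow(site$rep_coords)
  Dq <- as.matrix(stats::dist(site$rep_coords))
  Dt <- as.matrix(stats::dist(ca_coords(target)))
  taa <- target$residues$aa1
  compat <- lapply(subs, function(s) which(taa %in% s))
  res <- list()
  recur <- function(assigned) {
    k <- length(assigned) + 1
    if (k > n) {
      res[[length(res) + 1]] <<- assigned
      return()
    }
    for (t in compat[[k]]) {
      if (t %in% assigned) next
      ok <- TRUE
      for (m in seq_along(assigned)) {
        if (abs(Dt[t, assigned[m]] - Dq[k, m]) > pair_tol) { ok <- FALSE; break }
      }
      if (ok) recur(c(assigned, t))
    }
  }
  recur(integer(0))
  if (length(res) == 0) return(matrix(integer(0), 0, n))
  mp <- do.call(rbind, res)
  mp[do.call(order, as.data.frame(mp)), , drop = FALSE]
}

# Hypergeometric upper tail by exhaustive enumeration of draws (N <= 12).
hyper_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # treat genes 1..K as the pathway
  mean(hits >= k)
}

# BH step-up from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
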