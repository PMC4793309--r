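# Contact-matrix local structural alignment (the search engine).
#
# A query binding site is matched against each database structure by
# enumerating residue combinations whose codes are BLOSUM62-compatible with
# the query residues and whose pairwise Calpha distances reproduce the query
# contact matrix within a tolerance. Surviving candidates are scored by CMAD
# (contact-matrix average deviation), superposed by the Kabsch algorithm for
# an RMSD, and ranked by an empirical P-value calibrated on decoy structures;
# E-value = P-value x database size.

#' BLOSUM62 substitution sets for a query site
#'
#' For each query residue code `q`, the set of codes `t` with
#' `BLOSUM62[q, t] >= score_cutoff`. The residue's own code is always
#' retained, even under a cutoff that would exclude the diagonal.
#' Non-standard codes map to the full 20-code set with a warning.
#'
#' @param site A `BindingSite`, or a character vector of one-letter codes.
#' @param score_cutoff Integer BLOSUM62 score cutoff (default 1).
#' @return Named list (one element per site position) of allowed codes.
#' @export
substitution_sets <- function(site, score_cutoff = 1) {
  labels <- if (inherits(site, "BindingSite")) site$labels else toupper(site)
  B <- blosum62()
  lapply(seq_along(labels), function(i) {
    q <- labels[i]
    if (!q %in% rownames(B)) {
      warning("non-standard residue code '", q, "' mapped to all 20 codes")
      return(AA_CODES)
    }
    allowed <- colnames(B)[B[q, ] >= score_cutoff]
    union(q, allowed)
  })
}

#' Contact matrix average deviation (CMAD)
#'
#' Mean absolute difference between corresponding inter-residue distances of
#' the query site and a candidate local structure, over all residue pairs
#' `i < j`.
#'
#' @param query_cm A [contact_matrix()] of the query site.
#' @param cand_coords n x 3 matrix of candidate representative coordinates
#'   (rows in query site order).
#' @return CMAD in Angstrom.
#' @export
cmad <- function(query_cm, cand_coords) {
  stopifnot(inherits(query_cm, "ContactMatrix"))
  n <- nrow(query_cm$dist)
  cand_coords <- as.matrix(cand_coords)
  if (nrow(cand_coords) != n) stop("candidate size must equal query site size")
  if (n < 3L) stop("site must have at least 3 residues")
  dq <- query_cm$dist[lower.tri(query_cm$dist)]
  dc <- stats::dist(cand_coords)
  mean(abs(dq - as.numeric(dc)))
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of corresponded point sets; the
#' returned transform maps frame `a` onto frame `b` (`x' = R x + t`).
#' Reflections are excluded (proper rotation, `det(R) = +1`).
#'
#' @param coords_a,coords_b n x 3 matrices with row correspondence, n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (Angstrom).
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("point sets must have equal size")
  if (nrow(a) < 3L) stop("need at least 3 points")
  ca <- colMeans(a)
  cb <- colMeans(b)
  A <- sweep(a, 2L, ca)
  B <- sweep(b, 2L, cb)
  if (max(abs(A)) < 1e-9 && max(abs(B)) < 1e-9) stop("rank-0 point sets")
  s <- svd(crossprod(A, B))
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cb - R %*% ca)
  rmsd <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform List with `rotation` and `translation` (as returned by
#'   [kabsch()]).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

#' Enumerate candidate residue combinations in a target structure
#'
#' Anchor-and-extend search: the query residue pair with the largest
#' inter-residue distance (the most discriminating pair, since long distances
#' are rarest) is matched first against all code-compatible target residue
#' pairs within `pair_tol` of its distance; remaining query positions are
#' added one at a time, pruning any partial mapping whose worst pair
#' deviation exceeds `pair_tol`. Complete mappings are returned in
#' lexicographic order of target residue indices, capped at
#' `max_candidates` (a truncation flag is set, not an error).
#'
#' @param site A `BindingSite`.
#' @param target A `Structure`.
#' @param subs Substitution sets from [substitution_sets()] (computed at
#'   cutoff 1 when `NULL`).
#' @param pair_tol Pairwise distance tolerance in Angstrom (default 2.0).
#' @param max_candidates Cap on emitted mappings (default 50000).
#' @return List with `mappings` (matrix, one row per candidate, columns =
#'   query positions, entries = target residue indices) and `truncated`.
#' @export
enumerate_candidates <- function(site, target, subs = NULL, pair_tol = 2,
                                 max_candidates = 50000L) {
  stopifnot(inherits(site, "BindingSite"), inherits(target, "Structure"))
  if (pair_tol <= 0) stop("pair_tol must be positive")
  n <- site_size(site)
  if (is.null(subs)) subs <- substitution_sets(site)
  Dq <- as.matrix(stats::dist(site$rep_coords))
  taa <- target$residues$aa1
  N <- length(taa)
  empty <- list(mappings = matrix(integer(0), 0L, n), truncated = FALSE)
  if (N < n) return(empty)
  compat <- lapply(subs, function(s) which(taa %in% s))
  if (any(vapply(compat, length, integer(1)) == 0L)) return(empty)
  Dt <- as.matrix(stats::dist(ca_coords(target)))

  # anchor pair = largest query distance (ties: smallest indices)
  up <- which(upper.tri(Dq), arr.ind = TRUE)
  best <- up[which.max(Dq[up]), ]
  i0 <- best[1]
  j0 <- best[2]
  rest <- setdiff(seq_len(n), c(i0, j0))

  acc <- vector("list", 256L)
  n_acc <- 0L
  truncated <- FALSE

  extend <- function(assign_vec, depth) {
    if (truncated) return()
    if (depth > length(rest)) {
      n_acc <<- n_acc + 1L
      acc[[n_acc]] <<- assign_vec
      if (n_acc >= max_candidates) truncated <<- TRUE
      return()
    }
    k <- rest[depth]
    cand <- compat[[k]]
    cand <- cand[!cand %in% assign_vec]
    mapped <- which(!is.na(assign_vec))
    for (m in mapped) {
      if (length(cand) == 0L) return()
      cand <- cand[abs(Dt[cand, assign_vec[m]] - Dq[k, m]) <= pair_tol]
    }
    for (tcand in cand) {
      nxt <- assign_vec
      nxt[k] <- tcand
      extend(nxt, depth + 1L)
      if (truncated) return()
    }
  }

  dq0 <- Dq[i0, j0]
  for (a in compat[[i0]]) {
    bs <- compat[[j0]]
    bs <- bs[bs != a]
    bs <- bs[abs(Dt[a, bs] - dq0) <= pair_tol]
    for (b in bs) {
      base <- rep(NA_integer_, n)
      base[i0] <- a
      base[j0] <- b
      extend(base, 1L)
      if (truncated) break
    }
    if (truncated) break
  }
  if (n_acc == 0L) return(empty)
  mp <- do.call(rbind, acc[seq_len(n_acc)])
  ord <- do.call(order, as.data.frame(mp))
  list(mappings = mp[ord, , drop = FALSE], truncated = truncated)
}

#' Calibrate an empirical null RMSD distribution
#'
#' Samples random code-compatible residue combinations from decoy structures
#' (uniform over structures, then uniform over compatible residues per query
#' position, injective) and records their Kabsch RMSD to the query site. The
#' sorted sample is the empirical null used by [null_p_value()]; it stands in
#' for the unpublished analytic P-value of the original search tool.
#'
#' @param site A `BindingSite`.
#' @param decoy_db A non-empty `StructureDB` disjoint from the search
#'   database.
#' @param n_samples Number of null samples (minimum 100; default 20000,
#'   which resolves P-values small enough for E < 0.01 at database sizes
#'   of a few hundred).
#' @param seed Integer seed; the null is a pure function of it.
#' @return Object of class `NullModel` with sorted `rmsd_samples`.
#' @export
calibrate_null <- function(site, decoy_db, n_samples = 20000L, seed = 1L) {
  stopifnot(inherits(site, "BindingSite"), inherits(decoy_db, "StructureDB"))
  if (length(decoy_db) == 0L) stop("decoy database is empty")
  if (n_samples < 100L) stop("n_samples must be at least 100")
  n <- site_size(site)
  subs <- substitution_sets(site)
  per_struct <- lapply(decoy_db$structures, function(s) {
    lapply(subs, function(ss) which(s$residues$aa1 %in% ss))
  })
  ca_list <- lapply(decoy_db$structures, ca_coords)
  feasible <- which(vapply(per_struct, function(cp) {
    all(vapply(cp, length, integer(1)) > 0L) &&
      length(unique(unlist(cp))) >= n
  }, logical(1)))
  if (length(feasible) == 0L) stop("no decoy structure is code-compatible with the site")
  q <- site$rep_coords
  samples <- with_seed(seed, {
    out <- numeric(n_samples)
    got <- 0L
    tries <- 0L
    max_tries <- n_samples * 20L
    while (got < n_samples && tries < max_tries) {
      tries <- tries + 1L
      si <- feasible[sample.int(length(feasible), 1L)]
      cp <- per_struct[[si]]
      pick <- integer(n)
      ok <- TRUE
      for (k in seq_len(n)) {
        avail <- cp[[k]][!cp[[k]] %in% pick[seq_len(k - 1L)]]
        if (length(avail) == 0L) { ok <- FALSE; break }
        pick[k] <- avail[sample.int(length(avail), 1L)]
      }
      if (!ok) next
      got <- got + 1L
      out[got] <- kabsch(q, ca_list[[si]][pick, , drop = FALSE])$rmsd
    }
    out[seq_len(got)]
  })
  if (length(samples) < n_samples) {
    warning(sprintf("only %d of %d requested null samples were feasible",
                    length(samples), n_samples))
  }
  x <- list(n_samples = length(samples), rmsd_samples = sort(samples),
            seed = seed, site_size = n)
  class(x) <- "NullModel"
  x
}

#' Empirical P-value of a match RMSD
#'
#' Add-one empirical tail probability:
#' `p = (1 + #\{null <= rmsd\}) / (n_samples + 1)`.
#'
#' @param null A `NullModel`.
#' @param rmsd Observed RMSD in Angstrom.
#' @return P-value in `(0, 1]`.
#' @export
null_p_value <- function(null, rmsd) {
  stopifnot(inherits(null, "NullModel"))
  (1 + sum(null$rmsd_samples <= rmsd)) / (null$n_samples + 1)
}

#' E-value of a match
#'
#' Expected number of equally good matches by chance in a database of the
#' given size: `p_value * db_size`.
#'
#' @param p P-value.
#' @param db_size Number of structures searched.
#' @return Non-negative E-value.
#' @export
e_value <- function(p, db_size) {
  stopifnot(p >= 0, p <= 1, db_size >= 0)
  p * db_size
}

#' Search a structure database for matches to a binding site
#'
#' For each structure: enumerate candidates, filter by CMAD, superpose the
#' survivors (Kabsch RMSD), keep the best (lowest-RMSD) match per structure,
#' and assign empirical P-/E-values. Matches with `e_value < e_cutoff` are
#' returned sorted by E-value then RMSD.
#'
#' @param site A `BindingSite`.
#' @param db A non-empty `StructureDB`.
#' @param null A `NullModel` from [calibrate_null()].
#' @param cmad_cutoff CMAD filter in Angstrom (default 1.5).
#' @param pair_tol,max_candidates Passed to [enumerate_candidates()].
#' @param e_cutoff Significance cutoff on the E-value (default 0.01; use
#'   `Inf` to keep every best-per-structure match).
#' @param score_cutoff BLOSUM62 cutoff for [substitution_sets()].
#' @return Object of class `SiteHits`: list with `matches` (list of
#'   `SiteMatch` records), `db_size` and `query_site_id`.
#' @export
site_search <- function(site, db, null, cmad_cutoff = 1.5, pair_tol = 2,
                        max_candidates = 50000L, e_cutoff = 0.01,
                        score_cutoff = 1) {
  stopifnot(inherits(site, "BindingSite"), inherits(null, "NullModel"))
  if (!inherits(db, "StructureDB") || length(db) == 0L) {
    stop("search stage: empty or invalid structure database")
  }
  subs <- substitution_sets(site, score_cutoff)
  qcm <- contact_matrix(site)
  dq <- qcm$dist[lower.tri(qcm$dist)]
  q <- site$rep_coords
  db_size <- length(db)
  matches <- list()
  for (s in db$structures) {
    enum <- enumerate_candidates(site, s, subs, pair_tol, max_candidates)
    if (nrow(enum$mappings) == 0L) next
    tca <- ca_coords(s)
    cmads <- apply(enum$mappings, 1L, function(mp) {
      mean(abs(dq - as.numeric(stats::dist(tca[mp, , drop = FALSE]))))
    })
    keep <- which(cmads < cmad_cutoff)
    if (length(keep) == 0L) next
    best <- NULL
    for (ki in keep) {
      mp <- enum$mappings[ki, ]
      fit <- kabsch(q, tca[mp, , drop = FALSE])
      if (is.null(best) || fit$rmsd < best$rmsd) {
        best <- list(mapping = mp, cmad = cmads[ki], rmsd = fit$rmsd,
                     transform = fit[c("rotation", "translation")])
      }
    }
    p <- null_p_value(null, best$rmsd)
    m <- list(query_site_id = site$site_id, target_struct = s$struct_id,
              mapping = best$mapping, cmad = unname(best$cmad),
              rmsd = best$rmsd, transform = best$transform,
              p_value = p, e_value = e_value(p, db_size),
              truncated = enum$truncated)
    class(m) <- "SiteMatch"
    matches[[length(matches) + 1L]] <- m
  }
  if (length(matches) > 0L) {
    ev <- vapply(matches, function(m) m$e_value, numeric(1))
    rm_ <- vapply(matches, function(m) m$rmsd, numeric(1))
    matches <- matches[order(ev, rm_)]
    keep <- vapply(matches, function(m) m$e_value < e_cutoff, logical(1))
    matches <- matches[keep]
  }
  x <- list(query_site_id = site$site_id, matches = matches,
            db_size = db_size, e_cutoff = e_cutoff)
  class(x) <- "SiteHits"
  x
}

#' @export
print.SiteHits <- function(x, ...) {
  cat(sprintf("<SiteHits for %s: %d significant match(es) in %d structures>\n",
              x$query_site_id, length(x$matches), x$db_size))
  invisible(x)
}

#' Hit table of a search result
#'
#' @param hits A `SiteHits` object.
#' @param path Optional TSV output path; a JSON sidecar `<path>.json` with
#'   the rigid transforms (12 floats each) is written alongside.
#' @return Data frame with one row per match.
#' @export
hit_table <- function(hits, path = NULL) {
  rows <- lapply(hits$matches, function(m) {
    data.frame(query_site_id = m$query_site_id, target_struct = m$target_struct,
               n_mapped = length(m$mapping), cmad = m$cmad, rmsd = m$rmsd,
               p_value = m$p_value, e_value = m$e_value,
               mapped_residues = paste(m$mapping, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query_site_id = character(0), target_struct = character(0),
               n_mapped = integer(0), cmad = numeric(0), rmsd = numeric(0),
               p_value = numeric(0), e_value = numeric(0),
               mapped_residues = character(0), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    tf <- lapply(hits$matches, function(m) {
      list(target_struct = m$target_struct,
           transform = as.numeric(c(m$transform$rotation,
                                    m$transform$translation)))
    })
    jsonlite::write_json(tf, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}
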