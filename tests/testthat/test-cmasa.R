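test_that("substitution sets follow BLOSUM62 with the own-code guarantee", {
  expect_setequal(substitution_sets("W", 1)[[1]], c("W", "Y", "F"))
  # only the diagonal would survive cutoff 5 for alanine; own code retained
  expect_equal(substitution_sets("A", 5)[[1]], "A")
  all20 <- substitution_sets(c("A", "W"), -10)
  expect_equal(lengths(all20), c(20L, 20L))
  expect_warning(s <- substitution_sets("X", 1), "non-standard")
  expect_equal(length(s[[1]]), 20L)
})

test_that("CMAD is the mean absolute contact-matrix deviation", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  site <- toy_site(coords, c("A", "C", "D"))
  cm <- contact_matrix(site)
  expect_equal(cmad(cm, coords), 0)
  # candidate triangle with every side exactly 1 A longer (4, 5, 6)
  cand <- rbind(c(0, 0, 0), c(4, 0, 0),
                c((16 + 36 - 25) / 8, sqrt(36 - ((16 + 36 - 25) / 8)^2), 0))
  expect_equal(cmad(cm, cand), 1, tolerance = 1e-9)
  expect_error(cmad(cm, coords[1:2, ]), "size")

  set.seed(41)
  for (rep in 1:5) {
    q <- matrix(rnorm(12, sd = 4), 4, 3)
    c4 <- matrix(rnorm(12, sd = 4), 4, 3)
    s4 <- toy_site(q, c("A", "C", "D", "E"))
    dq <- as.matrix(dist(q)); dc <- as.matrix(dist(c4))
    oracle <- mean(abs(dq[lower.tri(dq)] - dc[lower.tri(dc)]))
    expect_equal(cmad(contact_matrix(s4), c4), oracle, tolerance = 1e-12)
  }
})

test_that("Kabsch superposition recovers rigid motions, excludes reflections", {
  set.seed(51)
  a <- matrix(rnorm(18, sd = 5), 6, 3)
  tf <- random_rigid(2)
  b <- apply_transform(a, tf)
  fit <- kabsch(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, tf$rotation, tolerance = 1e-6)
  expect_equal(apply_transform(a, fit), b, tolerance = 1e-6)
  # proper rotation invariants
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  # mirror image of a chiral 4-point set cannot be superposed
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.3, 1.7))
  mirror <- chiral %*% diag(c(1, 1, -1))
  fitm <- kabsch(chiral, mirror)
  expect_gt(fitm$rmsd, 0.1)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-8)
  expect_error(kabsch(matrix(0, 3, 3), matrix(0, 3, 3)), "rank-0")
})

test_that("Kabsch RMSD matches a rotation-grid search oracle", {
  set.seed(61)
  for (rep in 1:2) {
    a <- matrix(rnorm(15, sd = 3), 5, 3)
    b <- matrix(rnorm(15, sd = 3), 5, 3)
    expect_equal(kabsch(a, b)$rmsd, grid_rmsd_oracle(a, b), tolerance = 1e-4)
  }
})

test_that("candidate enumeration finds planted copies and nothing impossible", {
  qc <- make_query_complex(42)
  site <- qc$site
  # a target that literally contains the site coordinates
  n <- site_size(site)
  extra <- sweep(matrix(rnorm(30, sd = 3), 10, 3), 2, c(40, 0, 0), "+")
  tgt <- toy_structure(rbind(site$rep_coords, extra),
                       c(site$labels, sample(c("L", "V"), 10, TRUE)),
                       id = "PLANT")
  enum <- enumerate_candidates(site, tgt)
  expect_gt(nrow(enum$mappings), 0)
  expect_true(any(apply(enum$mappings, 1, function(m)
    all(m == seq_len(n)))))
  # no compatible residue for any query position -> empty
  allp <- toy_structure(matrix(rnorm(36), 12, 3), rep("P", 12))
  site_nop <- toy_site(site$rep_coords[1:4, ], c("W", "W", "W", "W"))
  expect_equal(nrow(enumerate_candidates(site_nop, allp)$mappings), 0)
})

test_that("enumeration equals exhaustive search on small instances", {
  set.seed(71)
  for (rep in 1:3) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    site <- toy_site(q, sample(c("L", "I", "V", "A"), 4, TRUE))
    tgt <- toy_structure(matrix(rnorm(36, sd = 4), 12, 3),
                         sample(c("L", "I", "V", "A", "M", "S"), 12, TRUE))
    subs <- substitution_sets(site)
    got <- enumerate_candidates(site, tgt, subs, pair_tol = 2)$mappings
    oracle <- exhaustive_candidates(site, tgt, subs, pair_tol = 2)
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("raising the enumeration cap never worsens the best CMAD", {
  qc <- make_query_complex(42)
  pl <- plant_site(make_decoy(80, 17), qc$site, plant_spec(0.5, 1, 3),
                   ligand = qc$ligand)
  cm <- contact_matrix(qc$site)
  best_cmad <- function(cap) {
    mp <- enumerate_candidates(qc$site, pl$structure,
                               max_candidates = cap)$mappings
    if (nrow(mp) == 0) return(Inf)
    min(apply(mp, 1, function(m)
      cmad(cm, ca_coords(pl$structure, m))))
  }
  expect_lte(best_cmad(50000), best_cmad(5))
})

test_that("the empirical null is seeded, stable across seeds, and add-one", {
  qc <- make_query_complex(42)
  decoys <- structure_db(lapply(1:6, function(i) make_decoy(60, 600 + i)))
  n1 <- calibrate_null(qc$site, decoys, n_samples = 1000, seed = 1)
  n1b <- calibrate_null(qc$site, decoys, n_samples = 1000, seed = 1)
  expect_identical(n1$rmsd_samples, n1b$rmsd_samples)
  expect_false(is.unsorted(n1$rmsd_samples))
  # two independent seeds give close empirical CDFs (Kolmogorov-Smirnov)
  n2 <- calibrate_null(qc$site, decoys, n_samples = 1000, seed = 2)
  ks <- suppressWarnings(stats::ks.test(n1$rmsd_samples, n2$rmsd_samples))
  expect_lt(unname(ks$statistic), 0.08)

  null <- list(n_samples = 999L, rmsd_samples = sort(runif(999, 2, 10)),
               seed = 1L, site_size = 5L)
  class(null) <- "NullModel"
  expect_equal(null_p_value(null, 0.5), 1 / 1000)
  expect_equal(null_p_value(null, 99), 1)
  expect_equal(e_value(0.001, 100), 0.1)
  # monotone in rmsd
  r <- sort(runif(20, 0, 12))
  p <- vapply(r, null_p_value, numeric(1), null = null)
  expect_false(is.unsorted(p))
})

test_that("search recovers its own source structure with zero deviation", {
  qc <- make_query_complex(23)
  db <- structure_db(c(list(qc$structure),
                       lapply(1:8, function(i) make_decoy(80, 800 + i))))
  decoys <- structure_db(lapply(1:6, function(i) make_decoy(80, 880 + i)))
  null <- calibrate_null(qc$site, decoys, n_samples = 2000, seed = 4)
  hits <- site_search(qc$site, db, null)
  expect_gte(length(hits$matches), 1)
  top <- hits$matches[[1]]
  expect_equal(top$target_struct, qc$struct_id)
  expect_equal(top$cmad, 0, tolerance = 1e-9)
  expect_equal(top$rmsd, 0, tolerance = 1e-9)
  expect_equal(top$e_value, top$p_value * length(db))
})

test_that("search is specific on decoy-only databases", {
  qc <- make_query_complex(42)
  calib <- structure_db(lapply(1:6, function(i) make_decoy(60, 7000 + i)))
  null <- calibrate_null(qc$site, calib, n_samples = 2000, seed = 9)
  clean_runs <- vapply(1:50, function(r) {
    db <- structure_db(lapply(1:6, function(i)
      make_decoy(60, 10000 + 10 * r + i)))
    length(site_search(qc$site, db, null)$matches) == 0L
  }, logical(1))
  expect_gte(mean(clean_runs), 0.95)
})

test_that("CMAD and RMSD of a match are rigid-motion invariant", {
  qc <- make_query_complex(42)
  pl <- plant_site(make_decoy(80, 55), qc$site, plant_spec(0.3, 1, 8),
                   ligand = qc$ligand)
  decoys <- structure_db(lapply(1:5, function(i) make_decoy(60, 9100 + i)))
  null <- calibrate_null(qc$site, decoys, n_samples = 500, seed = 3)
  db1 <- structure_db(list(pl$structure))
  st2 <- transform_structure(pl$structure, random_rigid(77))
  db2 <- structure_db(list(st2))
  h1 <- site_search(qc$site, db1, null, e_cutoff = Inf)
  h2 <- site_search(qc$site, db2, null, e_cutoff = Inf)
  expect_equal(h1$matches[[1]]$cmad, h2$matches[[1]]$cmad, tolerance = 1e-6)
  expect_equal(h1$matches[[1]]$rmsd, h2$matches[[1]]$rmsd, tolerance = 1e-6)
})

test_that("planted noisy sites are recovered at E < 0.01", {
  qc <- make_query_complex(42)
  bm <- make_benchmark(qc$site, n_planted = 3, n_decoys = 12,
                       spec = plant_spec(0.3, 1, 21), n_res = 60,
                       ligand = qc$ligand)
  decoys <- structure_db(lapply(1:6, function(i) make_decoy(60, 9900 + i)))
  null <- calibrate_null(qc$site, decoys, n_samples = 5000, seed = 6)
  hits <- site_search(qc$site, bm$db, null)
  found <- vapply(hits$matches, function(m) m$target_struct, character(1))
  expect_true(all(bm$truth$planted_ids %in% found))
  expect_equal(sum(!found %in% bm$truth$planted_ids), 0)
})
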