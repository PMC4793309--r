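fake_match <- function(transform, target = "T") {
  m <- list(query_site_id = "q", target_struct = target, mapping = 1:3,
            cmad = 0, rmsd = 0, transform = transform, p_value = 0.001,
            e_value = 0.001, truncated = FALSE)
  class(m) <- "SiteMatch"
  m
}

identity_tf <- list(rotation = diag(3), translation = c(0, 0, 0))

test_that("pose transplantation applies the rigid transform exactly", {
  lig <- make_toy_ligand()
  pose0 <- transplant_pose(fake_match(identity_tf), lig)
  expect_equal(pose_coords(pose0),
               unname(as.matrix(lig$atoms[, c("x", "y", "z")])),
               tolerance = 1e-12, ignore_attr = TRUE)

  shift <- list(rotation = diag(3), translation = c(1, 0, 0))
  pose1 <- transplant_pose(fake_match(shift), lig)
  expect_equal(pose1$atoms$x, lig$atoms$x + 1, tolerance = 1e-12)
  expect_equal(pose1$atoms$y, lig$atoms$y, tolerance = 1e-12)

  tf <- random_rigid(3)
  pose2 <- transplant_pose(fake_match(tf), lig)
  d0 <- dist(cbind(lig$atoms$x, lig$atoms$y, lig$atoms$z))
  expect_equal(as.numeric(dist(pose_coords(pose2))), as.numeric(d0),
               tolerance = 1e-6)
})

test_that("self-transplants pass the gate for query fixtures", {
  for (seed in c(42, 7)) {
    qc <- make_query_complex(seed)
    pose <- transplant_pose(fake_match(identity_tf, qc$struct_id), qc$ligand)
    sc <- steric_screen(pose, qc$structure)
    expect_true(sc$passed)
    expect_equal(sc$n_clashes, 0L)
    expect_gte(sc$n_contacts, 3L)
  }
})

test_that("a ligand atom on a Calpha is a clash that fails the gate", {
  qc <- make_query_complex(42)
  lig <- qc$ligand
  ca1 <- ca_coords(qc$structure)[1, ]
  lig$atoms$x[1] <- ca1[1]; lig$atoms$y[1] <- ca1[2]; lig$atoms$z[1] <- ca1[3]
  pose <- transplant_pose(fake_match(identity_tf), lig)
  sc <- steric_screen(pose, qc$structure)
  expect_gte(sc$n_clashes, 1L)
  expect_false(sc$passed)
})

test_that("contact counts equal an exhaustive pair-count oracle", {
  set.seed(81)
  st <- make_decoy(25, 250)
  lig <- toy_ligand_at(matrix(rnorm(12, sd = 5), 4, 3),
                       c("C", "O", "N", "C"))
  pose <- transplant_pose(fake_match(identity_tf), lig)
  sc <- steric_screen(pose, st, clash_dist = 2.2, contact_dist = 4.5)
  ha <- heavy_atoms(st)
  pc <- pose_coords(pose)
  mind <- vapply(seq_len(nrow(ha)), function(i)
    min(sqrt(colSums((t(pc) - c(ha$x[i], ha$y[i], ha$z[i]))^2))), numeric(1))
  expect_equal(sc$n_contacts, sum(mind <= 4.5))
  expect_equal(sc$n_clashes, sum(mind < 2.2))
})

test_that("hydrogen bonds are detected by the polar-pair distance rule", {
  # lysine NZ 2.8 A from a carboxyl oxygen
  st <- toy_structure(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)),
                      c("K", "A", "G"))
  st$atoms <- rbind(st$atoms, data.frame(res_idx = 1L, name = "NZ",
                                         element = "N", x = 2.8, y = 0,
                                         z = 0, is_h = FALSE))
  st <- new_structure("HB", st$residues[, c("chain", "seqno", "ins", "resname")],
                      st$atoms)
  lig <- toy_ligand_at(rbind(c(0, 0, 0), c(1.4, 0.5, 0)), c("O", "C"))
  pose <- transplant_pose(fake_match(identity_tf), lig)
  hb <- detect_hbonds(pose, st)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$protein_atom, "NZ")
  expect_equal(hb$dist, 2.8, tolerance = 1e-9)
  # all polar pairs beyond 3.5 A -> none
  far <- toy_ligand_at(rbind(c(50, 0, 0)), "O")
  expect_equal(nrow(detect_hbonds(transplant_pose(fake_match(identity_tf),
                                                  far), st)), 0L)
})

test_that("hydrogen-bond lists equal an exhaustive polar-pair scan", {
  set.seed(91)
  st <- make_decoy(20, 205)
  lig <- toy_ligand_at(matrix(rnorm(15, sd = 6), 5, 3),
                       c("O", "O", "N", "C", "C"))
  pose <- transplant_pose(fake_match(identity_tf), lig)
  hb <- detect_hbonds(pose, st)
  ha <- heavy_atoms(st)
  pp <- ha[ha$element %in% c("N", "O"), ]
  lp <- lig$atoms[lig$atoms$element %in% c("N", "O"), ]
  count <- 0
  for (i in seq_len(nrow(lp))) for (j in seq_len(nrow(pp))) {
    d <- sqrt(sum((c(lp$x[i], lp$y[i], lp$z[i]) -
                   c(pp$x[j], pp$y[j], pp$z[j]))^2))
    if (d <= 3.5) count <- count + 1
  }
  expect_equal(nrow(hb), count)
})

test_that("the gate is monotone under loosened thresholds", {
  set.seed(101)
  st <- make_decoy(30, 310)
  for (rep in 1:10) {
    lig <- toy_ligand_at(sweep(matrix(rnorm(9, sd = 3), 3, 3), 2,
                               ca_coords(st)[sample(30, 1), ], "+"),
                         c("C", "O", "N"))
    pose <- transplant_pose(fake_match(identity_tf), lig)
    strict <- steric_screen(pose, st, clash_dist = 2.2, min_contacts = 3)
    loose <- steric_screen(pose, st, clash_dist = 1.8, min_contacts = 1)
    if (strict$passed) expect_true(loose$passed)
  }
})

test_that("gate results are invariant under joint rigid motion", {
  qc <- make_query_complex(7)
  pose <- transplant_pose(fake_match(identity_tf), qc$ligand)
  sc0 <- steric_screen(pose, qc$structure)
  tf <- random_rigid(12)
  st2 <- transform_structure(qc$structure, tf)
  pose2 <- transplant_pose(fake_match(tf), qc$ligand)
  sc2 <- steric_screen(pose2, st2)
  expect_equal(sc2$n_clashes, sc0$n_clashes)
  expect_equal(sc2$n_contacts, sc0$n_contacts)
  expect_equal(sc2$passed, sc0$passed)
})
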