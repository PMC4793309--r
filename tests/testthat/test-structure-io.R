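test_that("hand-written PDB text parses into residues, sequence and ligand", {
  st <- parse_pdb(write_tiny_pdb())
  expect_equal(nrow(st$residues), 3L)
  expect_equal(st$sequence, "AGW")
  expect_equal(length(st$ligands), 0L)

  st2 <- parse_pdb(write_tiny_pdb(with_ligand = TRUE))
  expect_equal(length(st2$ligands), 1L)
  expect_equal(st2$ligands[[1]]$resname, "AIN")
  expect_equal(sum(!st2$ligands[[1]]$atoms$is_h), 13L)

  st3 <- parse_pdb(write_tiny_pdb(with_ligand = TRUE), keep_hetero = FALSE)
  expect_equal(length(st3$ligands), 0L)
  expect_error(parse_pdb(tempfile()), "cannot read")
})

test_that("multi-model files reduce to the first model", {
  single <- write_tiny_pdb()
  body <- setdiff(tiny_pdb_lines(), "END")
  multi <- tempfile(fileext = ".pdb")
  shifted <- sub("   0\\.000", "   9.000", body)
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", shifted, "ENDMDL", "END"), multi)
  a <- parse_pdb(single)
  b <- parse_pdb(multi)
  expect_equal(b$residues$resname, a$residues$resname)
  expect_equal(ca_coords(b), ca_coords(a), tolerance = 1e-9)
})

test_that("writing and re-parsing a structure preserves it to 1e-3 A", {
  qc <- make_query_complex(7)
  f <- tempfile(fileext = ".pdb")
  write_pdb(qc$structure, f)
  rt <- parse_pdb(f)
  expect_equal(nrow(rt$residues), nrow(qc$structure$residues))
  expect_equal(rt$residues$resname, qc$structure$residues$resname)
  expect_equal(rt$sequence, qc$structure$sequence)
  expect_lt(max(abs(ca_coords(rt) - ca_coords(qc$structure))), 1e-3)
  expect_equal(length(rt$ligands), 1L)
  expect_equal(nrow(rt$ligands[[1]]$atoms), nrow(qc$ligand$atoms))
})

test_that("sequence identity follows the shorter-sequence convention", {
  expect_equal(sequence_identity("ACDE", "ACDE"), 1)
  expect_equal(sequence_identity("ACDE", "WYWY"), 0)
  # 4 identical positions / length of the shorter sequence (4)
  expect_equal(sequence_identity("ACDEF", "ACDE"), 1)
  expect_error(sequence_identity("", "ACDE"), "empty")
})

test_that("alignment agrees with brute-force enumeration and Biostrings", {
  set.seed(11)
  for (rep in 1:8) {
    a <- paste(sample(c("A", "C", "D", "E", "W"), sample(3:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "W"), sample(3:6, 1), TRUE),
               collapse = "")
    al <- align_global(a, b)
    oracle <- brute_align(a, b)
    expect_equal(al$score, unname(oracle$score))
    expect_true(al$n_identical %in% oracle$idents)
    # symmetry of the normalized identity
    expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  }
  # independent scorer: Biostrings global alignment, same scoring scheme
  m <- matrix(0, 5, 5, dimnames = list(c("A", "C", "D", "E", "W"),
                                       c("A", "C", "D", "E", "W")))
  diag(m) <- 1
  set.seed(12)
  for (rep in 1:5) {
    a <- paste(sample(rownames(m), 8, TRUE), collapse = "")
    b <- paste(sample(rownames(m), 6, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = m,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(align_global(a, b)$score, ref)
  }
})

test_that("greedy clustering collapses duplicates and matches its oracle", {
  mk <- function(seq, id) toy_structure(matrix(rnorm(3 * nchar(seq)), ncol = 3),
                                        strsplit(seq, "")[[1]], id)
  same <- structure_db(lapply(1:3, function(i) mk("ACDEFGHIKL", paste0("s", i))))
  expect_equal(length(cluster_representatives(same, 0.95)), 1L)

  diff3 <- structure_db(list(mk("AAAAAAAAAA", "a"), mk("WWWWWWWWWW", "b"),
                             mk("CCCCCCCCCC", "c")))
  expect_equal(length(cluster_representatives(diff3, 0.95)), 3L)

  set.seed(5)
  seqs <- replicate(10, paste(sample(sitefish:::AA_CODES, 12, TRUE),
                              collapse = ""))
  db <- structure_db(lapply(seq_along(seqs), function(i)
    mk(seqs[i], paste0("r", i))))
  got <- length(cluster_representatives(db, 0.6))
  # independent greedy oracle over the all-pairs identity matrix
  lens <- nchar(seqs)
  ord <- order(-lens, seq_along(seqs))
  reps <- character(0)
  for (k in ord) {
    hit <- FALSE
    for (r in reps) {
      if (sequence_identity(seqs[k], r) >= 0.6) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, seqs[k])
  }
  expect_equal(got, length(reps))
  # representative count is monotone non-increasing as the cutoff drops
  expect_gte(length(cluster_representatives(db, 0.95)),
             length(cluster_representatives(db, 0.6)))
  expect_gte(length(cluster_representatives(db, 0.6)),
             length(cluster_representatives(db, 0.2)))
})

test_that("database manifest lists every structure", {
  db <- structure_db(list(make_decoy(12, 1), make_decoy(15, 2)))
  f <- tempfile(fileext = ".tsv")
  db_manifest(db, f)
  m <- read.delim(f)
  expect_equal(m$struct_id, db$ids)
  expect_equal(m$n_residues, c(12L, 15L))
  expect_error(structure_db(list(make_decoy(12, 1), make_decoy(12, 1))),
               "duplicate")
})
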