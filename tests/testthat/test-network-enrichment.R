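test_that("pairwise RMSD is zero for self and rigid copies", {
  st <- make_decoy(30, 330)
  expect_equal(pairwise_rmsd(st, st), 0, tolerance = 1e-9)
  shifted <- transform_structure(st, list(rotation = diag(3),
                                          translation = c(5, -3, 2)))
  expect_lt(pairwise_rmsd(st, shifted), 1e-6)
})

test_that("pairwise RMSD equals the Kabsch oracle on a known alignment", {
  set.seed(8)
  ca_a <- matrix(rnorm(18, sd = 4), 6, 3)
  ca_b <- ca_a + matrix(rnorm(18, sd = 0.5), 6, 3)
  aa <- c("A", "C", "D", "E", "F", "G")
  a <- toy_structure(ca_a, aa, "A6")
  b <- toy_structure(ca_b, aa, "B6")
  # identical sequences align position-by-position
  expect_equal(pairwise_rmsd(a, b), kabsch(ca_a, ca_b)$rmsd,
               tolerance = 1e-9)
})

test_that("network edges obey the strict RMSD threshold", {
  st <- make_decoy(25, 251)
  twin <- transform_structure(st, random_rigid(9))
  twin$struct_id <- "TWIN"
  net <- build_network(list(A = st, B = twin))
  expect_equal(nrow(net$edges), 1L)
  expect_lt(net$edges$rmsd, 1e-6)

  other <- make_decoy(25, 252)
  r <- pairwise_rmsd(st, other)
  # threshold exactly at the measured RMSD: strictly smaller required
  at <- build_network(list(A = st, B = other), threshold = r)
  expect_equal(nrow(at$edges), 0L)
  above <- build_network(list(A = st, B = other), threshold = r + 1e-6)
  expect_equal(nrow(above$edges), 1L)
})

test_that("network construction matches an exhaustive all-pairs oracle", {
  structs <- lapply(1:5, function(i) make_decoy(20, 2000 + i))
  names(structs) <- paste0("S", 1:5)
  net <- build_network(structs, threshold = 6)
  expected <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    r <- pairwise_rmsd(structs[[i]], structs[[j]])
    if (!is.na(r) && r < 6) expected <- expected + 1
  }
  expect_equal(nrow(net$edges), expected)
  # symmetry: order of the list must not matter
  net2 <- build_network(rev(structs), threshold = 6)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(key(net2$edges), key(net$edges))
})

test_that("network export writes edge list and GraphML", {
  st <- make_decoy(20, 20)
  twin <- transform_structure(st, random_rigid(2))
  twin$struct_id <- "T2"
  net <- build_network(list(A = st, B = twin),
                       categories = c(A = "primary", B = "new"))
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  export_network(net, tsv = tsv, graphml = gml)
  expect_equal(nrow(read.delim(tsv)), 1L)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # background of 4 genes, pathway of 2, targets exactly that pathway
  db <- pathway_db(list(pw = c("g1", "g2")),
                   background = paste0("g", 1:4))
  res <- enrich(c("g1", "g2"), db, alpha = 0.2)
  expect_equal(res$p_raw, 1 / 6, tolerance = 1e-12)
  expect_equal(res$count, 2L)
  expect_equal(res$percentage, 100)
  # overlap 0 has upper-tail probability 1
  db2 <- pathway_db(list(pw = c("g1", "g2")), background = paste0("g", 1:6))
  expect_equal(enrich(c("g5", "g6"), db2)$p_raw, 1)

  set.seed(9)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    bg <- paste0("g", seq_len(N))
    dbx <- pathway_db(list(pw = bg[seq_len(K)]), background = bg)
    targets <- sample(bg, n)
    k <- sum(targets %in% bg[seq_len(K)])
    got <- enrich(targets, dbx)$p_raw
    expect_equal(got, hyper_enum_oracle(k, K, n, N), tolerance = 1e-9)
  }
})

test_that("genes outside the background are dropped with a warning", {
  db <- pathway_db(list(pw = c("g1", "g2", "g3")),
                   background = paste0("g", 1:10))
  expect_warning(res <- enrich(c("g1", "g2", "NOT_A_GENE"), db),
                 "outside the background")
  # percentage denominator is the mapped gene count (2), not the input (3)
  expect_equal(res$count[1], 2L)
  expect_equal(res$percentage[1], 100)
})

test_that("multiple-testing adjustment follows BH and Bonferroni exactly", {
  expect_equal(adjust_p(0.04, "BH"), 0.04)
  expect_equal(adjust_p(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_p(c(0.01, 0.5, 0.7), "bonferroni")[1], 0.03)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_error(adjust_p(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(10)
  for (rep in 1:10) {
    p <- runif(sample(2:12, 1))
    bh <- adjust_p(p, "BH")
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    bonf <- adjust_p(p, "bonferroni")
    expect_true(all(bonf >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
  }
})

test_that("GMT files parse like the reference reader", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tg1\tg2\tg3",
               "pwB\tsomething\tg2\tg4"), f)
  got <- read_gmt(f)
  expect_equal(names(got), c("pwA", "pwB"))
  expect_equal(got$pwA, c("g1", "g2", "g3"))
  ref <- fgsea::gmtPathways(f)
  expect_equal(got, ref)
  writeLines("broken line", f)
  expect_error(read_gmt(f), "malformed")
})
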