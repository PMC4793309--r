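# Internal helpers shared across modules.

# Standard 3-letter -> 1-letter amino acid map; anything else becomes "X".
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_123 <- structure(names(AA_321), names = unname(AA_321))
AA_CODES <- unname(AA_321)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3")

aa321 <- function(res_name) {
  out <- AA_321[toupper(res_name)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa123 <- function(code) {
  out <- AA_123[toupper(code)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness is routed through explicit seeds via this helper.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive k child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Euclidean cross-distance matrix between two n x 3 / m x 3 coordinate sets.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

# BLOSUM62 from Biostrings, cached (20 standard residues only).
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_CODES, AA_CODES]
    }
    cache
  }
})

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
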