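# Global sequence alignment and greedy identity clustering.
#
# The aligner is a plain Needleman-Wunsch with linear gap penalty and a fixed
# traceback tie-break (diagonal > up > left) so that results are fully
# deterministic across platforms. Two scoring modes are used in the package:
# identity scoring (match +1, mismatch 0, gap -1) for redundancy clustering,
# and BLOSUM62 with gap -5 for the structural-network alignment step.

#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' @param a,b Character scalars (one-letter residue codes).
#' @param submat Optional substitution matrix (e.g. BLOSUM62); when `NULL`,
#'   `match`/`mismatch` scoring is used. Codes absent from the matrix score
#'   `mismatch`.
#' @param match,mismatch Scores used when `submat` is `NULL`.
#' @param gap Linear gap penalty per gapped position (negative).
#' @return List with `score`, `n_identical`, and the aligned index vectors
#'   `ai`, `bi` (0 marks a gap).
#' @export
align_global <- function(a, b, submat = NULL, match = 1, mismatch = 0,
                         gap = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av)
  m <- length(bv)
  if (is.null(submat)) {
    S <- outer(av, bv, function(x, y) ifelse(x == y, match, mismatch))
  } else {
    S <- matrix(mismatch, n, m)
    ok_a <- av %in% rownames(submat)
    ok_b <- bv %in% colnames(submat)
    S[ok_a, ok_b] <- submat[av[ok_a], bv[ok_b], drop = FALSE]
  }
  F <- matrix(0, n + 1L, m + 1L)
  F[1L, ] <- gap * (0:m)
  F[, 1L] <- gap * (0:n)
  # 0 = diagonal, 1 = up (consume a), 2 = left (consume b)
  P <- matrix(0L, n + 1L, m + 1L)
  P[1L, -1L] <- 2L
  P[-1L, 1L] <- 1L
  for (i in seq_len(n)) {
    fprev <- F[i, ]
    frow <- numeric(m + 1L)
    prow <- integer(m + 1L)
    frow[1L] <- gap * i
    prow[1L] <- 1L
    for (j in seq_len(m)) {
      d <- fprev[j] + S[i, j]
      u <- fprev[j + 1L] + gap
      l <- frow[j] + gap
      if (d >= u && d >= l) {
        frow[j + 1L] <- d
      } else if (u >= l) {
        frow[j + 1L] <- u
        prow[j + 1L] <- 1L
      } else {
        frow[j + 1L] <- l
        prow[j + 1L] <- 2L
      }
    }
    F[i + 1L, ] <- frow
    P[i + 1L, ] <- prow
  }
  ai <- integer(0)
  bi <- integer(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 0L) {
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1L; j <- j - 1L
    } else if (p == 1L) {
      ai <- c(i, ai); bi <- c(0L, bi); i <- i - 1L
    } else {
      ai <- c(0L, ai); bi <- c(j, bi); j <- j - 1L
    }
  }
  both <- ai > 0L & bi > 0L
  list(score = F[n + 1L, m + 1L],
       n_identical = sum(both & av[pmax(ai, 1L)] == bv[pmax(bi, 1L)]),
       ai = ai, bi = bi)
}

#' Pairwise sequence identity
#'
#' Identity of the optimal global alignment (match +1, mismatch 0, gap -1),
#' normalized by the shorter sequence length (the convention used by
#' CD-HIT-style redundancy removal).
#'
#' @param seq_a,seq_b Non-empty one-letter sequences.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  al <- align_global(seq_a, seq_b, match = 1, mismatch = 0, gap = -1)
  al$n_identical / min(nchar(seq_a), nchar(seq_b))
}

#' Greedy non-redundant representative selection
#'
#' Structures are visited in order of decreasing sequence length; each joins
#' the first existing representative with identity at or above `cutoff`,
#' otherwise it founds a new cluster. Only representatives are returned, in
#' the order their clusters were founded. This is the documented stand-in
#' for CD-HIT redundancy removal at the same identity cutoff.
#'
#' @param db A [structure_db()].
#' @param cutoff Identity cutoff in `(0, 1]` (default 0.95).
#' @return A `StructureDB` of representatives.
#' @export
cluster_representatives <- function(db, cutoff = 0.95) {
  stopifnot(inherits(db, "StructureDB"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (length(db) == 0L) return(db)
  lens <- vapply(db$structures, function(s) nchar(s$sequence), integer(1))
  ord <- order(-lens, seq_along(lens))
  reps <- list()
  for (k in ord) {
    s <- db$structures[[k]]
    joined <- FALSE
    for (r in reps) {
      if (sequence_identity(s$sequence, r$sequence) >= cutoff) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps[[length(reps) + 1L]] <- s
  }
  structure_db(reps, meta = sprintf("representatives at identity >= %.2f",
                                    cutoff))
}
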