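# Descriptive statistics over predicted binding pockets.

#' Build a pocket profile
#'
#' @param target_id Identifier of the target protein.
#' @param resnames Character vector of 3-letter residue codes in the pocket
#'   (one-letter codes are also accepted and converted).
#' @param formed_hbond Logical: did the pose form at least one hydrogen bond
#'   with this pocket.
#' @param chain,seqno Optional per-residue metadata.
#' @return Object of class `PocketProfile` with `size` and `has_KST` (any
#'   lysine/serine/threonine, the residues assumed acetylatable).
#' @export
pocket_profile <- function(target_id, resnames, formed_hbond = FALSE,
                           chain = NULL, seqno = NULL) {
  resnames <- toupper(resnames)
  if (all(nchar(resnames) == 1L)) resnames <- aa123(resnames)
  x <- list(target_id = target_id, resnames = resnames,
            aa1 = aa321(resnames),
            chain = chain, seqno = seqno,
            size = length(resnames),
            has_KST = any(resnames %in% c("LYS", "SER", "THR")),
            formed_hbond = isTRUE(formed_hbond))
  class(x) <- "PocketProfile"
  x
}

#' Pocket profile from a binding site
#'
#' Uses the same heavy-atom distance rule as site extraction so one pocket
#' definition serves both search and statistics.
#'
#' @param site A `BindingSite`.
#' @param formed_hbond Logical flag, typically from [detect_hbonds()].
#' @param target_id Defaults to the site's source structure.
#' @return A [pocket_profile()].
#' @export
pocket_from_site <- function(site, formed_hbond = FALSE, target_id = NULL) {
  pocket_profile(target_id %||% site$source_struct, site$residues$resname,
                 formed_hbond = formed_hbond, chain = site$residues$chain,
                 seqno = site$residues$seqno)
}

#' Residue composition across pockets
#'
#' @param pockets List of `PocketProfile`s.
#' @param threshold Count threshold for the `frequent` helper column
#'   (default 20).
#' @return Object of class `CompositionTable`: per-code counts, the codes
#'   above `threshold`, and `n_pockets`.
#' @export
composition <- function(pockets, threshold = 20) {
  if (length(pockets) == 0L) stop("no pockets")
  codes <- unlist(lapply(pockets, function(p) p$aa1))
  counts <- table(factor(codes, levels = AA_CODES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  x <- list(counts = counts,
            frequent = names(counts)[counts > threshold],
            threshold = threshold,
            n_pockets = length(pockets))
  class(x) <- "CompositionTable"
  x
}

#' Acetylation-candidate screen
#'
#' Counts pockets containing at least one lysine, serine or threonine (the
#' residues assumed acetylatable by aspirin's acetyl group).
#'
#' @param pockets List of `PocketProfile`s.
#' @return List with `n_with_KST`, `n_pockets` and `fraction`.
#' @export
acetylation_screen <- function(pockets) {
  if (length(pockets) == 0L) stop("no pockets")
  n <- sum(vapply(pockets, function(p) p$has_KST, logical(1)))
  list(n_with_KST = n, n_pockets = length(pockets),
       fraction = n / length(pockets))
}

#' Fraction of pockets that formed hydrogen bonds
#'
#' @param pockets List of `PocketProfile`s with `formed_hbond` set.
#' @return Fraction in `[0, 1]`.
#' @export
hbond_fraction <- function(pockets) {
  if (length(pockets) == 0L) stop("no pockets")
  mean(vapply(pockets, function(p) p$formed_hbond, logical(1)))
}

#' Read pocket residue lists from a TSV file
#'
#' Expected columns: `target_id`, `resname` (3-letter), and optionally
#' `chain`, `seqno`, `formed_hbond`. One row per pocket residue; used to
#' ingest externally supplied pocket tables for cross-checks.
#'
#' @param path TSV path.
#' @return List of [pocket_profile()]s, one per `target_id`, in file order.
#' @export
read_pocket_lists <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("target_id", "resname") %in% names(d)))
  ids <- unique(d$target_id)
  lapply(ids, function(id) {
    rows <- d[d$target_id == id, , drop = FALSE]
    hb <- if ("formed_hbond" %in% names(rows)) any(rows$formed_hbond) else FALSE
    pocket_profile(id, rows$resname, formed_hbond = hb,
                   chain = rows$chain %||% NULL, seqno = rows$seqno %||% NULL)
  })
}

#' Write a pocket statistics report
#'
#' @param pockets List of `PocketProfile`s.
#' @param path_json,path_tsv Optional output paths.
#' @param threshold Passed to [composition()].
#' @return List with `composition`, `acetylation`, `hbond_fraction`.
#' @export
pocket_report <- function(pockets, path_json = NULL, path_tsv = NULL,
                          threshold = 20) {
  comp <- composition(pockets, threshold)
  acet <- acetylation_screen(pockets)
  rep <- list(n_pockets = comp$n_pockets,
              sizes = vapply(pockets, function(p) p$size, integer(1)),
              composition = as.list(comp$counts),
              frequent = comp$frequent,
              acetylation = acet,
              hbond_fraction = hbond_fraction(pockets))
  if (!is.null(path_json)) {
    jsonlite::write_json(rep, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_tsv)) {
    tab <- data.frame(
      target_id = vapply(pockets, function(p) p$target_id, character(1)),
      size = rep$sizes,
      has_KST = vapply(pockets, function(p) p$has_KST, logical(1)),
      formed_hbond = vapply(pockets, function(p) p$formed_hbond, logical(1)),
      residues = vapply(pockets, function(p) paste(p$aa1, collapse = ""),
                        character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rep
}
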