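# Target structural-similarity network and pathway over-representation.

#' Sequence-alignment-guided pairwise RMSD
#'
#' Globally aligns the two sequences (BLOSUM62, linear gap penalty), then
#' superposes the aligned Calpha pairs by the Kabsch algorithm and returns
#' the RMSD. Pairs with fewer than 3 aligned residues are incomparable
#' (`NA`, no network edge).
#'
#' @param a,b `Structure`s.
#' @param gap Linear gap penalty (default -5).
#' @return RMSD in Angstrom, or `NA_real_` if incomparable.
#' @export
pairwise_rmsd <- function(a, b, gap = -5) {
  stopifnot(inherits(a, "Structure"), inherits(b, "Structure"))
  al <- align_global(a$sequence, b$sequence, submat = blosum62(),
                     mismatch = -4, gap = gap)
  both <- al$ai > 0L & al$bi > 0L
  if (sum(both) < 3L) return(NA_real_)
  kabsch(ca_coords(a, al$ai[both]), ca_coords(b, al$bi[both]))$rmsd
}

#' Build the target structural-similarity network
#'
#' Evaluates every unordered structure pair and places an edge where the
#' aligned-Calpha RMSD is strictly smaller than `threshold`.
#'
#' @param structures Named list of `Structure`s (names are node ids;
#'   `struct_id`s are used when unnamed).
#' @param categories Optional named character vector (`primary`/`new`) per
#'   node.
#' @param threshold Edge threshold in Angstrom (default 4.0, strict `<`).
#' @return Object of class `TargetNetwork` with `nodes` and `edges` data
#'   frames (edges carry their RMSD).
#' @export
build_network <- function(structures, categories = NULL, threshold = 4) {
  if (threshold <= 0) stop("threshold must be positive")
  ids <- names(structures) %||%
    vapply(structures, function(s) s$struct_id, character(1))
  if (is.null(names(structures))) names(structures) <- ids
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  nodes$category <- if (is.null(categories)) NA_character_ else
    unname(categories[ids])
  edges <- data.frame(from = character(0), to = character(0),
                      rmsd = numeric(0), stringsAsFactors = FALSE)
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- pairwise_rmsd(structures[[i]], structures[[j]])
        if (!is.na(r) && r < threshold) {
          edges <- rbind(edges, data.frame(from = ids[i], to = ids[j],
                                           rmsd = r, stringsAsFactors = FALSE))
        }
      }
    }
  }
  x <- list(nodes = nodes, edges = edges, threshold = threshold)
  class(x) <- "TargetNetwork"
  x
}

#' @export
print.TargetNetwork <- function(x, ...) {
  cat(sprintf("<TargetNetwork: %d nodes, %d edges (RMSD < %.1f A)>\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param network A `TargetNetwork`.
#' @param tsv,graphml Output paths (either may be `NULL`).
#' @return The edge data frame, invisibly.
#' @export
export_network <- function(network, tsv = NULL, graphml = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(network$edges, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(network$edges)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of gene symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ","))
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}

#' Build a pathway database with a background universe
#'
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Gene universe; defaults to the union of all pathway
#'   genes. Pathway genes outside the background are dropped.
#' @return Object of class `PathwayDB`.
#' @export
pathway_db <- function(pathways, background = NULL) {
  if (length(pathways) == 0L) stop("no pathways")
  background <- unique(background %||% unlist(pathways))
  if (length(background) == 0L) stop("empty background gene universe")
  pathways <- lapply(pathways, function(g) intersect(unique(g), background))
  keep <- vapply(pathways, length, integer(1)) > 0L
  x <- list(pathways = pathways[keep], background = background)
  class(x) <- "PathwayDB"
  x
}

#' Adjust P-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Bonferroni, preserving input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted P-values in input order.
#' @export
adjust_p <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Pathway over-representation analysis
#'
#' Hypergeometric upper-tail test per pathway: with `k` = overlap of the
#' target genes with the pathway, `K` = pathway size, `n` = number of target
#' genes in the background, `N` = background size, the raw P-value is
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Target genes outside the
#' background are dropped with a warning. The percentage column is
#' `overlap / n * 100` (denominator = targets mapped to the annotation).
#'
#' @param target_genes Character vector of gene symbols.
#' @param db A [pathway_db()].
#' @param method Multiple-testing adjustment (default `"BH"`).
#' @param alpha Significance threshold on the adjusted P-value
#'   (default 0.01).
#' @return Data frame sorted by adjusted then raw P-value with columns
#'   `pathway`, `count`, `percentage`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich <- function(target_genes, db, method = c("BH", "bonferroni"),
                   alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(db, "PathwayDB"))
  target_genes <- unique(target_genes)
  outside <- setdiff(target_genes, db$background)
  if (length(outside) > 0L) {
    warning(length(outside), " target gene(s) outside the background dropped")
    target_genes <- intersect(target_genes, db$background)
  }
  n <- length(target_genes)
  if (n == 0L) stop("no target genes in the background universe")
  N <- length(db$background)
  rows <- lapply(names(db$pathways), function(pw) {
    genes <- db$pathways[[pw]]
    k <- length(intersect(target_genes, genes))
    K <- length(genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, count = k, percentage = 100 * k / n,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_p(out$p_raw, method)
  out$method <- method
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p_raw, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
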