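# Pipeline orchestration: site search -> pose gate -> energy filter ->
# pocket stats / similarity network / enrichment, with stage-count
# reporting and deterministic seeded execution.

#' Build a validated pipeline configuration
#'
#' All stage thresholds in one place. The database is either a directory of
#' PDB files (`db_dir`) or a seeded synthetic benchmark (`benchmark`); the
#' query is either a `QueryComplex` or a seed for [make_query_complex()].
#'
#' @param query A `QueryComplex`, or `NULL` to generate one from
#'   `query_seed`.
#' @param query_seed Seed for the synthetic query complex.
#' @param db_dir Optional directory of target PDB files.
#' @param benchmark Optional list with `n_planted`, `n_decoys`,
#'   `noise_sigma`, `n_substitutions`, `n_res` describing a synthetic
#'   benchmark database (used when `db_dir` is `NULL`).
#' @param site_cutoff Site extraction cutoff, Angstrom (default 5).
#' @param cmad_cutoff CMAD filter, Angstrom (default 1.5).
#' @param pair_tol Enumeration pair tolerance, Angstrom (default 2).
#' @param e_cutoff Hit significance E-value cutoff (default 0.01).
#' @param n_null,null_decoys,null_decoy_res Null calibration size and decoy
#'   set.
#' @param clash_dist,contact_dist,max_clashes,min_contacts Pose gate
#'   thresholds.
#' @param t_delta_s Fixed entropy change, kcal/mol (default 4.728).
#' @param network_threshold Network edge RMSD threshold, Angstrom
#'   (default 4).
#' @param enrich_method,alpha Enrichment adjustment and significance level.
#' @param gmt,gene_map Optional pathway annotation: GMT path and named
#'   vector mapping struct_ids to gene symbols.
#' @param seed Master seed for the run.
#' @param out_dir Output directory for stage tables.
#' @return Object of class `PipelineConfig`.
#' @export
pipeline_config <- function(query = NULL, query_seed = 42L, db_dir = NULL,
                            benchmark = list(n_planted = 10L, n_decoys = 100L,
                                             noise_sigma = 0.3,
                                             n_substitutions = 1L,
                                             n_res = 80L),
                            site_cutoff = 5, cmad_cutoff = 1.5, pair_tol = 2,
                            e_cutoff = 0.01, n_null = 20000L,
                            null_decoys = 15L, null_decoy_res = 80L,
                            clash_dist = 2.2, contact_dist = 4.5,
                            max_clashes = 0L, min_contacts = 3L,
                            t_delta_s = 4.728, network_threshold = 4,
                            enrich_method = "BH", alpha = 0.01,
                            gmt = NULL, gene_map = NULL,
                            seed = 1L, out_dir = tempfile("sitefish_run_")) {
  thr <- c(site_cutoff = site_cutoff, cmad_cutoff = cmad_cutoff,
           pair_tol = pair_tol, e_cutoff = e_cutoff,
           clash_dist = clash_dist, contact_dist = contact_dist,
           network_threshold = network_threshold, alpha = alpha)
  if (any(thr <= 0)) {
    stop("non-positive threshold(s): ",
         paste(names(thr)[thr <= 0], collapse = ", "))
  }
  if (!is.null(db_dir) && !dir.exists(db_dir)) {
    stop("db_dir does not exist: ", db_dir)
  }
  x <- list(query = query, query_seed = query_seed, db_dir = db_dir,
            benchmark = benchmark, site_cutoff = site_cutoff,
            cmad_cutoff = cmad_cutoff, pair_tol = pair_tol,
            e_cutoff = e_cutoff, n_null = n_null, null_decoys = null_decoys,
            null_decoy_res = null_decoy_res, clash_dist = clash_dist,
            contact_dist = contact_dist, max_clashes = max_clashes,
            min_contacts = min_contacts, t_delta_s = t_delta_s,
            network_threshold = network_threshold,
            enrich_method = enrich_method, alpha = alpha, gmt = gmt,
            gene_map = gene_map, seed = as.integer(seed), out_dir = out_dir)
  class(x) <- "PipelineConfig"
  x
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  message("[sitefish] ", msg)
  if (!is.null(con)) writeLines(paste(Sys.time(), msg), con)
}

#' Run the full target-fishing pipeline
#'
#' Stage order: database assembly, binding-site search, pose gate
#' (transplant + steric screen), free-energy filter, pocket statistics,
#' structural-similarity network, and (when annotation is configured)
#' pathway enrichment. Every stage writes its table under
#' `config$out_dir`; the stage counts satisfy the funnel invariant
#' `n_energy_passed <= n_gate_passed <= n_site_hits <= n_db`. Given the same
#' configuration and seed the run is deterministic.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `StageReport`: `counts`, `tables` (paths),
#'   `targets` (final data frame), `recall`/`truth` for synthetic
#'   benchmarks, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  seeds <- derive_seeds(config$seed, 4L)
  hash <- config_hash(config)
  pipeline_log(logf, "run start (config %s, seed %d)", hash, config$seed)

  # --- query ---------------------------------------------------------------
  query <- config$query %||%
    make_query_complex(seeds[1], cutoff = config$site_cutoff)
  site <- query$site
  pipeline_log(logf, "query %s: site of %d residues", query$struct_id,
               site_size(site))

  # --- database ------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$db_dir)) {
    db <- tryCatch(read_structure_dir(config$db_dir), error = function(e) {
      stop("search stage: ", conditionMessage(e), call. = FALSE)
    })
  } else {
    b <- config$benchmark
    bm <- make_benchmark(site, n_planted = b$n_planted,
                         n_decoys = b$n_decoys,
                         spec = plant_spec(b$noise_sigma, b$n_substitutions,
                                           seeds[2]),
                         n_res = b$n_res, ligand = query$ligand)
    db <- bm$db
    truth <- bm$truth
  }
  if (length(db) == 0L) stop("search stage: empty structure database")
  n_db <- length(db)
  db_manifest(db, file.path(config$out_dir, "db_manifest.tsv"))
  pipeline_log(logf, "database: %d structures", n_db)

  # --- search --------------------------------------------------------------
  null_db <- structure_db(lapply(seq_len(config$null_decoys), function(i) {
    make_decoy(config$null_decoy_res, seeds[3] + i,
               struct_id = sprintf("NULLDECOY_%03d", i))
  }), meta = "null calibration decoys")
  null <- calibrate_null(site, null_db, n_samples = config$n_null,
                         seed = seeds[4])
  hits <- site_search(site, db, null, cmad_cutoff = config$cmad_cutoff,
                      pair_tol = config$pair_tol, e_cutoff = config$e_cutoff)
  hit_table(hits, file.path(config$out_dir, "hits.tsv"))
  n_site_hits <- length(hits$matches)
  pipeline_log(logf, "search: %d significant hit(s) at E < %g", n_site_hits,
               config$e_cutoff)

  # --- pose gate -----------------------------------------------------------
  by_id <- stats::setNames(db$structures, db$ids)
  screen_rows <- list()
  passed <- list()
  for (m in hits$matches) {
    target <- by_id[[m$target_struct]]
    pose <- transplant_pose(m, query$ligand)
    sc <- steric_screen(pose, target, clash_dist = config$clash_dist,
                        contact_dist = config$contact_dist,
                        max_clashes = config$max_clashes,
                        min_contacts = config$min_contacts)
    hb <- detect_hbonds(pose, target)
    screen_rows[[length(screen_rows) + 1L]] <- data.frame(
      target_struct = m$target_struct, n_clashes = sc$n_clashes,
      n_contacts = sc$n_contacts, n_hbonds = nrow(hb), passed = sc$passed,
      stringsAsFactors = FALSE)
    if (sc$passed) {
      passed[[length(passed) + 1L]] <- list(match = m, pose = pose,
                                            target = target,
                                            n_hbonds = nrow(hb))
    }
  }
  screen_tab <- if (length(screen_rows)) do.call(rbind, screen_rows) else
    data.frame(target_struct = character(0), n_clashes = integer(0),
               n_contacts = integer(0), n_hbonds = integer(0),
               passed = logical(0))
  utils::write.table(screen_tab, file.path(config$out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_gate_passed <- length(passed)
  pipeline_log(logf, "pose gate: %d of %d passed", n_gate_passed, n_site_hits)

  # --- energy --------------------------------------------------------------
  energy_rows <- lapply(passed, function(p) {
    sc <- score_pose(p$pose, p$target)
    energy_record(p$match$target_struct, sc$g_complex, sc$g_receptor,
                  sc$g_ligand, e_mm = sc$e_mm)
  })
  energy_tab <- if (length(energy_rows)) do.call(rbind, energy_rows) else
    energy_record(character(0), numeric(0), numeric(0), numeric(0))[0, ]
  targets <- apply_entropy_and_filter(energy_tab,
                                      t_delta_s_fixed = config$t_delta_s)
  utils::write.table(
    cbind(energy_tab,
          kept = energy_tab$delta_h - config$t_delta_s < 0),
    file.path(config$out_dir, "energy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  n_energy_passed <- nrow(targets)
  pipeline_log(logf, "energy filter: %d target(s) with dG < 0",
               n_energy_passed)

  # --- pocket statistics ---------------------------------------------------
  kept_ids <- targets$target_id
  kept <- passed[vapply(passed, function(p)
    p$match$target_struct %in% kept_ids, logical(1))]
  pockets <- lapply(kept, function(p) {
    ps <- tryCatch(
      extract_site(p$target,
                   new_ligand(query$ligand$resname, p$pose$atoms),
                   cutoff = config$site_cutoff),
      error = function(e) NULL)
    if (is.null(ps)) {
      pocket_profile(p$match$target_struct,
                     p$target$residues$resname[p$match$mapping],
                     formed_hbond = p$n_hbonds > 0)
    } else {
      pocket_from_site(ps, formed_hbond = p$n_hbonds > 0,
                       target_id = p$match$target_struct)
    }
  })
  stats_rep <- if (length(pockets) > 0L) {
    pocket_report(pockets,
                  path_json = file.path(config$out_dir, "pocket_stats.json"),
                  path_tsv = file.path(config$out_dir, "pockets.tsv"))
  } else NULL

  # --- similarity network --------------------------------------------------
  net <- NULL
  if (length(kept) >= 2L) {
    structs <- stats::setNames(lapply(kept, function(p) p$target),
                               vapply(kept, function(p)
                                 p$match$target_struct, character(1)))
    net <- build_network(structs, threshold = config$network_threshold)
    export_network(net, tsv = file.path(config$out_dir, "network_edges.tsv"),
                   graphml = file.path(config$out_dir, "network.graphml"))
  }

  # --- enrichment ----------------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt) && !is.null(config$gene_map)) {
    pdb_ <- pathway_db(read_gmt(config$gmt))
    genes <- unname(config$gene_map[kept_ids])
    genes <- genes[!is.na(genes)]
    if (length(genes) > 0L) {
      enr <- enrich(genes, pdb_, method = config$enrich_method,
                    alpha = config$alpha)
      utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  counts <- c(n_db = n_db, n_site_hits = n_site_hits,
              n_gate_passed = n_gate_passed,
              n_energy_passed = n_energy_passed)
  if (is.unsorted(rev(counts))) stop("funnel invariant violated")
  recall <- NULL
  if (!is.null(truth)) {
    recall <- list(
      search = mean(truth$planted_ids %in%
                      vapply(hits$matches, function(m) m$target_struct,
                             character(1))),
      final = mean(truth$planted_ids %in% kept_ids),
      false_positives = sum(!kept_ids %in% truth$planted_ids))
    pipeline_log(logf, "recall: search %.2f, final %.2f, FP %d",
                 recall$search, recall$final, recall$false_positives)
  }
  report <- list(counts = counts,
                 tables = list.files(config$out_dir, full.names = TRUE),
                 targets = targets, pocket_stats = stats_rep,
                 network = net, enrichment = enr, truth = truth,
                 recall = recall, seed = config$seed, config_hash = hash,
                 out_dir = config$out_dir)
  class(report) <- "StageReport"
  jsonlite::write_json(
    list(counts = as.list(counts), seed = config$seed, config_hash = hash,
         recall = recall),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  pipeline_log(logf, "run complete")
  report
}

#' @export
print.StageReport <- function(x, ...) {
  cat(sprintf(paste0("<StageReport: db %d -> hits %d -> gate %d -> ",
                     "dG<0 %d>\n"),
              x$counts["n_db"], x$counts["n_site_hits"],
              x$counts["n_gate_passed"], x$counts["n_energy_passed"]))
  invisible(x)
}

#' Target-table report
#'
#' Classifies a putative-target table into primary and new targets, writes
#' the table and a summary JSON.
#'
#' @param records Data frame with `gene`, `uniprot`, `family`, `delta_g`
#'   (see [read_target_table()]).
#' @param primary_families Passed to [classify_and_summarize()].
#' @param out_dir Optional output directory for `targets.tsv` and
#'   `target_summary.json`.
#' @return The [classify_and_summarize()] `TargetSummary`.
#' @export
table1_report <- function(records, primary_families = primary_target_families(),
                          out_dir = NULL) {
  summ <- classify_and_summarize(records, primary_families)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_target_table(summ$records, file.path(out_dir, "targets.tsv"))
    jsonlite::write_json(summ[setdiff(names(summ), "records")],
                         file.path(out_dir, "target_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summ
}
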