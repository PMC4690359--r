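#' Run the complete analysis pipeline
#'
#' Executes the full workflow on a matrix, age table, and area table:
#' heuristic parsimony search (with collapsing and deduplication), strict
#' and majority-rule consensus, Bremer and bootstrap supports, the
#' unambiguous character-change list, minimum-age time calibration with
#' ghost lineages, stratigraphic congruence metrics under uncertainty,
#' and the three ancestral-area reconstructions: PB (parsimony), LEB
#' (likelihood, every branch length 1), and LFR (likelihood, ghost-lineage
#' branch lengths).
#'
#' @param x a [morph_matrix()].
#' @param ages an `age_table` covering the taxa.
#' @param areas an `area_table` covering the taxa.
#' @param config a [search_config()].
#' @param n_bootstrap bootstrap pseudoreplicates (0 to skip).
#' @param bremer compute Bremer supports.
#' @param out_dir optional directory to write trees, tables, and a JSON
#'   manifest into.
#' @return object of class `strat_pipeline` with components `search`,
#'   `consensus`, `majority`, `bootstrap`, `bremer`, `changes`,
#'   `calibrated`, `strat`, `pb`, `leb`, `lfr`, `manifest`.
#' @export
run_full_analysis <- function(x, ages, areas, config = search_config(),
                              n_bootstrap = 0L, bremer = FALSE,
                              out_dir = NULL) {
  validate_taxa(ages, x$taxa)
  validate_taxa(areas, x$taxa)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    tick(stage)
    out
  }

  search <- run_stage("search", heuristic_search(x, config))
  consensus <- run_stage("consensus", strict_consensus(search$mpts))
  majority <- run_stage("majority", majority_rule_consensus(search$mpts))
  boot <- if (n_bootstrap > 0L)
    run_stage("bootstrap",
              bootstrap_supports(x, config, n_pseudoreplicates = n_bootstrap))
  else NULL
  brm <- if (bremer) run_stage("bremer", bremer_supports(x, search)) else NULL
  changes <- run_stage("synapomorphies",
                       unambiguous_changes(search$mpts_binary, x))
  calibrated <- run_stage("calibration", calibrate(consensus, ages, "oldest"))
  strat <- run_stage("stratigraphy",
                     strat_metrics(consensus, ages,
                                   seed = child_seed(config$seed, 99L)))
  pb <- run_stage("PB", parsimony_areas(consensus, areas))
  leb_tree <- assign_branch_lengths(consensus, "unit")
  leb <- run_stage("LEB", marginal_areas(leb_tree, areas, method = "LEB"))
  lfr_tree <- assign_branch_lengths(consensus, "ghost", ages = ages)
  lfr <- run_stage("LFR", marginal_areas(lfr_tree, areas, method = "LFR"))

  manifest <- list(
    n_taxa = n_taxa(x), n_characters = n_char(x),
    seed = config$seed,
    replicates = config$replicates,
    best_length = search$best_length,
    n_mpts = length(search$mpts),
    n_bootstrap = n_bootstrap,
    timings = as.list(round(timings, 3L))
  )
  out <- structure(list(search = search, consensus = consensus,
                        majority = majority, bootstrap = boot, bremer = brm,
                        changes = changes, calibrated = calibrated,
                        strat = strat, pb = pb, leb = leb, lfr = lfr,
                        manifest = manifest),
                   class = "strat_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, x, out_dir)
  out
}

#' @export
print.strat_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run:", m$n_taxa, "taxa x", m$n_characters, "characters\n")
  cat("  best length", m$best_length, "from", m$n_mpts,
      "distinct collapsed trees\n")
  cat(sprintf("  MIG on consensus: [%.1f, %.1f] myr\n",
              x$strat$table$lo[1L], x$strat$table$hi[1L]))
  invisible(x)
}

write_pipeline <- function(res, x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(res$consensus, file.path(dir, "strict_consensus.nwk"))
  write_newick(res$majority, file.path(dir, "majority_consensus.nwk"))
  writeLines(vapply(res$search$mpts, write_newick, ""),
             file.path(dir, "mpts.nwk"))
  ct <- res$calibrated
  cal <- ct$tree
  cal$edge.length <- ct$ghost
  write_newick(cal, file.path(dir, "calibrated_ghost.nwk"))
  utils::write.table(res$strat$table, file.path(dir, "strat_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  chg <- res$changes
  chg$clade <- vapply(chg$clade, function(cl) paste(cl, collapse = "+"), "")
  utils::write.table(chg, file.path(dir, "unambiguous_changes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  node_tab <- do.call(rbind, lapply(list(res$pb, res$leb, res$lfr),
                                    function(r) {
    ntip <- length(r$tree$tip.label)
    inner <- r$values[-seq_len(ntip), , drop = FALSE]
    data.frame(analysis = r$method, node = rownames(inner),
               round(100 * inner, 1L),
               best = colnames(inner)[apply(inner, 1L, which.max)],
               check.names = FALSE)
  }))
  utils::write.table(node_tab, file.path(dir, "ancestral_areas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$bootstrap)) {
    bt <- res$bootstrap
    bt$clade <- vapply(bt$clade, function(cl) paste(cl, collapse = "+"), "")
    utils::write.table(bt, file.path(dir, "bootstrap.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$bremer)) {
    br <- res$bremer
    br$clade <- vapply(br$clade, function(cl) paste(cl, collapse = "+"), "")
    utils::write.table(br, file.path(dir, "bremer.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Locate the published study files, if installed
#'
#' The full published analysis (65 taxa, 255 characters) requires the
#' study's supplementary data files, which are not distributed with the
#' package: the character matrix (TNT or NEXUS), the first-appearance age
#' table, and the taxon-area table.  Place them under
#' `inst/extdata/study/` as `matrix.tnt`, `ages.csv`, and `areas.csv`
#' before installation (or point this function at a directory) and the
#' full pipeline can be reproduced with [run_full_analysis()].
#'
#' @param dir directory to look in; defaults to the installed package's
#'   `extdata/study`.
#' @return list with `matrix`, `ages`, `areas` paths, or an error naming
#'   the missing files.
#' @export
study_data_paths <- function(dir = system.file("extdata", "study",
                                               package = "stratphylo")) {
  files <- c(matrix = "matrix.tnt", ages = "ages.csv", areas = "areas.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (dir == "" || any(missing))
    stop("study data files not installed: ",
         paste(files[if (dir == "") TRUE else missing], collapse = ", "),
         "; see ?study_data_paths")
  as.list(paths)
}
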