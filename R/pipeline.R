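#' Run a pipeline command from a configuration
#'
#' Orchestrates the simulate / detect / coloc / enrich / loci stages as
#' single reproducible runs. The configuration is a named list (or a JSON
#' file of one) with a `command`, an `output_dir`, an `rng_seed`, and
#' per-module parameter blocks; every output table carries the hash of
#' the resolved configuration, and re-running an unchanged configuration
#' reproduces byte-identical tables.
#'
#' Commands:
#' * `"simulate"` — spot-field cohort; writes `truth_spots.csv`.
#' * `"coloc"` — matching on a spot table (simulated here, or an
#'   `input_spots` CSV); writes `coloc_per_cell.csv` and
#'   `coloc_summary.json`.
#' * `"enrich"` — enrichment scoring on a count TSV (`input_counts`) or a
#'   simulated matrix; writes `enrichment.tsv`.
#' * `"loci"` — locus-pair cohort classification; writes
#'   `locus_calls.csv` and `locus_summary.json`.
#' * `"end-to-end"` — simulate + coloc in one run.
#'
#' @param config named list or path to a JSON file.
#' @return list with `output_dir`, `config_hash`, `files` (named paths),
#'   and the in-memory `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$command))
    stop_mod("run_pipeline", "command", "missing")
  command <- match.arg(config$command,
                       c("simulate", "coloc", "enrich", "loci",
                         "end-to-end"))
  out_dir <- config$output_dir %||% stop_mod("run_pipeline", "output_dir",
                                             "missing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the run parameters, not where they are written
  hash <- config_hash(config[setdiff(names(config), "output_dir")])
  files <- list()
  results <- list()
  log_lines <- c(sprintf("command: %s", command),
                 sprintf("config_hash: %s", hash))

  sim_cfg <- function() {
    blk <- config$simulate %||% list()
    do.call(sim_config, c(blk, list(rng_seed = config$rng_seed %||% 1L)))
  }

  if (command %in% c("simulate", "coloc", "end-to-end")) {
    if (command != "coloc" || is.null(config$input_spots)) {
      cfg <- sim_cfg()
      cohort <- simulate_cohort(cfg)
      truth <- fields_to_spot_table(cohort$fields)
      files$truth_spots <- file.path(out_dir, "truth_spots.csv")
      write_spot_table(truth, files$truth_spots, hash)
      results$truth <- truth
      log_lines <- c(log_lines,
                     sprintf("simulated %d cells, true_rho = %g",
                             cfg$n_cells, cfg$true_rho))
      spots <- truth
    } else {
      spots <- read_spot_table(config$input_spots)
    }
    if (command %in% c("coloc", "end-to-end")) {
      blk <- config$coloc %||% list()
      gate <- blk$gate_radius %||% 0.3
      ref <- blk$reference %||% "a"
      cc <- coloc_cohort(spots, gate_radius = gate, reference = ref)
      files$per_cell <- file.path(out_dir, "coloc_per_cell.csv")
      write_spot_table(cc$per_cell, files$per_cell, hash)
      s <- cc$summary
      files$summary <- file.path(out_dir, "coloc_summary.json")
      jsonlite::write_json(list(config_hash = hash, mean = s$mean,
                                sem = s$sem, n_cells = s$n_cells,
                                gate_radius = gate,
                                reference_channel = ref),
                           files$summary, auto_unbox = TRUE, digits = NA,
                           na = "null")
      results$coloc <- cc
      log_lines <- c(log_lines,
                     sprintf("coloc: mean %.4f, sem %.4f over %d cells",
                             s$mean, s$sem, s$n_cells))
    }
  } else if (command == "enrich") {
    blk <- config$enrich %||% list()
    em <- if (!is.null(config$input_counts)) {
      read_expression_tsv(config$input_counts, roles = blk$roles)
    } else {
      simulate_count_matrix(
        n_genes = blk$n_genes %||% 1000L,
        enriched_ids = blk$enriched_ids %||% character(0),
        fold = blk$fold %||% 4,
        dispersion = blk$dispersion %||% 0.1,
        rng_seed = config$rng_seed %||% 1L)
    }
    tab <- score_enrichment(em,
                            dispersion = blk$dispersion %||% 0.1,
                            min_fold = blk$min_fold %||% 4,
                            max_fdr = blk$max_fdr %||% 0.001)
    files$enrichment <- file.path(out_dir, "enrichment.tsv")
    con <- file(files$enrichment, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    results$enrichment <- tab
    log_lines <- c(log_lines,
                   sprintf("enrich: %d/%d genes pass the filter",
                           sum(tab$enriched), nrow(tab)))
  } else if (command == "loci") {
    blk <- config$loci %||% list()
    cohort <- simulate_locus_cohort(
      n_cells = blk$n_cells %||% 100L,
      class_probs = blk$class_probs %||% c(0.1, 0.7, 0.2),
      rng_seed = config$rng_seed %||% 1L)
    sc <- score_locus_cohort(cohort,
                             full_threshold = blk$full_threshold %||% 0.9)
    calls <- do.call(rbind, lapply(sc$calls, function(cl)
      data.frame(cell_id = cl$cell_id, overlap = cl$overlap,
                 centroid_distance_um = cl$centroid_distance_um,
                 label = cl$label, stringsAsFactors = FALSE)))
    files$calls <- file.path(out_dir, "locus_calls.csv")
    write_spot_table(calls, files$calls, hash)
    files$summary <- file.path(out_dir, "locus_summary.json")
    jsonlite::write_json(list(config_hash = hash,
                              classes = sc$table,
                              n_excluded = sc$n_excluded),
                         files$summary, digits = NA, dataframe = "rows")
    results$loci <- sc
    log_lines <- c(log_lines,
                   sprintf("loci: %d scored, %d excluded",
                           length(sc$calls), sc$n_excluded))
  }

  files$log <- file.path(out_dir, "run.log")
  writeLines(log_lines, files$log)
  list(output_dir = out_dir, config_hash = hash, files = files,
       results = results)
}

#' Render summary figures from a result bundle
#'
#' Writes static PNG figures next to the tables: a per-cell scatter of
#' co-localization fractions with mean +/- SEM bars, an enrichment
#' heatmap, and a locus-class histogram — whichever tables the bundle
#' contains.
#'
#' @param bundle result of [run_pipeline()] or a directory path.
#' @return character vector of figure paths (possibly empty), invisibly.
#' @export
render_report <- function(bundle) {
  dir <- if (is.character(bundle)) bundle else bundle$output_dir
  out <- character(0)
  per_cell_path <- file.path(dir, "coloc_per_cell.csv")
  if (file.exists(per_cell_path)) {
    pc <- read_spot_table(per_cell_path)
    f <- file.path(dir, "coloc_scatter.png")
    grDevices::png(f, 600, 600)
    x <- jitter(rep(1, nrow(pc)), amount = 0.1)
    plot(x, pc$fraction, xlim = c(0.5, 1.5), ylim = c(0, 1),
         xlab = "", ylab = "co-localized fraction per cell", xaxt = "n",
         pch = 19, col = grDevices::adjustcolor("steelblue", 0.6))
    m <- mean(pc$fraction, na.rm = TRUE)
    sem <- sd(pc$fraction, na.rm = TRUE) / sqrt(sum(!is.na(pc$fraction)))
    graphics::segments(0.8, m, 1.2, m, lwd = 3)
    graphics::arrows(1, m - sem, 1, m + sem, angle = 90, code = 3,
                     length = 0.1)
    grDevices::dev.off()
    out <- c(out, f)
  }
  enr_path <- file.path(dir, "enrichment.tsv")
  if (file.exists(enr_path)) {
    tab <- read.delim(enr_path, comment.char = "#")
    f <- file.path(dir, "enrichment_heatmap.png")
    grDevices::png(f, 600, 800)
    top <- head(tab[order(-tab$fold_change), ], 25)
    mat <- matrix(log2(top$fold_change), ncol = 1,
                  dimnames = list(top$gene, "pulldown"))
    graphics::image(t(mat)[, nrow(mat):1, drop = FALSE], axes = FALSE,
                    main = "log2 fold change (top genes)")
    grDevices::dev.off()
    out <- c(out, f)
  }
  calls_path <- file.path(dir, "locus_calls.csv")
  if (file.exists(calls_path)) {
    calls <- read_spot_table(calls_path)
    f <- file.path(dir, "locus_classes.png")
    grDevices::png(f, 600, 600)
    tb <- tabulate_calls(calls$label)
    graphics::barplot(tb$percent, names.arg = tb$label,
                      ylab = "% of cells", ylim = c(0, 100))
    grDevices::dev.off()
    out <- c(out, f)
  }
  invisible(out)
}
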