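# End-to-end pipeline: simulate -> segment -> quantify -> correlate -> enrich.
#
# A run is a pure function of its configuration: a single top-level seed is
# stably hashed into per-stage, per-line, per-replicate streams, so
# replicates differ from each other but the whole run reproduces exactly.
# Every stage writes plain-text tables; the manifest records their relative
# paths and md5 checksums.

PIPELINE_VERSION <- "0.1.0"

#' Default run configuration
#'
#' @param lines list of line descriptors; each a list with `line_id`,
#'   `faithfulness` (1, 2 or 3), `patterns` (named list: structure/division
#'   acronym -> pattern category), `n_replicates` (1-6) and `plane`
#'   ("coronal" or "sagittal").
#' @param atlas atlas spec, see [default_atlas_spec()].
#' @param seed top-level integer seed.
#' @param out_dir output directory.
#' @param base_density lambda0 (cells per mm^3).
#' @param noise list with `b0`, `sigma` (background level and texture sd).
#' @param pixel_size_um rendered pixel edge.
#' @param segmentation list with `k`, `s_min`.
#' @param grid_size_um unionization grid edge.
#' @param write_images also write the rendered PNG series (slower).
#' @return a `cre_config` list.
#' @export
run_config <- function(lines, atlas = default_atlas_spec(),
                       seed = 1L, out_dir = tempfile("crequant_run_"),
                       base_density = 5000,
                       noise = list(b0 = 20, sigma = 5),
                       pixel_size_um = 10,
                       segmentation = list(k = 3, s_min = 2),
                       grid_size_um = 200, write_images = FALSE) {
  cfg <- list(lines = lines, atlas = atlas, seed = as.integer(seed),
              out_dir = out_dir, base_density = base_density, noise = noise,
              pixel_size_um = pixel_size_um, segmentation = segmentation,
              grid_size_um = grid_size_um, write_images = isTRUE(write_images))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cq_assert(length(cfg$lines) >= 1, "config needs at least one line",
            "invalid_spec")
  for (ln in cfg$lines) {
    cq_assert(!is.null(ln$line_id) && nzchar(ln$line_id),
              "every line needs a line_id", "invalid_spec")
    nr <- ln$n_replicates %||% 1L
    cq_assert(nr >= 1 && nr <= 6,
              sprintf("line %s: n_replicates must be within 1-6", ln$line_id),
              "invalid_spec")
    cq_assert((ln$plane %||% "coronal") %in% c("coronal", "sagittal"),
              sprintf("line %s: unknown plane", ln$line_id), "invalid_spec")
    cq_assert((ln$faithfulness %||% 1) %in% 1:3,
              sprintf("line %s: faithfulness must be 1, 2 or 3", ln$line_id),
              "invalid_spec")
  }
  cq_assert(!anyDuplicated(vapply(cfg$lines, `[[`, "", "line_id")),
            "duplicate line_id", "invalid_spec")
  structure(cfg, class = "cre_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @return a validated `cre_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  atlas <- do.call(default_atlas_spec, raw$atlas %||% list())
  args <- raw[setdiff(names(raw), "atlas")]
  args$atlas <- atlas
  do.call(run_config, args)
}

stage_log <- function(fmt, ...) {
  message(sprintf("[crequant %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the whole characterization pipeline
#'
#' Builds the toy atlas, simulates every line's endogenous-gene and Cre
#' reporter image series, segments and quantifies them into per-structure
#' expression energies, computes per-line gene-vs-reporter correlations
#' with percentile bins and the replicate baseline, and the fold-change
#' enrichment table.  All outputs are plain-text tables under
#' `config$out_dir`; the returned manifest lists them with checksums.
#'
#' @param config a `cre_config` from [run_config()] / [read_config()].
#' @param quiet suppress per-stage log messages.
#' @return the manifest (also written to `manifest.json`): version, seed,
#'   relative table paths, md5 checksums.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  log_ <- if (quiet) function(...) invisible() else stage_log
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  tables <- character(0)

  log_("atlas: building toy atlas")
  atlas <- build_toy_atlas(config$atlas, seed = derive_seed(seed, "atlas"))
  partition <- midlevel_partition(atlas$ontology, atlas$annotation)
  write_ontology_csv(atlas$ontology, file.path(out, "ontology.csv"))
  tables <- c(tables, "ontology.csv")

  energies <- list()   # [[line_id]][[probe]] -> list of cre_energy
  for (ln in config$lines) {
    lid <- ln$line_id
    log_("simulate: line %s", lid)
    gt_gene <- sample_ground_truth(atlas$ontology, ln$patterns,
                                   base_density = config$base_density)
    pair <- make_line_pair(gt_gene, ln$faithfulness %||% 1,
                           seed = derive_seed(seed, "pair", lid))
    for (probe in c("endogenous", "tdTomato")) {
      gt <- if (probe == "endogenous") pair$gene else pair$cre
      gt_path <- sprintf("ground_truth_%s_%s.csv", lid, probe)
      write_ground_truth_csv(gt, file.path(out, gt_path))
      tables <- c(tables, gt_path)
      evs <- list()
      for (rep_i in seq_len(ln$n_replicates %||% 1L)) {
        cells <- place_cells(gt, atlas$annotation, partition,
                             seed = derive_seed(seed, "cells", lid, probe, rep_i))
        series <- generate_series(cells, atlas$annotation,
                                  plane = ln$plane %||% "coronal",
                                  pixel_size_um = config$pixel_size_um,
                                  noise = config$noise, line_id = lid,
                                  probe = probe, replicate_index = rep_i,
                                  seed = derive_seed(seed, "series", lid,
                                                     probe, rep_i))
        if (config$write_images)
          write_series(series, file.path(out, sprintf("images_%s_%s_r%d",
                                                      lid, probe, rep_i)))
        ev <- quantify_series(series, atlas$annotation, partition,
                              k = config$segmentation$k,
                              s_min = config$segmentation$s_min,
                              grid_size_um = config$grid_size_um)
        ev_path <- sprintf("energy_%s_%s_r%d.csv", lid, probe, rep_i)
        write_energy_csv(ev, file.path(out, ev_path), atlas$ontology)
        tables <- c(tables, ev_path)
        evs[[rep_i]] <- ev
      }
      energies[[lid]][[probe]] <- evs
    }
  }

  log_("correlate: %d lines", length(config$lines))
  corrs <- lapply(config$lines, function(ln) {
    line_correlation(energies[[ln$line_id]][["endogenous"]],
                     energies[[ln$line_id]][["tdTomato"]],
                     comparison = "gene_vs_reporter", line_id = ln$line_id)
  })
  mean_rhos <- vapply(corrs, `[[`, 0, "mean_rho")
  bins <- percentile_bins(mean_rhos)
  corr_df <- data.frame(
    line_id = vapply(corrs, `[[`, "", "line_id"),
    comparison = vapply(corrs, `[[`, "", "comparison"),
    n_pairs = vapply(corrs, `[[`, 0L, "n_pairs"),
    mean_rho = mean_rhos,
    mean_rho_sq = vapply(corrs, `[[`, 0, "mean_rho_sq"),
    percentile_bin = bins)
  baseline <- tryCatch(
    replicate_baseline(lapply(energies, `[[`, "tdTomato")),
    crequant_incomparable_datasets_error = function(e) NA_real_)
  corr_df <- rbind(corr_df,
                   data.frame(line_id = "(replicate baseline)",
                              comparison = "replicate", n_pairs = NA_integer_,
                              mean_rho = baseline, mean_rho_sq = baseline^2,
                              percentile_bin = "unbinned"))
  utils::write.csv(corr_df, file.path(out, "correlations.csv"),
                   row.names = FALSE, quote = TRUE)
  tables <- c(tables, "correlations.csv")

  log_("enrich: fold-change table")
  exemplars <- lapply(energies, function(e) e$tdTomato[[1]])
  enr <- fold_change_table(unname(exemplars))
  enr$acronym <- atlas$ontology$nodes$acronym[match(enr$structure_id,
                                                    atlas$ontology$nodes$id)]
  utils::write.csv(enr, file.path(out, "enrichment.csv"), row.names = FALSE,
                   quote = TRUE)
  tables <- c(tables, "enrichment.csv")

  checksums <- unname(tools::md5sum(file.path(out, tables)))
  manifest <- list(version = PIPELINE_VERSION, seed = seed,
                   n_lines = length(config$lines),
                   grid_size_um = config$grid_size_um,
                   segmentation = config$segmentation,
                   noise = config$noise, base_density = config$base_density,
                   pixel_size_um = config$pixel_size_um,
                   atlas = config$atlas,
                   out_dir = out, tables = tables, checksums = checksums)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_("done: %d tables under %s", length(tables), out)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Per line: the coarse division-level energy summary (12 divisions in the
#' default atlas), the line's correlation and percentile bin, and its top
#' enriched structures.  Regeneration from the same manifest is byte-stable.
#'
#' @param manifest manifest list from [run_pipeline()], or path to
#'   `manifest.json`.
#' @param top_n number of top fold-change structures to list per line.
#' @return character vector of report lines, invisibly; also written to
#'   `report.txt` in the run directory.
#' @export
summarize_run <- function(manifest, top_n = 5) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out <- manifest$out_dir
  rpt <- c(sprintf("crequant run report (version %s, seed %d)",
                   manifest$version, manifest$seed), "")

  ont_path <- file.path(out, "ontology.csv")
  ontology <- if (file.exists(ont_path)) read_ontology_csv(ont_path) else NULL
  corr <- tryCatch(utils::read.csv(file.path(out, "correlations.csv"),
                                   stringsAsFactors = FALSE),
                   error = function(e) NULL)
  enr <- tryCatch(utils::read.csv(file.path(out, "enrichment.csv"),
                                  stringsAsFactors = FALSE),
                  error = function(e) NULL)

  energy_files <- grep("^energy_.*_tdTomato_r1\\.csv$", manifest$tables,
                       value = TRUE)
  for (f in energy_files) {
    lid <- sub("^energy_(.*)_tdTomato_r1\\.csv$", "\\1", f)
    rpt <- c(rpt, sprintf("== line %s ==", lid))
    if (is.null(ontology) || !file.exists(file.path(out, f))) {
      rpt <- c(rpt, "  [division summary unavailable]")
    } else {
      ev <- read_energy_csv(file.path(out, f))
      ds <- division_summary(ev, ontology)
      rpt <- c(rpt, sprintf("  %-5s %s", ds$acronym,
                            ifelse(is.na(ds$energy), "missing",
                                   sprintf("%.4f", ds$energy))))
    }
    if (!is.null(corr) && lid %in% corr$line_id) {
      cr <- corr[corr$line_id == lid, ][1, ]
      rpt <- c(rpt, sprintf("  correlation: mean rho = %.3f (%s bin, %d pairs)",
                            cr$mean_rho, cr$percentile_bin, cr$n_pairs))
    } else rpt <- c(rpt, "  [correlation unavailable]")
    if (!is.null(enr)) {
      rows <- enr[enr$line_id == lid & !is.na(enr$fold_change), ]
      rows <- rows[order(-rows$fold_change, rows$structure_id), ]
      rows <- utils::head(rows, top_n)
      if (nrow(rows) > 0)
        rpt <- c(rpt, "  top enriched structures:",
                 sprintf("    %-6s fold change %.2f", rows$acronym,
                         rows$fold_change))
      else rpt <- c(rpt, "  [fold changes missing]")
    } else rpt <- c(rpt, "  [enrichment unavailable]")
    rpt <- c(rpt, "")
  }
  if (!is.null(corr) && "(replicate baseline)" %in% corr$line_id) {
    b <- corr$mean_rho[corr$line_id == "(replicate baseline)"]
    rpt <- c(rpt, sprintf("replicate baseline: mean rho = %s",
                          ifelse(is.na(b), "n/a", sprintf("%.3f", b))))
  }
  writeLines(rpt, file.path(out, "report.txt"))
  invisible(rpt)
}
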