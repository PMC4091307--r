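# Simulation studies: the package's own validation experiments.
#
# Each study generates synthetic brains with known ground truth, runs the
# full image -> mask -> grid -> energy pipeline, and measures how well a
# downstream statistic recovers the truth: expression strength (rank
# correlation with the generating densities), enrichment mining (does the
# designed restricted line rank first in its structure), and the ordering
# of the three gene-vs-Cre faithfulness categories against the replicate
# baseline.

#' Ground truth directly from a density vector
#'
#' Bypasses the category templates: assigns an explicit lambda (cells per
#' mm^3) per mid-level structure.
#'
#' @param ontology a `cre_ontology`.
#' @param lambda named numeric vector (names = mid-level ids) or unnamed
#'   vector in `ontology$midlevel_ids` order.
#' @param cell_intensity per-cell amplitude parameters.
#' @return a `cre_ground_truth`.
#' @export
ground_truth_from_lambda <- function(ontology, lambda,
                                     cell_intensity = list(mean = 150, sd = 30)) {
  ml <- ontology$midlevel_ids
  if (is.null(names(lambda))) {
    cq_assert(length(lambda) == length(ml),
              "unnamed lambda must cover every mid-level structure",
              "invalid_assignment")
    names(lambda) <- ml
  }
  cq_assert(all(names(lambda) %in% as.character(ml)),
            "unknown structure id in lambda", "invalid_assignment")
  cq_assert(all(lambda >= 0), "lambda must be >= 0", "invalid_assignment")
  lam <- stats::setNames(numeric(length(ml)), ml)
  lam[names(lambda)] <- lambda
  gt <- data.frame(structure_id = ml, lambda = unname(lam),
                   category = ifelse(lam > 0, "widespread", "none"),
                   stringsAsFactors = FALSE)
  structure(gt, cell_intensity = cell_intensity,
            class = c("cre_ground_truth", "data.frame"))
}

#' Expression-strength recovery study
#'
#' Assigns log-spaced densities spanning `lambda_range` across all
#' mid-level structures, simulates one full section series, quantifies it,
#' and reports the Spearman correlation between recovered expression energy
#' and the generating density.
#'
#' @param atlas_spec atlas specification.
#' @param lambda_range density range (cells per mm^3), log-spaced across
#'   structures.
#' @param noise rendering noise (`b0`, `sigma`); `sigma = 0` is noiseless.
#' @param plane sectioning plane.
#' @param seed integer seed.
#' @return list: `rho`, `energy` (the `cre_energy`), `gt`.
#' @export
recovery_study <- function(atlas_spec = default_atlas_spec(),
                           lambda_range = c(1e2, 1e5),
                           noise = list(b0 = 20, sigma = 0),
                           plane = "coronal", seed = 1L) {
  atlas <- build_toy_atlas(atlas_spec, seed = derive_seed(seed, "atlas"))
  partition <- midlevel_partition(atlas$ontology, atlas$annotation)
  ml <- atlas$ontology$midlevel_ids
  lambda <- 10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
                   length.out = length(ml))
  # shuffle so density is not confounded with position along the brain
  lambda <- with_seed(derive_seed(seed, "shuffle"), sample(lambda))
  gt <- ground_truth_from_lambda(atlas$ontology,
                                 stats::setNames(lambda, ml))
  cells <- place_cells(gt, atlas$annotation, partition,
                       seed = derive_seed(seed, "cells"))
  series <- generate_series(cells, atlas$annotation, plane, noise = noise,
                            seed = derive_seed(seed, "series"))
  ev <- quantify_series(series, atlas$annotation, partition)
  rho <- spearman_rho(ev$energy, gt$lambda[match(ev$structure_id,
                                                 gt$structure_id)])
  list(rho = rho, energy = ev, gt = gt)
}

# random pattern assignment for a simulated line: a couple of divisions of
# broad expression plus a few focal structures, leaving zero-density
# structures available for ectopic additions
random_patterns <- function(ontology, seed) {
  with_seed(seed, {
    divs <- ontology$nodes$acronym[match(ontology$division_ids,
                                         ontology$nodes$id)]
    ml_acr <- ontology$nodes$acronym[match(ontology$midlevel_ids,
                                           ontology$nodes$id)]
    p <- list()
    for (d in sample(divs, 2)) p[[d]] <- sample(c("scattered", "widespread"), 1)
    for (s in sample(ml_acr, 3)) p[[s]] <- sample(c("restricted", "enriched",
                                                    "restricted_sparse"), 1)
    p
  })
}

cohort_atlas_spec <- function() default_atlas_spec(6, 3, dims = c(40L, 26L, 48L))

#' Enrichment-mining recovery study
#'
#' Simulates cohorts of Cre lines in which exactly one designed line has
#' expression restricted to a chosen target structure, the others carrying
#' random broad patterns.  For each cohort the tdTomato energies are mined
#' with [fold_change_table()] and [rank_lines_for_structure()]; the study
#' reports how often the designed line ranks first in its target structure.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_lines lines per cohort (1 designed + `n_lines - 1` random).
#' @param atlas_spec atlas specification (a compact 6 x 3 atlas by default).
#' @param noise rendering noise.
#' @param seed integer seed.
#' @return list: `rate` (fraction of cohorts with the designed line at rank
#'   1), `hits` (logical per cohort).
#' @export
enrichment_study <- function(n_cohorts = 20, n_lines = 5,
                             atlas_spec = cohort_atlas_spec(),
                             noise = list(b0 = 20, sigma = 0), seed = 1L) {
  atlas <- build_toy_atlas(atlas_spec, seed = derive_seed(seed, "atlas"))
  partition <- midlevel_partition(atlas$ontology, atlas$annotation)
  ml <- atlas$ontology$midlevel_ids
  ml_acr <- atlas$ontology$nodes$acronym[match(ml, atlas$ontology$nodes$id)]

  quantify_line <- function(gt, lid, s) {
    cells <- place_cells(gt, atlas$annotation, partition, seed = s)
    series <- generate_series(cells, atlas$annotation, "coronal",
                              noise = noise, line_id = lid,
                              seed = derive_seed(s, "series"))
    quantify_series(series, atlas$annotation, partition)
  }

  hits <- vapply(seq_len(n_cohorts), function(ci) {
    target_i <- (ci - 1L) %% length(ml) + 1L
    target <- ml[target_i]
    evs <- vector("list", n_lines)
    gt1 <- sample_ground_truth(atlas$ontology,
                               stats::setNames(list("restricted"),
                                               ml_acr[target_i]))
    evs[[1]] <- quantify_line(gt1, "designed",
                              derive_seed(seed, "cohort", ci, "designed"))
    for (j in 2:n_lines) {
      repeat {  # random line must not itself be focal in the target
        pat <- random_patterns(atlas$ontology,
                               derive_seed(seed, "cohort", ci, "pat", j))
        if (!ml_acr[target_i] %in% names(pat)) break
        pat[[ml_acr[target_i]]] <- NULL
        break
      }
      gtj <- sample_ground_truth(atlas$ontology, pat)
      evs[[j]] <- quantify_line(gtj, sprintf("other%02d", j),
                                derive_seed(seed, "cohort", ci, "line", j))
    }
    ranking <- rank_lines_for_structure(fold_change_table(evs), target)
    ranking$line_id[1] == "designed"
  }, logical(1))
  list(rate = mean(hits), hits = hits)
}

#' Faithfulness-category ordering study
#'
#' Simulates line pairs (endogenous gene vs. Cre reporter) under the three
#' faithfulness categories -- (1) faithful everywhere, (2) faithful plus
#' ectopic structures, (3) faithful in a strict subset -- with replicated
#' series on both sides, computes the replicate-averaged plane-matched
#' correlation per line, and the within-line replicate baseline from the
#' reporter series.
#'
#' @param n_per_category simulated line pairs per category.
#' @param n_replicates replicates per dataset (1-6).
#' @param atlas_spec atlas specification.
#' @param noise rendering noise (default-noise conditions).
#' @param seed integer seed.
#' @return list: `mean_rho` (named, one per category), `baseline`,
#'   `per_line` data frame (line_id, category, mean_rho).
#' @export
faithfulness_study <- function(n_per_category = 10, n_replicates = 2,
                               atlas_spec = cohort_atlas_spec(),
                               noise = list(b0 = 20, sigma = 5), seed = 1L) {
  atlas <- build_toy_atlas(atlas_spec, seed = derive_seed(seed, "atlas"))
  partition <- midlevel_partition(atlas$ontology, atlas$annotation)

  make_evs <- function(gt, lid, probe) {
    lapply(seq_len(n_replicates), function(r) {
      s <- derive_seed(seed, lid, probe, r)
      cells <- place_cells(gt, atlas$annotation, partition, seed = s)
      series <- generate_series(cells, atlas$annotation, "coronal",
                                noise = noise, line_id = lid, probe = probe,
                                replicate_index = r,
                                seed = derive_seed(s, "series"))
      quantify_series(series, atlas$annotation, partition)
    })
  }

  rows <- list(); reporter_sets <- list()
  for (cat_i in 1:3) for (i in seq_len(n_per_category)) {
    lid <- sprintf("cat%d_line%02d", cat_i, i)
    gt_gene <- sample_ground_truth(atlas$ontology,
                                   random_patterns(atlas$ontology,
                                                   derive_seed(seed, lid, "gt")))
    pair <- make_line_pair(gt_gene, cat_i,
                           seed = derive_seed(seed, lid, "pair"))
    evs_gene <- make_evs(pair$gene, lid, "endogenous")
    evs_rep <- make_evs(pair$cre, lid, "tdTomato")
    cr <- line_correlation(evs_gene, evs_rep, line_id = lid)
    rows[[lid]] <- data.frame(line_id = lid, category = cat_i,
                              mean_rho = cr$mean_rho)
    reporter_sets[[lid]] <- evs_rep
  }
  per_line <- do.call(rbind, rows)
  baseline <- if (n_replicates >= 2) replicate_baseline(reporter_sets) else NA_real_
  mean_rho <- tapply(per_line$mean_rho, per_line$category, mean)
  names(mean_rho) <- paste0("category_", names(mean_rho))
  list(mean_rho = mean_rho, baseline = baseline, per_line = per_line)
}
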