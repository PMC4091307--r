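# Synthetic ground truth and cell placement.
#
# The generator's recoverable truth is a per-structure density of expressing
# cells, lambda_s (cells per mm^3).  Six qualitative pattern categories --
# widespread, scattered, sparse, enriched, restricted (laminar), and
# restricted-but-sparse -- are encoded as density templates relative to a
# base density lambda0.  Expression strength in the quantified output should
# track the number of expressing cells per region, which is what the
# recovery tests check.

PATTERN_CATEGORIES <- c("widespread", "scattered", "sparse",
                        "enriched", "restricted", "restricted_sparse", "none")

# density multipliers encoding the qualitative density ordering of the six
# visual categories (widespread > scattered > sparse); see package vignette
CATEGORY_MULTIPLIERS <- list(
  widespread        = list(target = 1,    division = 1,    sibling = 0),
  scattered         = list(target = 0.3,  division = 0.3,  sibling = 0),
  sparse            = list(target = 0.05, division = 0.05, sibling = 0),
  enriched          = list(target = 1,    division = 0,    sibling = 0.2),
  restricted        = list(target = 1,    division = 0,    sibling = 0),
  restricted_sparse = list(target = 0.1,  division = 0,    sibling = 0))

#' Sample a ground-truth expression profile
#'
#' Expands per-structure (or per-division) pattern-category assignments into
#' a full mid-level density vector lambda_s.  Density templates relative to
#' `base_density` (lambda0):
#' \itemize{
#'   \item restricted: lambda0 in the target structure, 0 elsewhere;
#'   \item restricted_sparse: 0.1 lambda0 in the target, 0 elsewhere;
#'   \item enriched: lambda0 in the target, 0.2 lambda0 in its sibling
#'     structures (same division);
#'   \item widespread / scattered / sparse: 1, 0.3, 0.05 lambda0 across every
#'     mid-level structure of the assigned structure's division (or of the
#'     division itself when a division id/acronym is assigned).
#' }
#' Overlapping assignments accumulate by taking the maximum density.
#'
#' @param ontology a `cre_ontology`.
#' @param assignments named character vector or list: names are structure or
#'   division ids/acronyms, values are pattern categories.
#' @param base_density lambda0, expressing cells per mm^3.
#' @param cell_intensity list with `mean` and `sd` of per-cell signal
#'   amplitude (8-bit units).
#' @param seed integer; kept for interface symmetry (the default templates
#'   are deterministic).
#' @return a `cre_ground_truth`: data frame with `structure_id`, `lambda`,
#'   `category`, plus `cell_intensity` attribute.
#' @export
sample_ground_truth <- function(ontology, assignments, base_density = 5000,
                                cell_intensity = list(mean = 150, sd = 30),
                                seed = 1L) {
  ml <- ontology$midlevel_ids
  div_map <- division_of(ontology)          # midlevel id -> division id
  nodes <- ontology$nodes
  lambda <- stats::setNames(numeric(length(ml)), ml)
  category <- stats::setNames(rep("none", length(ml)), ml)

  resolve_id <- function(key) {
    if (key %in% as.character(nodes$id)) return(as.integer(key))
    hit <- nodes$id[match(key, nodes$acronym)]
    if (is.na(hit)) cq_stop(sprintf("unknown structure '%s'", key),
                            "invalid_assignment")
    hit
  }

  for (key in names(assignments)) {
    cat_k <- as.character(assignments[[key]])
    if (!cat_k %in% setdiff(PATTERN_CATEGORIES, "none"))
      cq_stop(sprintf("unknown category '%s'", cat_k), "invalid_assignment")
    id <- resolve_id(key)
    mult <- CATEGORY_MULTIPLIERS[[cat_k]]
    if (id %in% ontology$division_ids) {
      members <- ml[div_map == id]
      targets <- if (mult$division > 0) members else members[1]
      upd <- stats::setNames(rep(base_density * max(mult$target, mult$division),
                                 length(targets)), targets)
    } else {
      cq_assert(id %in% ml, sprintf("structure %d is not mid-level", id),
                "invalid_assignment")
      upd <- stats::setNames(base_density * mult$target, id)
      sibs <- setdiff(ml[div_map == div_map[as.character(id)]], id)
      if (mult$division > 0)
        upd <- c(upd, stats::setNames(rep(base_density * mult$division,
                                          length(sibs)), sibs))
      if (mult$sibling > 0)
        upd <- c(upd, stats::setNames(rep(base_density * mult$sibling,
                                          length(sibs)), sibs))
    }
    for (s in names(upd)) {
      if (upd[[s]] > lambda[[s]]) {
        lambda[[s]] <- upd[[s]]
        category[[s]] <- cat_k
      }
    }
  }

  gt <- data.frame(structure_id = as.integer(names(lambda)),
                   lambda = unname(lambda),
                   category = unname(category),
                   stringsAsFactors = FALSE)
  structure(gt, cell_intensity = cell_intensity, class = c("cre_ground_truth",
                                                           "data.frame"))
}

gt_support <- function(gt) gt$structure_id[gt$lambda > 0]

#' Derive a gene / Cre-line ground-truth pair under a faithfulness category
#'
#' Models the three classes of agreement between a Cre line's recombination
#' pattern and its endogenous gene: (1) faithful recapitulation everywhere,
#' (2) faithful plus ectopic expression in additional structures, (3)
#' faithful in only a strict subset of the gene-positive structures.
#'
#' @param gt_gene `cre_ground_truth` for the endogenous gene.
#' @param faithfulness 1, 2 or 3.
#' @param frac for category 2, the fraction of currently zero-density
#'   structures gaining ectopic expression; for category 3, the fraction of
#'   gene-positive structures dropped.  At least one structure always changes.
#' @param seed integer seed (structure sampling).
#' @return list with `gene` and `cre` ground truths.
#' @export
make_line_pair <- function(gt_gene, faithfulness, frac = 0.5, seed = 1L) {
  cq_assert(faithfulness %in% 1:3, "faithfulness must be 1, 2 or 3",
            "invalid_assignment")
  gt_cre <- gt_gene
  if (faithfulness == 2) {
    zero <- gt_gene$structure_id[gt_gene$lambda == 0]
    if (length(zero) == 0)
      cq_stop("no zero-density structure available for ectopic expression",
              "infeasible")
    base <- max(gt_gene$lambda)
    extra <- with_seed(seed, {
      k <- max(1L, round(frac * length(zero)))
      if (length(zero) == 1) zero else sample(zero, k)
    })
    i <- match(extra, gt_cre$structure_id)
    gt_cre$lambda[i] <- base
    gt_cre$category[i] <- "restricted"
  } else if (faithfulness == 3) {
    pos <- gt_support(gt_gene)
    cq_assert(length(pos) >= 2,
              "need >= 2 expressing structures to drop a strict subset",
              "infeasible")
    drop <- with_seed(seed, {
      k <- min(length(pos) - 1L, max(1L, round(frac * length(pos))))
      sample(pos, k)
    })
    i <- match(drop, gt_cre$structure_id)
    gt_cre$lambda[i] <- 0
    gt_cre$category[i] <- "none"
  }
  list(gene = gt_gene, cre = gt_cre)
}

#' Place expressing cells by a Poisson point process
#'
#' Realises the ground truth: the number of cells in structure s is
#' Poisson(lambda_s * V_s) with V_s the structure's annotated volume, cell
#' positions are uniform within the structure's voxels, and amplitudes are
#' Gaussian around the ground truth's `cell_intensity` (truncated to
#' `[0, 255]`).
#'
#' @param gt a `cre_ground_truth`.
#' @param annotation a `cre_annotation`.
#' @param partition leaf -> mid-level map.
#' @param seed integer seed.
#' @return a `cre_cells` data frame: `x_um`, `y_um`, `z_um`, `amplitude`,
#'   `structure_id`.
#' @export
place_cells <- function(gt, annotation, partition, seed = 1L) {
  ci <- attr(gt, "cell_intensity") %||% list(mean = 150, sd = 30)
  vols <- structure_volumes(annotation, partition)
  v <- annotation$voxel_size_um
  # voxel index lists per mid-level structure
  lab_flat <- as.vector(annotation$labels)
  ml_flat <- rep(NA_integer_, length(lab_flat))
  nz <- lab_flat != 0L
  ml_flat[nz] <- partition[as.character(lab_flat[nz])]

  out <- with_seed(seed, {
    parts <- lapply(seq_len(nrow(gt)), function(i) {
      s <- gt$structure_id[i]
      lam <- gt$lambda[i]
      if (lam <= 0) return(NULL)
      vol <- vols[[as.character(s)]]
      n <- stats::rpois(1, lam * vol)
      if (n == 0) return(NULL)
      vox <- which(ml_flat == s)
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      idx <- arrayInd(pick, annotation$dims)
      data.frame(
        x_um = (idx[, 1] - 1 + stats::runif(n)) * v,
        y_um = (idx[, 2] - 1 + stats::runif(n)) * v,
        z_um = (idx[, 3] - 1 + stats::runif(n)) * v,
        amplitude = clip01(stats::rnorm(n, ci$mean, ci$sd), 0, 255),
        structure_id = rep(s, n))
    })
    do.call(rbind, parts)
  })
  if (is.null(out))
    out <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      amplitude = numeric(0), structure_id = integer(0))
  class(out) <- c("cre_cells", "data.frame")
  out
}
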