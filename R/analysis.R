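# Downstream statistics: profile correlations, percentile bins, enrichment.
#
# Expression-energy vectors from different datasets (endogenous gene vs.
# Cre reporter vs. Cre itself, or biological replicates) are compared by
# Spearman rank correlation over the mid-level structures present in both,
# after matching for plane of sectioning.  With 1-6 replicates per dataset,
# per-line correlations average the pairwise coefficients of all
# plane-matched replicate pairs (not the correlation of averaged vectors).

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get their mean rank).
#' Positions missing (NA) in either vector are dropped pairwise first.
#'
#' @param x,y numeric vectors of equal length.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  cq_assert(length(x) == length(y), "vectors must have equal length",
            "undefined_correlation")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  cq_assert(length(x) >= 3, "need at least 3 complete pairs",
            "undefined_correlation")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cq_assert(stats::var(rx) > 0 && stats::var(ry) > 0,
            "zero rank variance: correlation undefined",
            "undefined_correlation")
  stats::cor(rx, ry, method = "pearson")
}

ev_meta <- function(ev, what) attr(ev, what, exact = TRUE)

# energies of the structures present (non-missing) in both vectors
paired_energies <- function(a, b) {
  m <- merge(a[, c("structure_id", "energy")], b[, c("structure_id", "energy")],
             by = "structure_id", suffixes = c("_a", "_b"))
  m[!is.na(m$energy_a) & !is.na(m$energy_b), , drop = FALSE]
}

#' Replicate-averaged correlation between two datasets of one line
#'
#' Forms all cross pairs of replicates (one energy vector from each side)
#' that share the plane of sectioning (sagittal with sagittal, coronal with
#' coronal), computes Spearman rho per pair over the structures present in
#' both, and averages.
#'
#' @param evs_a,evs_b lists of `cre_energy` replicates for the two datasets.
#' @param comparison label, e.g. "gene_vs_reporter", "gene_vs_cre",
#'   "replicate".
#' @param line_id line identifier carried into the result.
#' @return a `cre_correlation` list: `line_id`, `comparison`, `pair_rhos`,
#'   `mean_rho`, `mean_rho_sq` (mean of rho^2), `n_pairs`, `percentile_bin`
#'   ("unbinned" until [percentile_bins()] is applied across lines).
#' @export
line_correlation <- function(evs_a, evs_b, comparison = "gene_vs_reporter",
                             line_id = NULL) {
  cq_assert(length(evs_a) >= 1 && length(evs_b) >= 1,
            "need at least one replicate on each side", "incomparable_datasets")
  rhos <- numeric(0)
  for (a in evs_a) for (b in evs_b) {
    if (!identical(ev_meta(a, "plane"), ev_meta(b, "plane"))) next
    p <- paired_energies(a, b)
    rhos <- c(rhos, spearman_rho(p$energy_a, p$energy_b))
  }
  if (length(rhos) == 0)
    cq_stop("no plane-matched replicate pair between the two datasets",
            "incomparable_datasets")
  structure(list(line_id = line_id %||% ev_meta(evs_a[[1]], "line_id"),
                 comparison = comparison, pair_rhos = rhos,
                 mean_rho = mean(rhos), mean_rho_sq = mean(rhos^2),
                 n_pairs = length(rhos), percentile_bin = "unbinned"),
            class = "cre_correlation")
}

#' Average correlation between biological replicates
#'
#' For each line with at least two plane-matched replicates, averages the
#' Spearman rho of all within-line plane-matched replicate pairs; the
#' baseline is the unweighted mean over lines (each line counts once,
#' whatever its replicate count).
#'
#' @param lines named list; each element is a list of `cre_energy`
#'   replicates of one line.
#' @return scalar baseline correlation.
#' @export
replicate_baseline <- function(lines) {
  per_line <- c()
  for (evs in lines) {
    if (length(evs) < 2) next
    rhos <- numeric(0)
    for (i in seq_along(evs)) for (j in seq_along(evs)) {
      if (j <= i) next
      if (!identical(ev_meta(evs[[i]], "plane"), ev_meta(evs[[j]], "plane"))) next
      p <- paired_energies(evs[[i]], evs[[j]])
      rhos <- c(rhos, spearman_rho(p$energy_a, p$energy_b))
    }
    if (length(rhos) > 0) per_line <- c(per_line, mean(rhos))
  }
  cq_assert(length(per_line) > 0,
            "no line with >= 2 plane-matched replicates", "incomparable_datasets")
  mean(per_line)
}

#' Quartile percentile bins for per-line correlations
#'
#' Splits lines into high (at or above the 75th percentile), mid (50-75th),
#' low (25-50th) and very low (below the 25th percentile) groups, the
#' thresholds computed with the inclusive linear-interpolation quantile
#' definition ([stats::quantile()] type 7).  Values equal to a threshold are
#' assigned upward (value = Q3 is "high", = median is "mid", = Q1 is "low").
#'
#' @param values numeric vector of per-line mean correlations (n >= 4).
#' @return character vector of bins; all "unbinned" when n < 4.
#' @export
percentile_bins <- function(values) {
  n <- length(values)
  if (n < 4) return(rep("unbinned", n))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  ifelse(values >= q[3], "high",
         ifelse(values >= q[2], "mid",
                ifelse(values >= q[1], "low", "very_low")))
}

#' Fold-change enrichment table
#'
#' For each line and structure, the fold change F = E_s / W of the
#' structure's expression energy over the line's whole-brain average.  No
#' expression floor is applied before the ratio, so very low absolute
#' energies can still produce large fold changes; interpret alongside the
#' energies themselves.  F is missing when E_s is missing or W = 0.
#'
#' @param evs list of `cre_energy`, one per line.
#' @return a `cre_enrichment` data frame: `line_id`, `structure_id`,
#'   `energy`, `whole_brain_energy`, `fold_change`.
#' @export
fold_change_table <- function(evs) {
  rows <- lapply(evs, function(ev) {
    w <- ev_meta(ev, "whole_brain_energy")
    data.frame(line_id = ev_meta(ev, "line_id"),
               structure_id = ev$structure_id,
               energy = ev$energy,
               whole_brain_energy = w,
               fold_change = if (is.na(w) || w == 0) NA_real_ else
                 ev$energy / w)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cre_enrichment", "data.frame")
  out
}

#' Rank lines by enrichment in one structure
#'
#' @param table a `cre_enrichment`.
#' @param structure_id structure to rank within.
#' @return data frame of the structure's rows ordered by descending fold
#'   change; missing fold changes last; ties broken by `line_id` lexical
#'   order.
#' @export
rank_lines_for_structure <- function(table, structure_id) {
  rows <- table[table$structure_id == structure_id, , drop = FALSE]
  cq_assert(nrow(rows) > 0, sprintf("structure %s not in table", structure_id),
            "unknown_structure")
  o <- order(is.na(rows$fold_change), -ifelse(is.na(rows$fold_change), -Inf,
                                              rows$fold_change), rows$line_id)
  rows[o, , drop = FALSE]
}

#' Two-tailed t-test comparison of two groups
#'
#' Paired comparisons use a one-sample t-test on the differences; unpaired
#' comparisons use Welch's unequal-variance t-test.  Degenerate data with
#' zero variance and equal means return t = 0, p = 1 rather than an error.
#'
#' @param values numeric vector.
#' @param labels group labels (exactly two distinct values); for paired
#'   comparisons the i-th value of each group is a pair.
#' @param paired logical.
#' @return list with `t`, `df`, `p`.
#' @export
group_compare <- function(values, labels, paired = FALSE) {
  labels <- as.character(labels)
  gl <- unique(labels)
  cq_assert(length(gl) == 2, "need exactly two groups", "invalid_spec")
  x <- values[labels == gl[1]]
  y <- values[labels == gl[2]]
  if (paired) {
    cq_assert(length(x) == length(y), "paired groups must have equal size",
              "invalid_spec")
    cq_assert(length(x) >= 2, "need >= 2 pairs", "invalid_spec")
    d <- x - y
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(list(t = t, df = length(d) - 1,
                  p = if (mean(d) == 0) 1 else 0))
    }
    ht <- stats::t.test(d, mu = 0, alternative = "two.sided")
  } else {
    cq_assert(length(x) >= 2 && length(y) >= 2, "need >= 2 per group",
              "invalid_spec")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      eq <- mean(x) == mean(y)
      return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = if (eq) 1 else 0))
    }
    ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
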