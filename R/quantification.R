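# Gridding and structure unionization: from expression masks to
# per-structure "expression energy".
#
# Each masked section is divided into 200 um grid cells (half-open tiling in
# pixel space).  Grid cells are assigned to atlas structures by mapping the
# cell centre through the section's exact transform into the annotation
# volume and taking the mid-level structure of that voxel.  The expression
# energy of structure s is then
#
#   E_s = sum over grids assigned to s of sum_detected_intensity
#         / sum over the same grids of n_total
#
# i.e. the sum of expressing-pixel intensity divided by the number of all
# (in-tissue) pixels for all grids associated with the structure, pooled
# across all sections of a series; the whole-brain energy uses the same
# ratio pooled over every assigned grid.

#' Grid a masked section
#'
#' Tiles the image with `grid_size_um` cells (half-open intervals in pixel
#' space; boundary cells may be partial) and accumulates per-cell detected
#' intensity, detected count, and total in-tissue pixel count.
#'
#' @param section a `cre_section`.
#' @param mask its `cre_mask`.
#' @param grid_size_um grid edge; must be a positive multiple of the pixel
#'   size (no resampling).
#' @return a `cre_grid`: data frame with `gi`, `gj` (0-based grid indices:
#'   row block, column block), `center_col_px`, `center_row_px`,
#'   `sum_detected_intensity`, `n_detected`, `n_total`, `structure_id`
#'   (NA until assigned); attributes `grid_size_um`, `transform`.
#' @export
grid_section <- function(section, mask, grid_size_um = 200) {
  ps <- section$pixel_size_um
  gpx <- grid_size_um / ps
  cq_assert(grid_size_um > 0 && abs(gpx - round(gpx)) < 1e-9,
            "grid size must be a positive multiple of the pixel size",
            "invalid_spec")
  gpx <- round(gpx)
  cq_assert(all(dim(mask$detected) == dim(section$pixels)),
            "mask and image are not co-registered", "registration")
  nr <- nrow(section$pixels); nc <- ncol(section$pixels)
  gi <- (seq_len(nr) - 1L) %/% gpx      # per-pixel row block
  gj <- (seq_len(nc) - 1L) %/% gpx
  idx <- outer(gi, gj * (max(gi) + 1L), "+")  # unique block id per pixel

  tis <- section$in_tissue
  det <- mask$detected
  inten <- section$pixels * det
  f <- factor(idx[tis])
  if (length(f) == 0L) {
    cells <- data.frame(gi = integer(0), gj = integer(0),
                        center_col_px = numeric(0), center_row_px = numeric(0),
                        sum_detected_intensity = numeric(0),
                        n_detected = integer(0), n_total = integer(0),
                        structure_id = integer(0))
  } else {
    n_total <- as.integer(tapply(rep(1L, sum(tis)), f, sum))
    n_det <- as.integer(tapply(det[tis], f, sum))
    s_det <- as.numeric(tapply(inten[tis], f, sum))
    id <- as.integer(levels(f))
    bi <- id %% (max(gi) + 1L)
    bj <- id %/% (max(gi) + 1L)
    cells <- data.frame(gi = bi, gj = bj,
                        center_col_px = bj * gpx + gpx / 2,
                        center_row_px = bi * gpx + gpx / 2,
                        sum_detected_intensity = s_det,
                        n_detected = n_det, n_total = n_total,
                        structure_id = NA_integer_)
  }
  structure(cells, grid_size_um = grid_size_um, transform = section$transform,
            class = c("cre_grid", "data.frame"))
}

#' Assign grid cells to atlas structures
#'
#' Maps each grid-cell centre through the section transform into the
#' annotation volume; the cell's structure is the mid-level structure of
#' that voxel (NA when the centre falls outside the brain or the volume).
#'
#' @param grid a `cre_grid`.
#' @param annotation a `cre_annotation`.
#' @param partition leaf -> mid-level map from [midlevel_partition()].
#' @return the grid with `structure_id` filled.
#' @export
assign_grid_structures <- function(grid, annotation, partition) {
  if (nrow(grid) == 0L) return(grid)
  tr <- attr(grid, "transform")
  xyz <- pixel_to_atlas_um(tr, grid$center_col_px, grid$center_row_px)
  ijk <- matrix(um_to_voxel(xyz, annotation$voxel_size_um), ncol = 3)
  labs <- labels_at(annotation, ijk)
  sid <- rep(NA_integer_, length(labs))
  nz <- labs != 0L
  sid[nz] <- partition[as.character(labs[nz])]
  grid$structure_id <- sid
  grid
}

#' Per-structure expression energy of a series
#'
#' Pools assigned grid cells across every section of a series and computes
#' the expression-energy statistic per mid-level structure, plus the
#' whole-brain energy (same ratio over all assigned grids).  Structures
#' with no assigned grid are reported as missing (NA), not zero: a
#' sectioning plane can simply miss a small structure, and conflating
#' "unsampled" with "not expressed" would bias rank correlations.
#'
#' @param grids list of assigned `cre_grid`s (one per section).
#' @param partition leaf -> mid-level map; defines the structure universe.
#' @param line_id,probe,plane metadata carried into the result.
#' @return a `cre_energy`: data frame with `structure_id`,
#'   `sum_detected_intensity`, `n_total`, `energy`; attributes `line_id`,
#'   `probe`, `plane`, `whole_brain_energy`.
#' @export
expression_energy <- function(grids, partition, line_id = "line",
                              probe = "tdTomato", plane = "coronal") {
  all_cells <- do.call(rbind, lapply(grids, as.data.frame))
  assigned <- all_cells[!is.na(all_cells$structure_id), , drop = FALSE]
  cq_assert(nrow(assigned) > 0, "no grid cell was assigned to any structure",
            "empty_series")
  ml <- sort(unique(partition))
  sums <- rowsum(assigned[, c("sum_detected_intensity", "n_total")],
                 assigned$structure_id)
  i <- match(ml, as.integer(rownames(sums)))
  sdet <- ifelse(is.na(i), 0, sums$sum_detected_intensity[i])
  ntot <- ifelse(is.na(i), 0, sums$n_total[i])
  energy <- ifelse(ntot > 0, sdet / ntot, NA_real_)
  sdet[is.na(i)] <- NA_real_
  ntot[is.na(i)] <- NA_real_
  ev <- data.frame(structure_id = ml, sum_detected_intensity = sdet,
                   n_total = ntot, energy = energy)
  structure(ev, line_id = line_id, probe = probe, plane = plane,
            whole_brain_energy = sum(assigned$sum_detected_intensity) /
              sum(assigned$n_total),
            class = c("cre_energy", "data.frame"))
}

#' Coarse 12-division expression summary
#'
#' Division energy is the pixel-weighted pool of its member structures:
#' total detected intensity over total pixel count, consistent with the
#' per-structure formula (not a mean of member energies).
#'
#' @param ev a `cre_energy`.
#' @param ontology the `cre_ontology` defining division membership.
#' @return data frame with `division_id`, `acronym`, `energy`.
#' @export
division_summary <- function(ev, ontology) {
  div <- division_of(ontology)   # midlevel id -> division id
  d <- div[as.character(ev$structure_id)]
  ok <- !is.na(ev$energy)   # missing (unsampled) structures are excluded
  agg <- rowsum(data.frame(s = ifelse(ok, ev$sum_detected_intensity, 0),
                           n = ifelse(ok, ev$n_total, 0)),
                d)
  ids <- ontology$division_ids
  i <- match(ids, as.integer(rownames(agg)))
  energy <- ifelse(!is.na(i) & agg$n[i] > 0, agg$s[i] / agg$n[i], NA_real_)
  data.frame(division_id = ids,
             acronym = ontology$nodes$acronym[match(ids, ontology$nodes$id)],
             energy = energy)
}

#' Quantify a whole image series
#'
#' Convenience wrapper: segment every section, grid, assign and pool into an
#' energy vector.
#'
#' @param series a `cre_series`.
#' @param annotation,partition atlas objects.
#' @param k,s_min segmentation parameters (see [detect_expression()]).
#' @param grid_size_um grid edge passed to [grid_section()].
#' @return a `cre_energy`.
#' @export
quantify_series <- function(series, annotation, partition, k = 3, s_min = 2,
                            grid_size_um = 200) {
  grids <- lapply(series$sections, function(sec) {
    if (!any(sec$in_tissue)) return(NULL)   # blank slide (slab off-tissue)
    mask <- detect_expression(sec, k = k, s_min = s_min)
    assign_grid_structures(grid_section(sec, mask, grid_size_um),
                           annotation, partition)
  })
  grids <- Filter(Negate(is.null), grids)
  cq_assert(length(grids) > 0, "series has no in-tissue section", "empty_series")
  expression_energy(grids, partition, line_id = series$line_id,
                    probe = series$probe, plane = series$plane)
}
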