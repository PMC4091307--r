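# Forward model of serial ISH section imaging.
#
# A section is a 2D signal-intensity image (higher = more ISH product; real
# colorimetric scans are dark-on-light and are inverted by loaders upstream
# of this model).  Cells whose sectioning-axis coordinate falls inside the
# 25 um slab are rendered as Gaussian blobs on a noisy tissue background;
# out-of-tissue pixels are 0.  Every section records the exact pixel ->
# atlas-micrometre affine transform used later to assign grids to structures.
#
# Plane conventions (one hemisphere, no midline mirroring):
#   coronal  - slab at fixed z; image columns = x (medio-lateral),
#              rows = y (dorso-ventral)
#   sagittal - slab at fixed x; image columns = z (rostro-caudal),
#              rows = y (dorso-ventral)

plane_axes <- function(plane) {
  switch(plane,
         coronal  = list(slab = 3L, col = 1L, row = 2L),
         sagittal = list(slab = 1L, col = 3L, row = 2L),
         cq_stop(sprintf("unknown plane '%s'", plane), "invalid_spec"))
}

# affine pixel -> atlas map: atlas_um = A %*% c(col, row) + b, where
# (col, row) are *continuous* 1-based pixel coordinates (pixel centre at
# integer - 0.5 offsets handled by callers via pixel_center_um)
section_transform <- function(plane, position_um, pixel_size_um) {
  ax <- plane_axes(plane)
  A <- matrix(0, 3, 2)
  A[ax$col, 1] <- pixel_size_um
  A[ax$row, 2] <- pixel_size_um
  b <- numeric(3)
  b[ax$slab] <- position_um
  list(A = A, b = b, plane = plane, position_um = position_um,
       pixel_size_um = pixel_size_um)
}

#' Map pixel coordinates to atlas micrometres
#'
#' @param transform a section transform (`section$transform`).
#' @param col,row continuous pixel coordinates; the centre of pixel
#'   `[r, c]` is `(c - 0.5, r - 0.5)`.
#' @return n x 3 matrix of atlas coordinates (x, y, z in micrometres).
#' @export
pixel_to_atlas_um <- function(transform, col, row) {
  t(transform$A %*% rbind(col, row) + transform$b)
}

#' Map atlas micrometres to in-plane pixel coordinates
#'
#' Inverse of [pixel_to_atlas_um()] for the two in-plane axes.
#'
#' @param transform a section transform.
#' @param xyz_um n x 3 matrix (or length-3 vector) of atlas coordinates.
#' @return n x 2 matrix of continuous (col, row) pixel coordinates.
#' @export
atlas_um_to_pixel <- function(transform, xyz_um) {
  xyz_um <- rbind(xyz_um)
  ax <- plane_axes(transform$plane)
  cbind(col = xyz_um[, ax$col] / transform$pixel_size_um,
        row = xyz_um[, ax$row] / transform$pixel_size_um)
}

# in-tissue pixel mask for a slab: label > 0 at the voxel under each pixel
# centre, sampled at the slab centre
tissue_mask <- function(annotation, plane, position_um, pixel_size_um) {
  ax <- plane_axes(plane)
  v <- annotation$voxel_size_um
  slab_vox <- um_to_voxel(position_um, v)
  cq_assert(slab_vox >= 1 && slab_vox <= annotation$dims[ax$slab],
            "section position outside volume", "bounds")
  ncol_px <- ceiling(annotation$dims[ax$col] * v / pixel_size_um)
  nrow_px <- ceiling(annotation$dims[ax$row] * v / pixel_size_um)
  col_vox <- um_to_voxel((seq_len(ncol_px) - 0.5) * pixel_size_um, v)
  row_vox <- um_to_voxel((seq_len(nrow_px) - 0.5) * pixel_size_um, v)
  col_vox <- pmin(col_vox, annotation$dims[ax$col])
  row_vox <- pmin(row_vox, annotation$dims[ax$row])
  slice <- switch(plane,
                  coronal  = annotation$labels[, , slab_vox],   # x by y
                  sagittal = annotation$labels[slab_vox, , ])   # y by z
  if (plane == "coronal") {
    m <- matrix(slice[cbind(rep(col_vox, each = nrow_px), rep(row_vox, ncol_px))] > 0,
                nrow = nrow_px, ncol = ncol_px)
  } else {
    m <- matrix(slice[cbind(rep(row_vox, ncol_px), rep(col_vox, each = nrow_px))] > 0,
                nrow = nrow_px, ncol = ncol_px)
  }
  m
}

# peak-normalised Gaussian kernel (odd size)
gaussian_kernel <- function(sd_px) {
  r <- max(1L, ceiling(3 * sd_px))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sd_px^2))
  outer(k, k)
}

# 2D convolution by shift-and-add (kernel is small); zero padding
convolve2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) / 2L
  out <- matrix(0, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  nz <- which(kernel != 0, arr.ind = TRUE)
  for (t in seq_len(nrow(nz))) {
    di <- nz[t, 1] - kr - 1L; dj <- nz[t, 2] - kr - 1L
    w <- kernel[nz[t, 1], nz[t, 2]]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * img[si, sj]
  }
  out
}

#' Render one section image
#'
#' Cells whose sectioning-axis coordinate lies in the half-open slab
#' `[position - thickness/2, position + thickness/2)` are deposited at their
#' nearest pixel and spread as a peak-normalised Gaussian blob; the result is
#' added onto an in-tissue background `b0` plus Gaussian texture of standard
#' deviation `sigma`, clipped to `[0, 255]`.  Out-of-tissue pixels are 0.
#'
#' @param cells a `cre_cells` data frame.
#' @param annotation a `cre_annotation`.
#' @param plane "coronal" or "sagittal".
#' @param position_um slab centre along the sectioning axis.
#' @param thickness_um slab thickness (default 25 um).
#' @param pixel_size_um pixel edge (default 10 um).
#' @param noise list with background level `b0` and texture sd `sigma`.
#' @param blob_radius_um blob radius (Gaussian sd is half of it).
#' @param seed integer seed for the background texture.
#' @return a `cre_section`: list with `pixels` (numeric matrix),
#'   `in_tissue` (logical matrix), `plane`, `position_um`, `thickness_um`,
#'   `pixel_size_um`, `transform`.
#' @export
render_section <- function(cells, annotation, plane, position_um,
                           thickness_um = 25, pixel_size_um = 10,
                           noise = list(b0 = 20, sigma = 5),
                           blob_radius_um = 10, seed = 1L) {
  cq_assert(thickness_um > 0, "thickness must be positive", "invalid_spec")
  tis <- tissue_mask(annotation, plane, position_um, pixel_size_um)
  ax <- plane_axes(plane)
  transform <- section_transform(plane, position_um, pixel_size_um)

  img <- with_seed(seed, {
    bg <- matrix(0, nrow(tis), ncol(tis))
    bg[tis] <- noise$b0 + if (noise$sigma > 0)
      stats::rnorm(sum(tis), 0, noise$sigma) else 0

    signal <- matrix(0, nrow(tis), ncol(tis))
    if (nrow(cells) > 0) {
      pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
      axc <- pos[, ax$slab]
      keep <- in_halfopen(axc, position_um - thickness_um / 2,
                          position_um + thickness_um / 2)
      if (any(keep)) {
        px <- atlas_um_to_pixel(transform, pos[keep, , drop = FALSE])
        cc <- pmin(pmax(floor(px[, "col"]) + 1L, 1L), ncol(tis))
        rr <- pmin(pmax(floor(px[, "row"]) + 1L, 1L), nrow(tis))
        amp <- cells$amplitude[keep]
        idx <- (cc - 1) * nrow(tis) + rr
        acc <- rowsum(amp, idx)
        deposit <- matrix(0, nrow(tis), ncol(tis))
        deposit[as.integer(rownames(acc))] <- acc[, 1]
        signal <- convolve2d(deposit, gaussian_kernel((blob_radius_um / 2) /
                                                        pixel_size_um))
      }
    }
    out <- clip01(bg + signal, 0, 255)
    out[!tis] <- 0
    out
  })

  structure(list(pixels = img, in_tissue = tis, plane = plane,
                 position_um = position_um, thickness_um = thickness_um,
                 pixel_size_um = pixel_size_um, transform = transform),
            class = "cre_section")
}

#' Generate a serial section image series
#'
#' Sections every `spacing_um` (default 200 um) at `thickness_um` (default
#' 25 um) across the full extent of the sectioning axis, emulating one
#' series of a multi-series sectioning protocol that uniformly samples the
#' brain.  Positions start at `thickness_um / 2` so the first slab is fully
#' inside the volume; the count is
#' `floor((extent - thickness) / spacing) + 1`.
#'
#' @inheritParams render_section
#' @param spacing_um distance between slab centres; must be >= thickness.
#' @param line_id,probe,replicate_index series metadata (probe is one of
#'   "tdTomato", "cre", "endogenous").
#' @param seed integer; per-section seeds are derived from it.
#' @return a `cre_series`: list of `cre_section`s plus metadata.
#' @export
generate_series <- function(cells, annotation, plane, spacing_um = 200,
                            thickness_um = 25, pixel_size_um = 10,
                            noise = list(b0 = 20, sigma = 5),
                            blob_radius_um = 10,
                            line_id = "line", probe = "tdTomato",
                            replicate_index = 1L, seed = 1L) {
  cq_assert(spacing_um >= thickness_um,
            "section spacing smaller than thickness (overlapping slabs)",
            "overlap")
  ax <- plane_axes(plane)
  extent <- annotation$dims[ax$slab] * annotation$voxel_size_um
  n <- floor((extent - thickness_um) / spacing_um) + 1
  positions <- thickness_um / 2 + spacing_um * (seq_len(n) - 1)
  sections <- lapply(seq_len(n), function(i) {
    render_section(cells, annotation, plane, positions[i], thickness_um,
                   pixel_size_um, noise, blob_radius_um,
                   seed = derive_seed(seed, "section", i))
  })
  structure(list(sections = sections, plane = plane, spacing_um = spacing_um,
                 thickness_um = thickness_um, pixel_size_um = pixel_size_um,
                 positions_um = positions, line_id = line_id, probe = probe,
                 replicate_index = replicate_index, seed = seed),
            class = "cre_series")
}

#' @export
print.cre_series <- function(x, ...) {
  cat(sprintf("<cre_series> %s/%s rep %d: %d %s sections every %g um (%g um thick)\n",
              x$line_id, x$probe, x$replicate_index, length(x$sections),
              x$plane, x$spacing_um, x$thickness_um))
  invisible(x)
}
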