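# Gridding, structure assignment and the expression-energy statistic.

# annotation with two leaf slabs splitting x, for hand-checkable assignment:
# leaves 3 (x voxels 1..6) and 4 (x voxels 7..12), voxel 50 um, single z
two_structure_annotation <- function() {
  nodes <- data.frame(id = 1:4,
                      acronym = c("root", "D", "A", "B"),
                      name = c("root", "division", "left", "right"),
                      parent_id = c(NA_integer_, 1L, 2L, 2L),
                      is_midlevel = c(FALSE, FALSE, TRUE, TRUE),
                      is_division = c(FALSE, TRUE, FALSE, FALSE))
  ont <- structure(list(nodes = nodes, division_ids = 2L, midlevel_ids = 3:4),
                   class = "cre_ontology")
  labels <- array(0L, dim = c(12, 6, 1))
  labels[1:6, , 1] <- 3L
  labels[7:12, , 1] <- 4L
  ann <- structure(list(voxel_size_um = 50, dims = c(12L, 6L, 1L),
                        labels = labels), class = "cre_annotation")
  list(ontology = ont, annotation = ann,
       partition = midlevel_partition(ont, ann))
}

test_that("grid cells tile the image and match a per-pixel loop oracle", {
  # 20 x 20 pixels of 10 um = exactly one 200 um grid cell
  px <- matrix(seq_len(400), 20, 20)
  sec <- manual_section(px)
  det <- px > 300
  g1 <- grid_section(sec, manual_mask(det), 200)
  expect_equal(nrow(g1), 1)
  ms <- mask_summary(manual_mask(det), sec)
  expect_equal(g1$n_total, ms$n_total)
  expect_equal(g1$n_detected, ms$n_detected)
  expect_equal(g1$sum_detected_intensity, ms$sum_detected_intensity)

  # 60 x 60 px at 10 um -> 3 x 3 grids of 20 x 20 px each
  set.seed(5)
  px <- matrix(sample(0:255, 3600, replace = TRUE), 60, 60)
  tis <- matrix(runif(3600) < 0.9, 60, 60)
  det <- tis & px > 128
  g <- grid_section(manual_section(px, tis), manual_mask(det), 200)
  expect_equal(nrow(g), 9)
  for (r in seq_len(nrow(g))) {
    rows <- (g$gi[r] * 20 + 1):(g$gi[r] * 20 + 20)
    cols <- (g$gj[r] * 20 + 1):(g$gj[r] * 20 + 20)
    nt <- 0; nd <- 0; sdet <- 0
    for (i in rows) for (j in cols) {
      if (tis[i, j]) nt <- nt + 1
      if (det[i, j]) { nd <- nd + 1; sdet <- sdet + px[i, j] }
    }
    expect_equal(g$n_total[r], nt)
    expect_equal(g$n_detected[r], nd)
    expect_equal(g$sum_detected_intensity[r], sdet)
  }
  # every in-tissue pixel lands in exactly one cell
  expect_equal(sum(g$n_total), sum(tis))

  # boundary cells may be partial: 30 px tall image -> bottom cells 10 px
  gpart <- grid_section(manual_section(matrix(0, 30, 40)),
                        manual_mask(matrix(FALSE, 30, 40)), 200)
  expect_setequal(gpart$n_total, c(400, 200))

  expect_error(grid_section(manual_section(px, tis), manual_mask(det), 155),
               class = "crequant_invalid_spec_error")
})

test_that("grid centres are assigned by centre-point atlas lookup", {
  fx <- two_structure_annotation()
  # image covers 120 x 60 px at 10 um; grid 200 um -> 20 px
  px <- matrix(10, 30, 60)
  sec <- manual_section(px)
  g <- grid_section(sec, manual_mask(matrix(FALSE, 30, 60)), 200)
  ga <- assign_grid_structures(g, fx$annotation, fx$partition)
  # oracle: centre pixel -> um -> voxel -> leaf -> midlevel
  for (r in seq_len(nrow(ga))) {
    um <- pixel_to_atlas_um(sec$transform, ga$center_col_px[r],
                            ga$center_row_px[r])
    ijk <- crequant:::um_to_voxel(as.vector(um), 50)
    want <- if (any(ijk < 1 | ijk > fx$annotation$dims)) NA_integer_ else
      voxel_structure(fx$annotation, fx$partition, ijk)
    expect_equal(ga$structure_id[r], want)
  }
  # first column of grids is deep in the left structure; the straddling and
  # right grids take their centre's structure; bottom row centres fall past
  # the 300 um tissue extent and stay unassigned
  expect_equal(unique(ga$structure_id[ga$gj == 0 & ga$gi == 0]), 3L)
  expect_equal(unique(ga$structure_id[ga$gj >= 1 & ga$gi == 0]), 4L)
  expect_true(all(is.na(ga$structure_id[ga$gi == 1])))
})

test_that("grid centres over background or outside the volume get no structure", {
  fx <- two_structure_annotation()
  ann0 <- fx$annotation
  ann0$labels[1:6, , 1] <- 0L   # left half now outside the brain
  sec <- manual_section(matrix(10, 30, 60))
  g <- grid_section(sec, manual_mask(matrix(FALSE, 30, 60)), 200)
  ga <- assign_grid_structures(g, ann0, fx$partition)
  expect_true(all(is.na(ga$structure_id[ga$gj == 0])))
})

test_that("expression energy implements the pooled sum/count ratio", {
  fx <- two_structure_annotation()
  # every tissue pixel detected at intensity I -> energy I everywhere covered
  I <- 37
  px <- matrix(I, 30, 60)
  sec <- manual_section(px)
  det <- matrix(TRUE, 30, 60)
  ga <- assign_grid_structures(grid_section(sec, manual_mask(det), 200),
                               fx$annotation, fx$partition)
  ev <- expression_energy(list(ga), fx$partition)
  expect_equal(ev$energy, c(I, I))
  expect_equal(attr(ev, "whole_brain_energy"), I)

  # hand fixture: two grids in one structure -> (30 + 10) / (100 + 100)
  g <- data.frame(gi = 0:1, gj = 0, center_col_px = 10, center_row_px = c(10, 30),
                  sum_detected_intensity = c(30, 10), n_detected = c(3, 1),
                  n_total = c(100, 100), structure_id = c(3L, 3L))
  class(g) <- c("cre_grid", "data.frame")
  ev2 <- expression_energy(list(g), c("3" = 3L))
  expect_equal(ev2$energy, 0.2)

  # empty masks -> zero energy everywhere covered
  ga0 <- assign_grid_structures(
    grid_section(sec, manual_mask(matrix(FALSE, 30, 60)), 200),
    fx$annotation, fx$partition)
  ev0 <- expression_energy(list(ga0), fx$partition)
  expect_equal(ev0$energy, c(0, 0))

  # a structure with no assigned grids is missing, not zero
  gb <- g; gb$structure_id <- c(3L, NA)
  ev3 <- expression_energy(list(gb), c("3" = 3L, "4" = 4L))
  expect_true(is.na(ev3$energy[ev3$structure_id == 4L]))

  # all grids unassigned -> empty-series error
  gna <- g; gna$structure_id <- NA_integer_
  expect_error(expression_energy(list(gna), fx$partition),
               class = "crequant_empty_series_error")
})

test_that("detected intensity and pixel counts are conserved through pooling", {
  atlas <- tiny_atlas()
  part <- midlevel_partition(atlas$ontology, atlas$annotation)
  gt <- sample_ground_truth(atlas$ontology,
                            list(Iso = "scattered", HPF1 = "restricted"))
  cells <- place_cells(gt, atlas$annotation, part, seed = 31)
  ser <- generate_series(cells, atlas$annotation, "coronal", seed = 32)
  grids <- lapply(ser$sections, function(sec) {
    assign_grid_structures(grid_section(sec, detect_expression(sec), 200),
                           atlas$annotation, part)
  })
  ev <- expression_energy(grids, part)
  all_g <- do.call(rbind, lapply(grids, as.data.frame))
  assigned <- all_g[!is.na(all_g$structure_id), ]
  expect_lt(abs(sum(ev$sum_detected_intensity, na.rm = TRUE) -
                  sum(assigned$sum_detected_intensity)), 1e-9)
  expect_lt(abs(sum(ev$n_total, na.rm = TRUE) - sum(assigned$n_total)), 1e-9)
  # whole-brain energy is the n_total-weighted mean of structure energies
  ok <- !is.na(ev$energy)
  wmean <- sum(ev$energy[ok] * ev$n_total[ok]) / sum(ev$n_total[ok])
  expect_lt(abs(attr(ev, "whole_brain_energy") - wmean), 1e-9)
})

test_that("halving the grid size leaves energies unchanged on aligned fixtures", {
  # structure boundary at x = 400 um and tissue extent 400 x 600 um, both
  # multiples of 200 and of 100, so neither grid straddles a boundary
  fx <- two_structure_annotation()
  ann <- fx$annotation
  ann$dims <- c(12L, 8L, 1L)
  ann$labels <- array(0L, dim = ann$dims)
  ann$labels[1:8, , 1] <- 3L
  ann$labels[9:12, , 1] <- 4L
  fx$annotation <- ann
  set.seed(6)
  px <- matrix(sample(0:255, 2400, replace = TRUE), 40, 60)
  sec <- manual_section(px)
  det <- px > 100
  for (gs in c(200, 100)) {
    g <- assign_grid_structures(grid_section(sec, manual_mask(det), gs),
                                fx$annotation, fx$partition)
    ev <- expression_energy(list(g), fx$partition)
    if (gs == 200) first <- ev$energy else expect_equal(ev$energy, first)
  }
})

test_that("division summaries pool member structures pixel-weighted", {
  fx <- two_structure_annotation()
  # both structures under one division: equal totals, energies 0.1 and 0.3
  ev <- manual_energy(3:4, c(0.1, 0.3))
  ds <- division_summary(ev, fx$ontology)
  expect_equal(ds$energy, 0.2)

  # unequal totals: pooled ratio, not the mean of energies
  ev2 <- manual_energy(3:4, c(0.1, 0.3), n_total = c(300, 100))
  ds2 <- division_summary(ev2, fx$ontology)
  expect_equal(ds2$energy, (0.1 * 300 + 0.3 * 100) / 400)

  # single-structure division reproduces the structure energy
  atlas <- tiny_atlas()
  ml <- atlas$ontology$midlevel_ids
  ev3 <- manual_energy(ml, c(0.5, NA, NA, NA, NA, NA))
  ds3 <- division_summary(ev3, atlas$ontology)
  expect_equal(ds3$energy[ds3$acronym == "Iso"], 0.5)
})
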