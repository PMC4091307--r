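# File formats: ontology CSV/JSON, annotation volume TIFF + JSON sidecar,
# section images (8-bit grayscale PNG/TIFF + per-series JSON sidecar), and
# the CSV tables (energy, correlation report, enrichment, ground truth).
# Every writer has a reader and the pair round-trips exactly, which the
# pipeline's determinism checks rely on.

#' Write / read an ontology as flat CSV
#'
#' Columns: id, acronym, name, parent_id, is_midlevel, is_division -- the
#' toy analog of a reference-atlas ontology key.
#'
#' @param ontology a `cre_ontology`.
#' @param path CSV file path.
#' @return `read_ontology_csv()` returns a validated `cre_ontology`.
#' @export
write_ontology_csv <- function(ontology, path) {
  utils::write.csv(ontology$nodes, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ontology_csv
#' @export
read_ontology_csv <- function(path) {
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE)
  nodes$parent_id <- as.integer(nodes$parent_id)
  ont <- structure(list(nodes = nodes,
                        division_ids = nodes$id[nodes$is_division],
                        midlevel_ids = nodes$id[nodes$is_midlevel]),
                   class = "cre_ontology")
  validate_ontology(ont)
}

#' Write / read an ontology as nested JSON
#'
#' @inheritParams write_ontology_csv
#' @export
write_ontology_json <- function(ontology, path) {
  nodes <- ontology$nodes
  build <- function(id) {
    i <- match(id, nodes$id)
    kids <- nodes$id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    list(id = nodes$id[i], acronym = nodes$acronym[i], name = nodes$name[i],
         is_midlevel = nodes$is_midlevel[i], is_division = nodes$is_division[i],
         children = lapply(kids, build))
  }
  root <- nodes$id[is.na(nodes$parent_id)]
  jsonlite::write_json(build(root), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ontology_json
#' @export
read_ontology_json <- function(path) {
  tree <- jsonlite::read_json(path)
  rows <- list()
  walk <- function(node, parent_id) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = node$id, acronym = node$acronym, name = node$name,
      parent_id = if (is.null(parent_id)) NA_integer_ else parent_id,
      is_division = isTRUE(node$is_division),
      is_midlevel = isTRUE(node$is_midlevel))
    for (k in node$children) walk(k, node$id)
  }
  walk(tree, NULL)
  nodes <- do.call(rbind, rows)
  nodes <- nodes[, c("id", "acronym", "name", "parent_id", "is_midlevel",
                     "is_division")]
  ont <- structure(list(nodes = nodes,
                        division_ids = nodes$id[nodes$is_division],
                        midlevel_ids = nodes$id[nodes$is_midlevel]),
                   class = "cre_ontology")
  validate_ontology(ont)
}

#' Write / read an annotation volume (multi-page TIFF + JSON sidecar)
#'
#' One 16-bit grayscale TIFF page per z slice (x along columns, y along
#' rows); the sidecar records voxel size, dims and axis order.
#'
#' @param annotation a `cre_annotation`.
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @export
write_annotation <- function(annotation, path) {
  pages <- lapply(seq_len(annotation$dims[3]), function(z) {
    t(annotation$labels[, , z]) / 65535   # rows = y, cols = x
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(voxel_size_um = annotation$voxel_size_um,
                            dims = annotation$dims,
                            axis_order = c("x_ml", "y_dv", "z_rc"),
                            page_axis = "z", row_axis = "y", col_axis = "x"),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  dims <- as.integer(meta$dims)
  labels <- array(0L, dim = dims)
  for (z in seq_len(dims[3])) labels[, , z] <- as.integer(t(pages[[z]]))
  structure(list(voxel_size_um = meta$voxel_size_um, dims = dims,
                 labels = labels), class = "cre_annotation")
}

#' Write an image series (8-bit grayscale PNGs + JSON sidecar)
#'
#' @param series a `cre_series`.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(series$sections))
  for (i in seq_along(series$sections)) {
    files[i] <- sprintf("section_%03d.png", i)
    png::writePNG(round(series$sections[[i]]$pixels) / 255,
                  file.path(dir, files[i]))
  }
  sidecar <- list(line_id = series$line_id, probe = series$probe,
                  replicate_index = series$replicate_index,
                  plane = series$plane, positions_um = series$positions_um,
                  pixel_size_um = series$pixel_size_um,
                  thickness_um = series$thickness_um,
                  spacing_um = series$spacing_um, seed = series$seed,
                  files = files)
  jsonlite::write_json(sidecar, file.path(dir, "series.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "series.json"))
}

#' Read an image series written by [write_series()]
#'
#' Tissue masks are reconstructed from the annotation volume using the
#' stored section positions.
#'
#' @param dir series directory.
#' @param annotation the `cre_annotation` the series was rendered against.
#' @return a `cre_series`.
#' @export
read_series <- function(dir, annotation) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  sections <- lapply(seq_along(meta$files), function(i) {
    px <- png::readPNG(file.path(dir, meta$files[i])) * 255
    tis <- tissue_mask(annotation, meta$plane, meta$positions_um[i],
                       meta$pixel_size_um)
    structure(list(pixels = px, in_tissue = tis, plane = meta$plane,
                   position_um = meta$positions_um[i],
                   thickness_um = meta$thickness_um,
                   pixel_size_um = meta$pixel_size_um,
                   transform = section_transform(meta$plane,
                                                 meta$positions_um[i],
                                                 meta$pixel_size_um)),
              class = "cre_section")
  })
  structure(list(sections = sections, plane = meta$plane,
                 spacing_um = meta$spacing_um, thickness_um = meta$thickness_um,
                 pixel_size_um = meta$pixel_size_um,
                 positions_um = meta$positions_um, line_id = meta$line_id,
                 probe = meta$probe, replicate_index = meta$replicate_index,
                 seed = meta$seed),
            class = "cre_series")
}

#' Write / read an energy vector CSV
#'
#' One row per mid-level structure (`structure_id`, `acronym` if an ontology
#' is supplied, `sum_detected_intensity`, `n_total`, `energy`); header
#' metadata (line, probe, plane, whole-brain energy) in comment lines.
#'
#' @param ev a `cre_energy`.
#' @param path CSV path.
#' @param ontology optional, adds acronyms.
#' @export
write_energy_csv <- function(ev, path, ontology = NULL) {
  df <- as.data.frame(ev)
  if (!is.null(ontology))
    df$acronym <- ontology$nodes$acronym[match(df$structure_id,
                                               ontology$nodes$id)]
  hdr <- sprintf("# %s: %s", c("line_id", "probe", "plane", "whole_brain_energy"),
                 c(ev_meta(ev, "line_id"), ev_meta(ev, "probe"),
                   ev_meta(ev, "plane"),
                   format(ev_meta(ev, "whole_brain_energy"), digits = 17)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_csv
#' @export
read_energy_csv <- function(path) {
  hdr <- readLines(path, n = 4)
  meta <- sub("^# [a-z_]+: ", "", hdr)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- df[, c("structure_id", "sum_detected_intensity", "n_total", "energy")]
  structure(df, line_id = meta[1], probe = meta[2], plane = meta[3],
            whole_brain_energy = as.numeric(meta[4]),
            class = c("cre_energy", "data.frame"))
}

#' Write a ground-truth CSV (structure_id, lambda, category)
#' @param gt a `cre_ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth_csv <- function(gt, path) {
  utils::write.csv(as.data.frame(gt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("cre_ground_truth", "data.frame"))
}
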