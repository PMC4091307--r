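# Shared fixtures, built in code at test time.

# small 3-division atlas with deterministic (jitter-free) block boundaries
tiny_atlas <- function(seed = 1) {
  build_toy_atlas(default_atlas_spec(3, 2, dims = c(20, 12, 24),
                                     voxel_size_um = 50, jitter_voxels = 0),
                  seed = seed)
}

# hand-made section: pixels and tissue mask given explicitly, with the same
# transform conventions as the renderer
manual_section <- function(pixels, in_tissue = NULL, plane = "coronal",
                           position_um = 12.5, pixel_size_um = 10,
                           thickness_um = 25) {
  if (is.null(in_tissue)) in_tissue <- matrix(TRUE, nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, in_tissue = in_tissue, plane = plane,
                 position_um = position_um, thickness_um = thickness_um,
                 pixel_size_um = pixel_size_um,
                 transform = crequant:::section_transform(plane, position_um,
                                                          pixel_size_um)),
            class = "cre_section")
}

manual_mask <- function(detected, b = 0, s = 0, k = 3) {
  structure(list(detected = detected, background_level = b, spread = s,
                 threshold = b + k * s, k = k), class = "cre_mask")
}

# hand-made energy vector for analysis tests
manual_energy <- function(structure_ids, energies, line_id = "L",
                          plane = "coronal", probe = "tdTomato",
                          n_total = rep(100, length(energies)),
                          whole_brain = NULL) {
  sdet <- energies * n_total
  structure(data.frame(structure_id = structure_ids,
                       sum_detected_intensity = sdet, n_total = n_total,
                       energy = energies),
            line_id = line_id, probe = probe, plane = plane,
            whole_brain_energy = whole_brain %||%
              (sum(sdet, na.rm = TRUE) / sum(n_total[!is.na(energies)])),
            class = c("cre_energy", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Spearman oracle: explicit average ranks + textbook Pearson sum
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force ancestor list by repeated parent lookup on the nodes table
oracle_ancestors <- function(nodes, id) {
  out <- integer(0)
  repeat {
    p <- nodes$parent_id[nodes$id == id]
    if (is.na(p)) return(out)
    out <- c(out, p)
    id <- p
  }
}

# random valid 3-level ontology: root -> divisions -> children, some children
# get an extra level of grandchildren; midlevel = children of divisions
random_ontology <- function(seed) {
  withr::with_seed(seed, {
    nd <- sample(2:4, 1)
    rows <- data.frame(id = 1L, acronym = "root", name = "root",
                       parent_id = NA_integer_, is_midlevel = FALSE,
                       is_division = FALSE)
    nid <- 1L
    mids <- integer(0)
    for (d in seq_len(nd)) {
      nid <- nid + 1L; did <- nid
      rows <- rbind(rows, data.frame(id = did, acronym = paste0("D", d),
                                     name = paste0("div", d), parent_id = 1L,
                                     is_midlevel = FALSE, is_division = TRUE))
      for (m in seq_len(sample(1:4, 1))) {
        nid <- nid + 1L; mid <- nid
        mids <- c(mids, mid)
        rows <- rbind(rows, data.frame(id = mid,
                                       acronym = paste0("D", d, "M", m),
                                       name = "mid", parent_id = did,
                                       is_midlevel = TRUE, is_division = FALSE))
        for (g in seq_len(sample(0:3, 1))) {
          nid <- nid + 1L
          rows <- rbind(rows, data.frame(id = nid,
                                         acronym = paste0("D", d, "M", m, "L", g),
                                         name = "leaf", parent_id = mid,
                                         is_midlevel = FALSE,
                                         is_division = FALSE))
        }
      }
    }
    structure(list(nodes = rows,
                   division_ids = rows$id[rows$is_division],
                   midlevel_ids = mids),
              class = "cre_ontology")
  })
}
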