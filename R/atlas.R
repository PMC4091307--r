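# Toy brain atlas: hierarchical ontology + 3D annotation volume.
#
# The real reference atlas carries ~800 annotated structures organised in a
# tree, with a designated mid-ontology level of non-overlapping structures
# that tile the whole brain, grouped under 12 major divisions.  The toy atlas
# reproduces that topology (root -> divisions -> leaf structures) on a small
# label volume whose leaf regions are axis-aligned blocks, so ground-truth
# volumes stay analytically computable.

DIVISION_ACRONYMS <- c("Iso", "OLF", "HPF", "CTsp", "STR", "PAL",
                       "TH", "HY", "MB", "P", "MY", "CB")
DIVISION_NAMES <- c("isocortex", "olfactory areas", "hippocampal formation",
                    "cortical subplate", "striatum", "pallidum", "thalamus",
                    "hypothalamus", "midbrain", "pons", "medulla", "cerebellum")

#' Default toy atlas specification
#'
#' Twelve major divisions with four mid-level structures each, on a
#' 80 x 44 x 192 voxel volume at 50 um isotropic resolution
#' (4.0 x 2.2 x 9.6 mm; one hemisphere, rostro-caudal extent comparable to a
#' mouse brain).  Divisions are rostro-caudal (z) slabs, mid-level structures
#' dorso-ventral (y) slabs within a division; with the default margins each
#' leaf slab is ~500 um tall, several 200 um grid rows, so grid-centre
#' structure assignment is only mildly diluted at slab boundaries.
#'
#' @param n_divisions number of major divisions (z slabs).
#' @param leaves_per_division leaf structures per division (y slabs).
#' @param dims integer triple: voxels along x (medio-lateral),
#'   y (dorso-ventral), z (rostro-caudal).
#' @param voxel_size_um isotropic voxel edge, micrometres.
#' @param margin_voxels out-of-brain margin (label 0) along x and y.
#' @param jitter_voxels max random shift of internal block boundaries.
#' @return a list usable as the `spec` of [build_toy_atlas()].
#' @export
default_atlas_spec <- function(n_divisions = 12, leaves_per_division = 4,
                               dims = c(80L, 44L, 192L), voxel_size_um = 50,
                               margin_voxels = 2L, jitter_voxels = 1L) {
  list(n_divisions = n_divisions, leaves_per_division = leaves_per_division,
       dims = as.integer(dims), voxel_size_um = voxel_size_um,
       margin_voxels = as.integer(margin_voxels),
       jitter_voxels = as.integer(jitter_voxels))
}

# split `n` items into `k` contiguous blocks with optional boundary jitter;
# returns integer vector of block sizes, each >= 1
split_blocks <- function(n, k, jitter) {
  cuts <- round(seq(0, n, length.out = k + 1))
  if (jitter > 0 && k > 1) {
    inner <- cuts[2:k] + sample(-jitter:jitter, k - 1, replace = TRUE)
    cuts[2:k] <- pmin(pmax(inner, seq_len(k - 1)), n - rev(seq_len(k - 1)))
    cuts <- cummax(cuts)
  }
  sizes <- diff(cuts)
  if (any(sizes < 1)) sizes <- diff(round(seq(0, n, length.out = k + 1)))
  as.integer(sizes)
}

#' Build a toy hierarchical ontology and annotation volume
#'
#' Constructs a three-level structure tree (root, `n_divisions` major
#' divisions, `leaves_per_division` leaf structures per division) and a 3D
#' integer label volume in which each leaf occupies a contiguous axis-aligned
#' block.  Label 0 marks out-of-brain voxels.  The mid-level tiling partition
#' defaults to the divisions' children, i.e. the leaves themselves.
#'
#' @param spec atlas specification, see [default_atlas_spec()].
#' @param seed integer seed controlling boundary jitter; the result is a pure
#'   function of `(spec, seed)`.
#' @return a list with elements `ontology` (class `cre_ontology`) and
#'   `annotation` (class `cre_annotation`).
#' @examples
#' atlas <- build_toy_atlas(default_atlas_spec(3, 2, dims = c(12, 8, 12)), seed = 1)
#' nrow(atlas$ontology$nodes)  # 1 + 3 + 3 * 2
#' @export
build_toy_atlas <- function(spec = default_atlas_spec(), seed = 1L) {
  nd <- spec$n_divisions; lpd <- spec$leaves_per_division
  dims <- as.integer(spec$dims)
  cq_assert(length(dims) == 3 && all(dims >= 1), "dims must be 3 positive integers",
            "invalid_spec")
  cq_assert(isTRUE(nd >= 1) && isTRUE(lpd >= 1),
            "n_divisions and leaves_per_division must be >= 1", "invalid_spec")
  cq_assert(spec$voxel_size_um > 0, "voxel_size_um must be positive", "invalid_spec")
  margin <- spec$margin_voxels %||% 0L
  jitter <- spec$jitter_voxels %||% 0L
  cq_assert(dims[1] > 2 * margin && dims[2] > 2 * margin,
            "margin leaves no in-brain voxels", "invalid_spec")

  div_acr <- if (nd <= 12) DIVISION_ACRONYMS[seq_len(nd)] else
    c(DIVISION_ACRONYMS, paste0("DIV", 13:nd))[seq_len(nd)]
  div_name <- if (nd <= 12) DIVISION_NAMES[seq_len(nd)] else
    c(DIVISION_NAMES, paste0("division ", 13:nd))[seq_len(nd)]

  nd <- as.integer(nd); lpd <- as.integer(lpd)
  root_id <- 1L
  div_ids <- 1L + seq_len(nd)
  leaf_ids <- 1L + nd + seq_len(nd * lpd)
  nodes <- data.frame(
    id = c(root_id, div_ids, leaf_ids),
    acronym = c("grey",
                div_acr,
                paste0(rep(div_acr, each = lpd), seq_len(lpd))),
    name = c("brain root",
             div_name,
             paste0(rep(div_name, each = lpd), ", part ", seq_len(lpd))),
    parent_id = c(NA_integer_, rep(root_id, nd), rep(div_ids, each = lpd)),
    stringsAsFactors = FALSE)
  nodes$is_midlevel <- nodes$id %in% leaf_ids
  nodes$is_division <- nodes$id %in% div_ids

  ontology <- structure(
    list(nodes = nodes, division_ids = div_ids, midlevel_ids = leaf_ids),
    class = "cre_ontology")
  validate_ontology(ontology)

  labels <- with_seed(seed, {
    lab <- array(0L, dim = dims)
    xs <- (margin + 1L):(dims[1] - margin)
    ybrain <- (margin + 1L):(dims[2] - margin)
    z_sizes <- split_blocks(dims[3], nd, jitter)
    z_hi <- cumsum(z_sizes); z_lo <- z_hi - z_sizes + 1L
    for (d in seq_len(nd)) {
      y_sizes <- split_blocks(length(ybrain), lpd, jitter)
      y_hi <- cumsum(y_sizes); y_lo <- y_hi - y_sizes + 1L
      for (l in seq_len(lpd)) {
        leaf <- leaf_ids[(d - 1L) * lpd + l]
        lab[xs, ybrain[y_lo[l]:y_hi[l]], z_lo[d]:z_hi[d]] <- leaf
      }
    }
    lab
  })

  annotation <- structure(
    list(voxel_size_um = spec$voxel_size_um, dims = dims, labels = labels),
    class = "cre_annotation")
  validate_annotation(annotation, ontology)
  list(ontology = ontology, annotation = annotation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ontology_leaves <- function(ontology) {
  nodes <- ontology$nodes
  setdiff(nodes$id, nodes$parent_id[!is.na(nodes$parent_id)])
}

# all ancestors of id, nearest first (excludes id itself)
ancestors_of <- function(nodes, id) {
  out <- integer(0)
  p <- nodes$parent_id[match(id, nodes$id)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- nodes$parent_id[match(p, nodes$id)]
    if (length(out) > nrow(nodes)) cq_stop("cycle in parent assignment", "invalid_spec")
  }
  out
}

#' Validate an ontology's structural invariants
#'
#' Checks unique ids and acronyms, a single root, acyclic and connected
#' parent links, that `midlevel_ids` form an antichain, and that every leaf
#' has exactly one mid-level ancestor-or-self and exactly one division
#' ancestor-or-self.
#'
#' @param ontology a `cre_ontology`.
#' @return the ontology, invisibly; raises an `invalid_spec` or
#'   `partition_violation` error otherwise.
#' @export
validate_ontology <- function(ontology) {
  nodes <- ontology$nodes
  cq_assert(!anyDuplicated(nodes$id), "duplicate node ids", "invalid_spec")
  cq_assert(!anyDuplicated(nodes$acronym), "duplicate acronyms", "invalid_spec")
  cq_assert(all(nodes$id > 0), "ids must be positive", "invalid_spec")
  roots <- nodes$id[is.na(nodes$parent_id)]
  cq_assert(length(roots) == 1, "exactly one root required", "invalid_spec")
  cq_assert(all(nodes$parent_id[!is.na(nodes$parent_id)] %in% nodes$id),
            "parent_id refers to unknown node", "invalid_spec")
  # acyclicity + connectivity: every node must reach the root
  for (id in nodes$id) {
    anc <- ancestors_of(nodes, id)  # raises on cycle
    cq_assert(id == roots || roots %in% anc, "node not connected to root",
              "invalid_spec")
  }
  ml <- ontology$midlevel_ids
  cq_assert(all(ml %in% nodes$id), "unknown midlevel id", "invalid_spec")
  for (m in ml)
    cq_assert(!any(ancestors_of(nodes, m) %in% ml),
              "midlevel_ids are not an antichain", "partition_violation")
  for (leaf in ontology_leaves(ontology)) {
    n_ml <- sum(c(leaf, ancestors_of(nodes, leaf)) %in% ml)
    cq_assert(n_ml == 1L,
              sprintf("leaf %d has %d mid-level ancestors (need exactly 1)",
                      leaf, n_ml), "partition_violation")
  }
  invisible(ontology)
}

validate_annotation <- function(annotation, ontology) {
  leaves <- ontology_leaves(ontology)
  labs <- unique(as.vector(annotation$labels))
  labs <- labs[labs != 0L]
  cq_assert(all(labs %in% leaves), "nonzero labels must be ontology leaves",
            "invalid_spec")
  cq_assert(all(leaves %in% labs), "every leaf needs at least one voxel",
            "invalid_spec")
  invisible(annotation)
}

#' Mid-level tiling partition of the leaves
#'
#' Maps every leaf structure to the unique mid-level structure whose subtree
#' contains it.  The mid-level set is the atlas analog of the mid-ontology
#' list of non-overlapping structures tiling the whole brain.
#'
#' @param ontology a validated `cre_ontology`.
#' @param annotation optional `cre_annotation`; when given, labels are checked
#'   against the ontology's leaves.
#' @return named integer vector: names are leaf ids, values mid-level ids.
#' @export
midlevel_partition <- function(ontology, annotation = NULL) {
  nodes <- ontology$nodes
  ml <- ontology$midlevel_ids
  leaves <- ontology_leaves(ontology)
  if (!is.null(annotation)) validate_annotation(annotation, ontology)
  out <- vapply(leaves, function(leaf) {
    hits <- intersect(c(leaf, ancestors_of(nodes, leaf)), ml)
    if (length(hits) != 1L)
      cq_stop(sprintf("leaf %d has %d mid-level ancestors (need exactly 1)",
                      leaf, length(hits)), "partition_violation")
    hits
  }, integer(1))
  names(out) <- leaves
  out
}

#' Mid-level structure of a voxel
#'
#' @param annotation a `cre_annotation`.
#' @param partition leaf -> mid-level map from [midlevel_partition()].
#' @param ijk integer voxel index triple (1-based x, y, z).
#' @return the mid-level structure id, or `NA` for out-of-brain voxels.
#' @export
voxel_structure <- function(annotation, partition, ijk) {
  cq_assert(length(ijk) == 3 && all(ijk >= 1) && all(ijk <= annotation$dims),
            "voxel index out of bounds", "bounds")
  lab <- annotation$labels[ijk[1], ijk[2], ijk[3]]
  if (lab == 0L) return(NA_integer_)
  unname(partition[as.character(lab)])
}

# vectorized interior lookup used by gridding: labels for n x 3 index matrix,
# out-of-volume rows -> 0
labels_at <- function(annotation, ijk) {
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= annotation$dims[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= annotation$dims[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= annotation$dims[3]
  out <- integer(nrow(ijk))
  if (any(ok)) out[ok] <- annotation$labels[ijk[ok, , drop = FALSE]]
  out
}

#' Structure volumes in cubic millimetres
#'
#' @inheritParams voxel_structure
#' @return named numeric vector, one entry per mid-level id (mm^3).
#' @export
structure_volumes <- function(annotation, partition) {
  counts <- table(factor(partition[as.character(annotation$labels)],
                         levels = sort(unique(partition))))
  v_mm3 <- (annotation$voxel_size_um / 1000)^3
  out <- as.numeric(counts) * v_mm3
  names(out) <- names(counts)
  out
}

# division ancestor-or-self for each mid-level id
division_of <- function(ontology, ids = ontology$midlevel_ids) {
  nodes <- ontology$nodes
  names(ids) <- as.character(ids)
  vapply(ids, function(id) {
    hits <- intersect(c(id, ancestors_of(nodes, id)), ontology$division_ids)
    if (length(hits) != 1L)
      cq_stop(sprintf("structure %d has %d division ancestors", id, length(hits)),
              "partition_violation")
    hits
  }, integer(1))
}

#' @export
print.cre_ontology <- function(x, ...) {
  cat(sprintf("<cre_ontology> %d nodes, %d divisions, %d mid-level structures\n",
              nrow(x$nodes), length(x$division_ids), length(x$midlevel_ids)))
  invisible(x)
}

#' @export
print.cre_annotation <- function(x, ...) {
  cat(sprintf("<cre_annotation> %d x %d x %d voxels @ %g um (%.2f mm^3 brain)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_um,
              sum(x$labels != 0L) * (x$voxel_size_um / 1000)^3))
  invisible(x)
}
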