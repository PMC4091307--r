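# Internal helpers: classed conditions, seeded RNG scopes, voxel geometry.

#' Signal a classed crequant error
#'
#' All user-facing failures raise conditions with class
#' `crequant_<class>_error` so callers (and tests) can discriminate failure
#' modes without string matching.
#'
#' @param msg message text.
#' @param class short error class, e.g. "invalid_spec".
#' @param call. included for symmetry with [stop()]; unused.
#' @keywords internal
#' @noRd
cq_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("crequant_", class, "_error"),
                                     "crequant_error")))
}

# bitwise xor for non-negative doubles < 2^32 (base bitwXor is 31-bit only)
xor32 <- function(a, b) {
  a1 <- as.integer(floor(a / 65536)); a0 <- as.integer(a %% 65536)
  b1 <- as.integer(floor(b / 65536)); b0 <- as.integer(b %% 65536)
  bitwXor(a1, b1) * 65536 + bitwXor(a0, b0)
}

cq_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) cq_stop(msg, class)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a top-level seed and a label
#'
#' A small stable arithmetic hash (32-bit, Fowler/Noll/Vo style) so that
#' per-stage / per-replicate streams differ but the whole run is a pure
#' function of the top-level seed.
#'
#' @param seed integer top-level seed.
#' @param ... label components (coerced to character, pasted with "/").
#' @return an integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  p <- 16777619
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- xor32(h, b)
    # h * p mod 2^32 in double precision via 16-bit split
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- ((h1 * p) %% 65536 * 65536 + h0 * p) %% 2^32
  }
  h <- xor32(h %% 2^31, as.numeric(seed) %% 2^31)
  as.integer(h %% .Machine$integer.max)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Half-open interval membership lo <= x < hi, the tiling convention used for
# voxels, slabs and grid cells throughout (no double counting at boundaries).
in_halfopen <- function(x, lo, hi) x >= lo & x < hi

# Map micrometre coordinates to 1-based voxel indices under half-open voxel
# intervals [(i-1)*v, i*v).
um_to_voxel <- function(um, voxel_size_um) floor(um / voxel_size_um) + 1L

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
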