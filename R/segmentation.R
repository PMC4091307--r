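# Expression-mask segmentation: detect ISH signal above background.
#
# The background of an ISH section is estimated robustly from in-tissue
# pixels (median and MAD), and a pixel is called "expressing" when its
# intensity exceeds background + k * max(MAD_sd, s_min).  The MAD floor
# s_min keeps the threshold meaningful on noiseless or near-constant
# sections, where the raw MAD collapses to 0.

#' Robust background estimate of a section
#'
#' @param section a `cre_section`.
#' @return list with `b` (median of in-tissue intensities) and `s` (median
#'   absolute deviation scaled to an SD equivalent, x 1.4826).
#' @export
estimate_background <- function(section) {
  v <- section$pixels[section$in_tissue]
  cq_assert(length(v) > 0, "section has no in-tissue pixels", "no_tissue")
  b <- stats::median(v)
  s <- stats::mad(v, center = b)  # constant = 1.4826
  list(b = b, s = s)
}

#' Segment expression above background
#'
#' A pixel is detected iff it is in-tissue and strictly brighter than
#' `b + k * max(s, s_min)`.  Pure, idempotent, no morphological cleanup.
#'
#' @param section a `cre_section`.
#' @param b,s background level and spread; when `NULL` both are estimated
#'   with [estimate_background()].
#' @param k threshold multiplier (> 0).
#' @param s_min floor on the spread estimate, intensity units.
#' @return a `cre_mask`: list with logical matrix `detected`,
#'   `background_level`, `spread`, `threshold`, `k`.
#' @export
detect_expression <- function(section, b = NULL, s = NULL, k = 3, s_min = 2) {
  cq_assert(k > 0, "k must be positive", "invalid_spec")
  if (is.null(b) || is.null(s)) {
    est <- estimate_background(section)
    b <- b %||% est$b
    s <- s %||% est$s
  }
  thr <- b + k * max(s, s_min)
  structure(list(detected = section$in_tissue & section$pixels > thr,
                 background_level = b, spread = s, threshold = thr, k = k),
            class = "cre_mask")
}

#' Summary counts of an expression mask
#'
#' @param mask a `cre_mask`.
#' @param section the `cre_section` the mask was computed from.
#' @return list with `n_detected`, `n_total` (in-tissue pixels) and
#'   `sum_detected_intensity`.
#' @export
mask_summary <- function(mask, section) {
  cq_assert(all(dim(mask$detected) == dim(section$pixels)),
            "mask and image are not co-registered", "registration")
  list(n_detected = sum(mask$detected),
       n_total = sum(section$in_tissue),
       sum_detected_intensity = sum(section$pixels[mask$detected]))
}
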