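# Centroid-to-axle distance descriptor.
#
# Per frame i the raw distance is the Euclidean distance between the fillet
# centroid and the fixed reference point at the roller axle center,
#   d_i = sqrt((x_c - x_r)^2 + (y_c - y_r)^2)           [px].
# The raw distance is not scale invariant: thicker fillets ride higher and
# give larger d_i. It is therefore normalized by a per-fillet scale factor
# measured on the first (flat) tracking frame,
#   H = ht + R,          d_hat_i = d_i / H              [unitless],
# and the per-fillet summaries are MDM = min_i d_i and NMDM = min_i d_hat_i
# (= MDM / H). A flexible (normal) fillet drapes further over the edge, its
# centroid approaches the axle, and both minima are smaller than for a
# stiff wooden-breast fillet.

#' Euclidean centroid-to-reference distance
#'
#' @param centroid numeric (row, col) position of the fillet centroid.
#' @param reference numeric (row, col) position of the reference point
#'   (roller axle center).
#' @return distance in pixels.
#' @examples
#' distance_i(c(3, 4), c(0, 0))  # 5
#' @export
distance_i <- function(centroid, reference) {
  if (length(centroid) != 2L || length(reference) != 2L) {
    stop_invalid("`centroid` and `reference` must be (row, col) pairs")
  }
  sqrt(sum((as.numeric(centroid) - as.numeric(reference))^2))
}

#' Per-fillet scale factors from the first flat frame
#'
#' `scale_factor_H()` returns `H = ht + R`, the normalization used by the
#' distance descriptor. `alt_scale_factors()` additionally returns the
#' alternative `H' = hb + R`; both are exported to the feature table as
#' `HTR` and `HBR`.
#'
#' @param first_segment the `fillet_segment` of the first tracking-window
#'   frame (fillet still flat on the belt).
#' @param R roller radius in pixels.
#' @return `scale_factor_H()`: the scalar `H` in pixels;
#'   `alt_scale_factors()`: named vector `c(HTR, HBR)`.
#' @export
scale_factor_H <- function(first_segment, R) {
  if (!is_number(R) || R < 0) stop_invalid("`R` must be a non-negative number")
  hf <- height_features(first_segment)
  unname(hf[["ht"]] + R)
}

#' @rdname scale_factor_H
#' @export
alt_scale_factors <- function(first_segment, R) {
  if (!is_number(R) || R < 0) stop_invalid("`R` must be a non-negative number")
  hf <- height_features(first_segment)
  c(HTR = unname(hf[["ht"]] + R), HBR = unname(hf[["hb"]] + R))
}

#' Distance trace and minima over a tracked pass
#'
#' Computes `H` from the first segment, the raw and normalized distances for
#' every frame, and the minima `MDM`/`NMDM` with first-occurrence
#' tie-breaking. Frames where segmentation failed (`NULL` entries) are
#' skipped, not interpolated.
#'
#' @param window_segments list of `fillet_segment` objects for the frames of
#'   one tracking window (first entry must be the flat first frame).
#' @param geom a [scene_geometry()] supplying the reference point and `R`.
#' @return an object of class `distance_trace`: `d_raw`, `d_norm` (per-frame
#'   vectors, `NA` where skipped), `H`, `R`, `reference_point`, `MDM`,
#'   `NMDM`, `argmin_frame`.
#' @export
run_distance_trace <- function(window_segments, geom) {
  stopifnot(inherits(geom, "scene_geometry"))
  if (inherits(window_segments, "fillet_segment")) {
    window_segments <- list(window_segments)
  }
  if (!is.list(window_segments) || !length(window_segments)) {
    stop_no_object("empty tracking window")
  }
  valid <- !vapply(window_segments, is.null, logical(1))
  if (!any(valid)) stop_no_object("no valid segment in the tracking window")
  first <- window_segments[[which(valid)[1]]]
  H <- scale_factor_H(first, geom$roller_radius)
  ref <- geom$reference_point
  d_raw <- rep(NA_real_, length(window_segments))
  for (i in which(valid)) {
    d_raw[i] <- distance_i(window_segments[[i]]$centroid, ref)
  }
  argmin <- which.min(d_raw)  # first occurrence on ties
  structure(list(
    d_raw = d_raw,
    d_norm = d_raw / H,
    H = H,
    R = geom$roller_radius,
    reference_point = ref,
    MDM = d_raw[argmin],
    NMDM = d_raw[argmin] / H,
    argmin_frame = as.integer(argmin)
  ), class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat("Distance trace over", length(x$d_raw), "frames: MDM =",
      round(x$MDM, 2), "px, NMDM =", round(x$NMDM, 4),
      "(H =", round(x$H, 2), "px) at frame", x$argmin_frame, "\n")
  invisible(x)
}
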