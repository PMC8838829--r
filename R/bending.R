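# Scale-invariant bending energy of a fillet segment.
#
# Pipeline per frame: (1) measure the major-axis angle of the segment,
# (2) rotate the mask about its centroid so the major axis is horizontal,
# (3) skeletonize the rotated mask with the medial-axis transform,
# (4) regress the skeleton points with a quadratic curve y = a x^2 + b x + c,
# (5) evaluate the analytic curvature of the fitted curve at the L integer
# columns spanned by the skeleton and assemble
#     BE = (P^2 / L) * sum_k C(k)^2,
# where P is the segment contour perimeter. Normalizing by L and P^2 makes
# BE invariant to uniform scaling of the shape.

#' Rotate a fillet mask so its major axis is horizontal
#'
#' Nearest-neighbor (binary-preserving) rotation of the segment mask about
#' its centroid by minus the major-axis angle, onto a square canvas large
#' enough to hold the rotated shape.
#'
#' @param segment a `fillet_segment` (or a logical mask, which is first
#'   passed through [region_properties()]).
#' @return a logical matrix whose major-axis angle is within about a degree
#'   of zero.
#' @export
rotate_to_major_axis <- function(segment) {
  if (!inherits(segment, "fillet_segment")) segment <- region_properties(segment)
  if (segment$area < 3L) stop_invalid("mask too small to orient")
  bb <- segment$bbox
  rows_px <- (bb[["top"]] + 1L):bb[["bottom"]]
  cols_px <- (bb[["left"]] + 1L):bb[["right"]]
  crop <- segment$mask[rows_px, cols_px, drop = FALSE]
  hc <- nrow(crop); wc <- ncol(crop)
  theta <- segment$major_axis_angle
  side <- ceiling(sqrt(hc^2 + wc^2)) + 4L
  cy <- segment$centroid[["row"]] - bb[["top"]]   # centroid in crop coords
  cx <- segment$centroid[["col"]] - bb[["left"]]
  # inverse mapping: source = R(theta) (p_out - canvas center) + centroid
  dy <- matrix(seq_len(side) - 0.5 - side / 2, side, side)
  dx <- matrix(rep(seq_len(side) - 0.5 - side / 2, each = side), side, side)
  sx <- cos(theta) * dx - sin(theta) * dy + cx
  sy <- sin(theta) * dx + cos(theta) * dy + cy
  sr <- floor(sy) + 1L; sc <- floor(sx) + 1L
  valid <- sr >= 1L & sr <= hc & sc >= 1L & sc <= wc
  out <- matrix(FALSE, side, side)
  out[valid] <- crop[cbind(sr[valid], sc[valid])]
  out
}

# Medial-axis points of a binary mask: foreground pixels whose Euclidean
# distance-transform value is a (weak) local maximum over the 8-neighborhood,
# i.e. centers of maximal inscribed discs. Returned unpruned.
medial_axis_points <- function(mask) {
  dm <- as.matrix(EBImage::distmap(mask * 1))
  H <- nrow(dm); W <- ncol(dm)
  nbmax <- matrix(-Inf, H, W)
  for (dr in -1:1) {
    sr <- max(1L, 1L - dr):min(H, H - dr)
    tr <- sr + dr
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      sc <- max(1L, 1L - dc):min(W, W - dc)
      tc <- sc + dc
      nbmax[tr, tc] <- pmax(nbmax[tr, tc], dm[sr, sc])
    }
  }
  which(mask & dm >= nbmax, arr.ind = TRUE)
}

#' Skeletonize a rotated mask and fit a quadratic curve
#'
#' Collects the medial-axis points of the (major-axis-horizontal) mask and
#' least-squares fits the skeleton row coordinate on the column coordinate
#' with a second-degree polynomial. Medial points otherwise feed the fit
#' unpruned (the quadratic regression is robust to sparse interior spurs),
#' except that points in the outermost `end_trim` quantiles of the column
#' extent are dropped: the branched end caps of a medial axis are boundary
#' artifacts that would otherwise leak the shape's pose into the fit.
#'
#' @param rotated_mask a logical matrix, typically from
#'   [rotate_to_major_axis()].
#' @param end_trim fraction of the column-coordinate distribution trimmed
#'   from each end before fitting.
#' @return an object of class `skeleton_curve`: `raw_points` (matrix of
#'   (row, col) pixel indices, untrimmed), `fit_coeffs` (named `a`, `b`, `c`
#'   of `y = a x^2 + b x + c` in continuous coordinates), `x_range` (pixel
#'   column span of the fitted points) and `n_samples` (`L`, the number of
#'   integer columns in `x_range`).
#' @export
skeletonize_and_fit <- function(rotated_mask, end_trim = 0.03) {
  if (!is.matrix(rotated_mask)) stop_invalid("`rotated_mask` must be a matrix")
  pts <- medial_axis_points(rotated_mask > 0)
  if (nrow(pts) < 3L || length(unique(pts[, 2])) < 3L) {
    stop_degenerate("fewer than 3 usable skeleton points")
  }
  lo <- stats::quantile(pts[, 2], end_trim, names = FALSE)
  hi <- stats::quantile(pts[, 2], 1 - end_trim, names = FALSE)
  keep <- pts[, 2] >= lo & pts[, 2] <= hi
  if (sum(keep) < 3L || length(unique(pts[keep, 2])) < 3L) {
    keep <- rep(TRUE, nrow(pts))
  }
  x <- pts[keep, 2] - 0.5
  y <- pts[keep, 1] - 0.5
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  co <- fit$coefficients
  structure(list(
    raw_points = pts,
    fit_coeffs = c(a = unname(co[3]), b = unname(co[2]), c = unname(co[1])),
    x_range = c(min(pts[keep, 2]), max(pts[keep, 2])),
    n_samples = as.integer(diff(range(pts[keep, 2]))) + 1L
  ), class = "skeleton_curve")
}

#' Bending energy of one fillet segment
#'
#' The curvature `C(k) = |y''| / (1 + y'^2)^(3/2)` of the fitted skeleton
#' quadratic is evaluated at the `L` integer columns the skeleton spans, and
#' the bending energy assembled as `BE = (P^2 / L) * sum C(k)^2` with `P`
#' the segment contour perimeter, measured on the de-rotated mask as a
#' chord-length sum along the traced contour (a weighted pixel-step length
#' is orientation sensitive, and `P` enters squared). A straight
#' fillet has `BE ~ 0`; stronger bending gives larger `BE`, and uniform
#' rescaling of the shape leaves `BE` essentially unchanged.
#'
#' @param segment a `fillet_segment` (or logical mask).
#' @return an object of class `bending_energy_value`: `BE`, `P`, `L`,
#'   `curvature_samples` (the `C(k)`, units 1/px) and the fitted
#'   `skeleton` curve.
#' @export
compute_bending_energy <- function(segment) {
  if (!inherits(segment, "fillet_segment")) segment <- region_properties(segment)
  rotated <- rotate_to_major_axis(segment)
  sk <- skeletonize_and_fit(rotated)
  a <- sk$fit_coeffs[["a"]]; b <- sk$fit_coeffs[["b"]]
  xs <- (sk$x_range[1]:sk$x_range[2]) - 0.5
  yp <- 2 * a * xs + b
  curv <- abs(2 * a) / (1 + yp^2)^1.5
  P <- .smooth_perimeter(rotated)
  structure(list(
    BE = (P^2 / sk$n_samples) * sum(curv^2),
    P = P,
    L = sk$n_samples,
    curvature_samples = curv,
    skeleton = sk
  ), class = "bending_energy_value")
}

#' @export
print.bending_energy_value <- function(x, ...) {
  cat("Bending energy:", signif(x$BE, 5), "(P =", round(x$P, 1),
      "px, L =", x$L, "px)\n")
  invisible(x)
}

#' Maximum bending energy over a tracked pass
#'
#' Computes the per-frame bending energy for every segment in the tracking
#' window and returns the maximum. Frames whose shape is degenerate (e.g.
#' the fillet is mostly out of the field of view) are skipped with a
#' warning, not zero-filled.
#'
#' @param segments list of `fillet_segment` objects (entries may be `NULL`
#'   for frames where segmentation found no object; these are skipped).
#' @return an object of class `bending_trace`: `BE` (per-frame values, `NA`
#'   where skipped), `MBE` (the maximum), and `argmax_frame` (index of its
#'   first occurrence).
#' @export
max_bending_energy <- function(segments) {
  if (inherits(segments, "fillet_segment")) segments <- list(segments)
  if (!is.list(segments) || !length(segments)) {
    stop_invalid("`segments` must be a non-empty list")
  }
  be <- rep(NA_real_, length(segments))
  n_skipped <- 0L
  for (i in seq_along(segments)) {
    if (is.null(segments[[i]])) next
    be[i] <- tryCatch(compute_bending_energy(segments[[i]])$BE,
                      fb_degenerate_shape = function(e) NA_real_,
                      fb_invalid_argument = function(e) NA_real_)
    if (is.na(be[i])) n_skipped <- n_skipped + 1L
  }
  if (all(is.na(be))) stop_no_object("no frame yielded a valid bending energy")
  if (n_skipped > 0L) {
    warning(sprintf("%d degenerate frame(s) skipped in bending-energy trace",
                    n_skipped))
  }
  structure(list(BE = be, MBE = max(be, na.rm = TRUE),
                 argmax_frame = which.max(be)),
            class = "bending_trace")
}

#' @export
print.bending_trace <- function(x, ...) {
  cat("Bending trace over", length(x$BE), "frames: MBE =",
      signif(x$MBE, 5), "at frame", x$argmax_frame, "\n")
  invisible(x)
}
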