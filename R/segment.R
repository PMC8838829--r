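# Sideview fillet segmentation: a five-stage morphological pipeline
# (global threshold -> hole filling -> median filter -> morphological
# opening -> object size filter), followed by region properties of the
# surviving object. Stage order is fixed; see the methods vignette.

#' Segmentation parameters
#'
#' @param global_threshold 8-bit intensity threshold separating the bright
#'   fillet from the dark backdrop.
#' @param median_kernel side length (odd) of the median filter window; for a
#'   binary mask the median equals the neighborhood majority vote.
#' @param opening_radius radius in pixels of the disc structuring element for
#'   morphological opening (0 disables the stage).
#' @param min_object_area minimum object size in pixels; smaller isolated
#'   objects are removed.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(global_threshold = 60, median_kernel = 3,
                       opening_radius = 2, min_object_area = 500) {
  if (!is_number(global_threshold) || global_threshold < 0 ||
      global_threshold > 255) {
    stop_invalid("`global_threshold` must be in [0, 255]")
  }
  if (!is_count(median_kernel) || median_kernel %% 2 == 0) {
    stop_invalid("`median_kernel` must be an odd integer >= 1")
  }
  if (!is_count(opening_radius, min = 0L)) {
    stop_invalid("`opening_radius` must be an integer >= 0")
  }
  if (!is_count(min_object_area, min = 0L)) {
    stop_invalid("`min_object_area` must be an integer >= 0")
  }
  structure(list(global_threshold = global_threshold,
                 median_kernel = as.integer(median_kernel),
                 opening_radius = as.integer(opening_radius),
                 min_object_area = as.integer(min_object_area)),
            class = "seg_params")
}

# Majority (= median) filter for a binary mask: a pixel is foreground when
# more than half of its k x k neighborhood is foreground; borders are
# zero-padded. Implemented with shifted block sums.
.binary_median <- function(mask, k) {
  if (k <= 1L) return(mask)
  r <- (k - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  m <- mask * 1L
  acc <- matrix(0L, H, W)
  for (dr in -r:r) {
    sr <- max(1L, 1L - dr):min(H, H - dr)
    tr <- sr + dr
    for (dc in -r:r) {
      sc <- max(1L, 1L - dc):min(W, W - dc)
      tc <- sc + dc
      acc[tr, tc] <- acc[tr, tc] + m[sr, sc]
    }
  }
  acc >= (k * k + 1L) %/% 2L
}

# Outer contour pixels by Moore-neighbor tracing (8-connectivity, clockwise).
# Assumes a single object; for multi-object masks the object containing the
# topmost-leftmost foreground pixel is traced. Returns the ordered boundary
# points as an (n x 2) matrix of (row, col) indices.
.contour_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(idx)
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && mask[r, c]
  # clockwise Moore ring starting north
  dirs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)
  top <- min(idx[, 1])
  s <- c(top, min(idx[idx[, 1] == top, 2]))
  bdir <- 1L  # backtrack starts at the (background) north neighbor
  cur <- s
  pts <- matrix(NA_integer_, 4L * nrow(idx) + 8L, 2L)
  pts[1L, ] <- s
  steps <- 0L
  maxsteps <- 4L * nrow(idx) + 7L
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      r <- cur[1] + dirs[d, 1]; c2 <- cur[2] + dirs[d, 2]
      if (fg(r, c2)) {
        prev_d <- ((d - 2L) %% 8L) + 1L  # last background neighbor examined
        br <- cur[1] + dirs[prev_d, 1]; bc <- cur[2] + dirs[prev_d, 2]
        bdir <- which(dirs[, 1] == br - r & dirs[, 2] == bc - c2)
        cur <- c(r, c2)
        found <- TRUE
        break
      }
    }
    if (!found) return(pts[1L, , drop = FALSE])  # isolated under 8-connectivity
    steps <- steps + 1L
    if (cur[1] == s[1] && cur[2] == s[2]) break
    pts[steps + 1L, ] <- cur
    if (steps >= maxsteps) break
  }
  pts[seq_len(steps), , drop = FALSE]
}

# 8-connected contour length: steps weighted 1 (axial) and sqrt(2)
# (diagonal) along the closed Moore contour.
.contour_perimeter <- function(mask) {
  pts <- .contour_points(mask)
  n <- nrow(pts)
  if (n <= 1L) return(0)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  diag <- abs(nxt[, 1] - pts[, 1]) + abs(nxt[, 2] - pts[, 2]) == 2L
  sum(ifelse(diag, sqrt(2), 1))
}

# Orientation-robust contour length: chord sums over every `stride`-th
# contour point, insensitive to the staircase jitter that resampling (e.g.
# de-rotation) introduces into the digital boundary.
.smooth_perimeter <- function(mask, stride = 3L) {
  pts <- .contour_points(mask)
  n <- nrow(pts)
  if (n <= 1L) return(0)
  if (n <= 2L * stride) return(.contour_perimeter(mask))
  sel <- pts[seq(1L, n, by = stride), , drop = FALSE]
  nxt <- rbind(sel[-1L, , drop = FALSE], sel[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - sel)^2)))
}

#' Region properties of a binary fillet mask
#'
#' Computes the centroid (center of mass of the foreground, in continuous
#' edge-based coordinates where pixel `(i, j)` has center `(i-0.5, j-0.5)`),
#' area, 8-connected contour perimeter, bounding box, major-axis orientation
#' from second central moments, and the height/length summaries: maximum
#' height = bounding-box height, average height = mean per-column foreground
#' height, length = bounding-box width.
#'
#' @param mask a logical matrix with at least one foreground pixel,
#'   containing a single object.
#' @return an object of class `fillet_segment` with fields `mask`,
#'   `centroid` (row, col), `area`, `perimeter`, `bbox` (top, left, bottom,
#'   right edge coordinates), `major_axis_angle` (radians from the +column
#'   axis toward the +row axis), `max_height`, `avg_height`, `length`.
#' @export
region_properties <- function(mask) {
  if (!is.matrix(mask)) stop_invalid("`mask` must be a matrix")
  mask <- mask > 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_no_object("empty mask")
  rows <- idx[, 1]; cols <- idx[, 2]
  area <- nrow(idx)
  centroid <- c(row = mean(rows) - 0.5, col = mean(cols) - 0.5)
  top_px <- min(rows); bottom_px <- max(rows)
  left_px <- min(cols); right_px <- max(cols)
  len <- right_px - left_px + 1L
  colcount <- tabulate(cols - left_px + 1L, nbins = len)
  x <- cols - 0.5; y <- rows - 0.5
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  structure(list(
    mask = mask,
    centroid = centroid,
    area = area,
    perimeter = .contour_perimeter(mask),
    bbox = c(top = top_px - 1L, left = left_px - 1L,
             bottom = bottom_px, right = right_px),
    major_axis_angle = 0.5 * atan2(2 * mu11, mu20 - mu02),
    max_height = bottom_px - top_px + 1L,
    avg_height = area / sum(colcount > 0),
    length = len
  ), class = "fillet_segment")
}

#' @export
print.fillet_segment <- function(x, ...) {
  cat("Fillet segment:", x$area, "px, centroid (",
      round(x$centroid[["row"]], 1), ",", round(x$centroid[["col"]], 1),
      "), bbox", x$length, "x", x$max_height, "px, angle",
      round(x$major_axis_angle * 180 / pi, 1), "deg\n")
  invisible(x)
}

#' Segment the fillet object in one frame
#'
#' Applies, in order: (1) global thresholding, (2) hole filling (flood fill
#' from the raster border), (3) median filtering, (4) morphological opening
#' with a disc, (5) object size filtering. If several objects survive, the
#' largest is returned.
#'
#' @param frame an 8-bit grayscale matrix.
#' @param params a [seg_params()].
#' @return a [region_properties()] result (`fillet_segment`).
#' @export
segment_fillet <- function(frame, params = seg_params()) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop_invalid("`frame` must be a numeric matrix")
  }
  th <- frame > params$global_threshold
  if (!any(th)) stop_no_object("no pixel above the global threshold")
  filled <- as.matrix(EBImage::fillHull(th)) > 0
  med <- .binary_median(filled, params$median_kernel)
  if (params$opening_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$opening_radius + 1L, "disc")
    opened <- as.matrix(EBImage::opening(med * 1, brush)) > 0
  } else {
    opened <- med
  }
  lab <- as.matrix(EBImage::bwlabel(opened * 1))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= max(1L, params$min_object_area))
  if (!length(keep)) stop_no_object("no object survived segmentation")
  best <- keep[which.max(sizes[keep])]
  region_properties(lab == best)
}

#' First-frame height features h, ht, hb
#'
#' From a flat-fillet mask: `h` is the bounding-box height, `ht` the distance
#' from the top of the bounding box down to the centroid, and `hb` the
#' distance from the centroid down to the bottom of the bounding box (the
#' belt surface for a resting fillet), so that `h = ht + hb` exactly.
#'
#' @param mask a logical matrix or a `fillet_segment`.
#' @param belt_row optional row index of the belt surface used as the bottom
#'   edge instead of the mask's own bounding box (for a resting fillet the
#'   two coincide).
#' @return named numeric vector `c(h, ht, hb)` in pixels.
#' @export
height_features <- function(mask, belt_row = NULL) {
  if (inherits(mask, "fillet_segment")) mask <- mask$mask
  mask <- mask > 0
  idx_rows <- which(mask, arr.ind = TRUE)[, 1]
  if (!length(idx_rows)) stop_no_object("empty mask")
  top_edge <- min(idx_rows) - 1
  bottom_edge <- if (is.null(belt_row)) max(idx_rows) else belt_row
  centroid_row <- mean(idx_rows) - 0.5
  c(h = bottom_edge - top_edge,
    ht = centroid_row - top_edge,
    hb = bottom_edge - centroid_row)
}
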