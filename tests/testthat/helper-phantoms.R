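# Shared fixtures: all phantoms and scenes are generated in code.

# Compact scene for fast simulator-driven tests (same proportions as the
# default full-resolution scene, ~1/3 linear scale).
small_geom <- function(...) {
  scene_geometry(image_w = 320, image_h = 240, belt_row = 100,
                 edge_col = 200, roller_radius = 18,
                 arrival_col = 140, departure_row = 185,
                 line_speed = 5, ...)
}

small_profile <- function(rigidity = 30, length_px = 100,
                          max_thickness_px = 26, taper = 0.45) {
  fillet_profile(length_px, max_thickness_px, taper = taper,
                 rigidity = rigidity)
}

small_seg_params <- function(...) seg_params(min_object_area = 150, ...)

# Profile generator at small-scene scale, used to exercise cohort plumbing
# without full-resolution rendering.
small_profile_fun <- function(class_label, seed, ...) {
  rig <- c(normal = 20, moderate = 100, severe = 400)[[class_label]]
  with_seed(seed, {
    len <- max(40, round(stats::rnorm(1, 100, 4)))
    hgt <- max(8, round(stats::rnorm(1, 26, 2)))
    fillet_profile(len, hgt, rigidity = rig * exp(stats::rnorm(1, 0, 0.15)))
  })
}

# Axis-aligned filled rectangle mask.
mk_rect <- function(nrow = 200, ncol = 300, r0 = 50, r1 = 89,
                    c0 = 100, c1 = 199) {
  m <- matrix(FALSE, nrow, ncol)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# Filled disk mask of radius r.
mk_disk <- function(r, pad = 6) {
  n <- 2 * (r + pad)
  cy <- cx <- r + pad
  rowm <- matrix(seq_len(n) - 0.5, n, n)
  colm <- t(rowm)
  (rowm - cy)^2 + (colm - cx)^2 <= r^2
}

# Rectangle of half-extents (hx, hy) rotated by `theta` about the raster
# center, rasterized exactly from its inequality description.
mk_rot_rect <- function(theta, hx = 100, hy = 20, n = 400) {
  rowm <- matrix(seq_len(n) - 0.5, n, n)
  colm <- t(rowm)
  xr <- (colm - n / 2) * cos(theta) + (rowm - n / 2) * sin(theta)
  yr <- -(colm - n / 2) * sin(theta) + (rowm - n / 2) * cos(theta)
  abs(xr) <= hx & abs(yr) <= hy
}

# Band of vertical half-thickness `ht` around y = y0 + a (x - x0)^2.
mk_parabola_band <- function(a = 0.001, ht = 20, ncol = 320, nrow = 200,
                             y0 = 60, margin = 10) {
  colm <- matrix(rep(seq_len(ncol) - 0.5, each = nrow), nrow, ncol)
  rowm <- matrix(seq_len(nrow) - 0.5, nrow, ncol)
  yc <- y0 + a * (colm - ncol / 2)^2
  abs(rowm - yc) <= ht & colm >= margin & colm <= ncol - margin
}

# Constant-curvature band: radial half-thickness `ht` about a circle of
# radius R0, clipped to half-angle `phi` about the top of the circle.
mk_arc_band <- function(R0 = 400, phi = 0.5, ht = 12, n = 900) {
  cy <- R0 + 120; cx <- n / 2
  rowm <- matrix(seq_len(n) - 0.5, n, n)
  colm <- t(rowm)
  dist <- sqrt((rowm - cy)^2 + (colm - cx)^2)
  ang <- atan2(colm - cx, cy - rowm)
  abs(dist - R0) <= ht & abs(ang) <= phi
}

# Nearest-neighbor integer upscaling of a mask.
scale_mask <- function(mask, s) {
  stopifnot(s == round(s), s >= 1)
  mask[rep(seq_len(nrow(mask)), each = s), rep(seq_len(ncol(mask)), each = s)]
}

# Render a synthetic frame (background 10, object 200) from a mask.
frame_from_mask <- function(mask) {
  matrix(as.integer(ifelse(mask, 200L, 10L)), nrow(mask), ncol(mask))
}

# One cached small noise-free pass per rigidity, shared across tests.
.pass_cache <- new.env(parent = emptyenv())
cached_small_pass <- function(rigidity = 30, seed = 1, noise_sd = 0) {
  key <- paste0("r", rigidity, "s", seed, "n", noise_sd)
  if (is.null(.pass_cache[[key]])) {
    .pass_cache[[key]] <- simulate_pass(small_profile(rigidity), small_geom(),
                                        seed = seed, noise_sd = noise_sd)
  }
  .pass_cache[[key]]
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
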