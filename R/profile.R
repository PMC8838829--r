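# Fillet profiles: the 2D sideview silhouette and stiffness of one fillet.

# Class-conditional presets. Dimension means/SDs follow published sideview
# measurements of normal / moderate / severe wooden-breast fillets (length
# ~319-323 px, maximum height 73-85 px at the reference scale). Rigidity is
# a dimensionless stiffness used by the simulator's cantilever-like
# deflection law; wooden-breast fillets are stiffer, so presets increase
# with severity (see the methods vignette for the calibration rationale).
.fillet_presets <- list(
  normal   = list(length_mean = 319, length_sd = 12,
                  height_mean = 73, height_sd = 8, rigidity = 80),
  moderate = list(length_mean = 322, length_sd = 18,
                  height_mean = 80, height_sd = 7, rigidity = 320),
  severe   = list(length_mean = 323, length_sd = 15,
                  height_mean = 85, height_sd = 7, rigidity = 480)
)

#' Construct a fillet sideview profile
#'
#' A fillet silhouette is modeled as a smooth single-lobed height function
#' over its length: a rounded bump whose thickness tapers toward the leading
#' (tail) end, reflecting that fillets travel tail-end first and the tail is
#' typically thinner than the head. The `rigidity` parameter controls how
#' strongly the simulator's overhanging portion resists bending (high =
#' wooden-breast-like, low = normal-like).
#'
#' @param length_px head-to-tail extent in pixels (bounding-box width of the
#'   rasterized profile).
#' @param max_thickness_px maximum height in pixels.
#' @param taper fraction in `[0, 1]`; 0 gives a symmetric profile, larger
#'   values thin the tail end relative to the head end.
#' @param rigidity positive dimensionless stiffness (may be `Inf` for a
#'   perfectly rigid body).
#' @return an object of class `fillet_profile` with the per-column rasterized
#'   heights (`heights`), the closed outline polygon in local coordinates
#'   (`outline`, columns `x`, `y`, y measured up from the resting surface)
#'   and the input parameters.
#' @examples
#' p <- fillet_profile(120, 36, taper = 0.4)
#' max(p$heights)
#' @export
fillet_profile <- function(length_px, max_thickness_px, taper = 0.45,
                           rigidity = 120) {
  if (!is_count(length_px, min = 8)) {
    stop_invalid("`length_px` must be an integer >= 8")
  }
  if (!is_count(max_thickness_px, min = 3)) {
    stop_invalid("`max_thickness_px` must be an integer >= 3")
  }
  if (!is_number(taper) || taper < 0 || taper > 1) {
    stop_invalid("`taper` must be in [0, 1]")
  }
  if (!(is.numeric(rigidity) && length(rigidity) == 1L && rigidity > 0)) {
    stop_invalid("`rigidity` must be a positive number (possibly Inf)")
  }
  L <- as.integer(length_px)
  u <- (seq_len(L) - 0.5) / L              # 0 = tail (leading), 1 = head
  bump <- sin(pi * u)^0.6                  # rounded symmetric lobe
  tap <- (1 - taper) + taper * u           # thinner toward the tail
  h <- bump * tap
  h <- h / max(h) * max_thickness_px
  heights <- pmax(1L, as.integer(round(h)))
  # outline: counter-clockwise closed polygon, bottom edge then top profile
  outline <- data.frame(
    x = c(seq_len(L) - 0.5, rev(seq_len(L)) - 0.5),
    y = c(rep(0, L), rev(heights))
  )
  structure(list(
    length_px = L,
    max_thickness_px = as.integer(max_thickness_px),
    taper = taper,
    rigidity = rigidity,
    heights = heights,
    outline = outline
  ), class = "fillet_profile")
}

#' @export
print.fillet_profile <- function(x, ...) {
  cat("Fillet profile:", x$length_px, "px long, max height",
      x$max_thickness_px, "px, taper", x$taper,
      ", rigidity", x$rigidity, "\n")
  invisible(x)
}

#' Draw a class-conditional fillet profile
#'
#' Samples fillet dimensions from class-conditional Gaussians matching the
#' reference group means/SDs (normal: length 319 +/- 12, height 73 +/- 8 px;
#' moderate: 322 +/- 18, 80 +/- 7; severe: 323 +/- 15, 85 +/- 7), clamped to
#' sensible positive values, and a stiffness from the class rigidity preset
#' with log-normal between-fillet variation. Deterministic given `seed`.
#'
#' @param class_label one of `"normal"`, `"moderate"`, `"severe"`.
#' @param seed integer seed for the draw.
#' @param taper taper fraction passed to [fillet_profile()].
#' @param rigidity_base multiplier applied to the class rigidity preset
#'   (1 keeps the defaults).
#' @param rigidity_cv log-scale SD of the between-fillet rigidity jitter.
#' @return a [fillet_profile()].
#' @export
make_fillet_profile <- function(class_label, seed, taper = 0.45,
                                rigidity_base = 1, rigidity_cv = 0.3) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% names(.fillet_presets)) {
    stop_invalid("`class_label` must be one of 'normal', 'moderate', 'severe'")
  }
  ps <- .fillet_presets[[class_label]]
  with_seed(seed, {
    len <- max(50, round(stats::rnorm(1, ps$length_mean, ps$length_sd)))
    hgt <- max(10, round(stats::rnorm(1, ps$height_mean, ps$height_sd)))
    rig <- ps$rigidity * rigidity_base * exp(stats::rnorm(1, 0, rigidity_cv))
    fillet_profile(len, hgt, taper = taper, rigidity = rig)
  })
}
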