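# Scene geometry and trigger-line configuration.
#
# Image coordinates are matrix coordinates: row 1 is the image top and row
# indices increase downward. Continuous positions use edge-based coordinates
# in which pixel (i, j) occupies the unit square [i-1, i] x [j-1, j] and has
# its center at (i - 0.5, j - 0.5). The belt surface is the lower edge of
# `belt_row` (continuous row coordinate `belt_row`), and the roller axle
# center sits exactly `roller_radius` below it at the roller edge column.

#' Scene geometry of the conveyor discharge edge
#'
#' Describes the imaged scene: raster dimensions, the belt surface row, the
#' column of the roller (discharge) edge, the roller radius `R`, the fixed
#' reference point at the roller axle center, the two trigger-line positions
#' and the belt speed in pixels per frame.
#'
#' @param image_w,image_h raster width and height in pixels.
#' @param belt_row row index of the belt surface (fillets rest on rows
#'   `<= belt_row`, their bottom pixel row being `belt_row`).
#' @param edge_col column index of the roller edge; material in columns
#'   beyond it is unsupported.
#' @param roller_radius roller radius `R` in pixels. The reference point
#'   (axle center) is at continuous position `(belt_row + R, edge_col)`.
#' @param arrival_col column of the vertical arrival trigger line; must lie
#'   upstream (left) of `edge_col`.
#' @param departure_row row of the horizontal departure trigger line; must
#'   lie below `belt_row`.
#' @param line_speed belt translation in pixels per frame.
#' @param frame_rate nominal acquisition rate in frames per second.
#' @return an object of class `scene_geometry`.
#' @examples
#' geom <- scene_geometry()
#' geom$reference_point
#' @export
scene_geometry <- function(image_w = 960, image_h = 696,
                           belt_row = 300, edge_col = 600,
                           roller_radius = 55,
                           arrival_col = 420, departure_row = 550,
                           line_speed = 6, frame_rate = 200) {
  for (nm in c("image_w", "image_h", "belt_row", "edge_col", "arrival_col",
               "departure_row")) {
    v <- get(nm)
    if (!is_count(v)) stop_invalid(sprintf("`%s` must be a positive integer", nm))
  }
  if (!is_number(roller_radius) || roller_radius <= 0) {
    stop_invalid("`roller_radius` must be a positive number")
  }
  if (!is_number(line_speed) || line_speed <= 0) {
    stop_invalid("`line_speed` must be a positive number")
  }
  if (!is_number(frame_rate) || frame_rate <= 0) {
    stop_invalid("`frame_rate` must be a positive number")
  }
  if (arrival_col >= edge_col) stop_invalid("`arrival_col` must be < `edge_col`")
  if (departure_row <= belt_row) stop_invalid("`departure_row` must be > `belt_row`")
  if (belt_row >= image_h || edge_col > image_w || departure_row > image_h) {
    stop_invalid("scene landmarks must lie inside the image raster")
  }
  structure(list(
    image_w = as.integer(image_w), image_h = as.integer(image_h),
    belt_row = as.integer(belt_row), edge_col = as.integer(edge_col),
    roller_radius = roller_radius,
    reference_point = c(row = belt_row + roller_radius, col = edge_col),
    arrival_col = as.integer(arrival_col),
    departure_row = as.integer(departure_row),
    line_speed = line_speed, frame_rate = frame_rate
  ), class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat("Scene geometry:", x$image_w, "x", x$image_h, "px\n")
  cat("  belt row", x$belt_row, "| edge col", x$edge_col,
      "| roller R", x$roller_radius, "px\n")
  cat("  reference point (axle center): row", x$reference_point[["row"]],
      ", col", x$reference_point[["col"]], "\n")
  cat("  trigger lines: arrival col", x$arrival_col,
      ", departure row", x$departure_row, "\n")
  cat("  line speed", x$line_speed, "px/frame @", x$frame_rate, "fps\n")
  invisible(x)
}

#' Trigger-line configuration for software motion sensing
#'
#' @param arrival_col column index of the one-pixel-wide vertical arrival
#'   trigger line.
#' @param departure_row row index of the horizontal departure trigger line.
#' @param intensity_threshold 8-bit intensity above which a pixel counts as
#'   active on a trigger line.
#' @param min_active_pixels minimum number of active pixels on a line for the
#'   trigger to fire.
#' @param debounce_frames number of consecutive frames a trigger condition
#'   must hold before it is accepted (noise robustness).
#' @return an object of class `trigger_config`.
#' @seealso [as_trigger_config()] to derive one from a [scene_geometry()].
#' @export
trigger_config <- function(arrival_col, departure_row,
                           intensity_threshold = 60,
                           min_active_pixels = 5,
                           debounce_frames = 2) {
  if (!is_count(arrival_col)) stop_invalid("`arrival_col` must be a positive integer")
  if (!is_count(departure_row)) stop_invalid("`departure_row` must be a positive integer")
  if (!is_number(intensity_threshold) || intensity_threshold < 0 ||
      intensity_threshold > 255) {
    stop_invalid("`intensity_threshold` must be in [0, 255]")
  }
  if (!is_count(min_active_pixels)) {
    stop_invalid("`min_active_pixels` must be >= 1")
  }
  if (!is_count(debounce_frames)) stop_invalid("`debounce_frames` must be >= 1")
  structure(list(
    arrival_col = as.integer(arrival_col),
    departure_row = as.integer(departure_row),
    intensity_threshold = intensity_threshold,
    min_active_pixels = as.integer(min_active_pixels),
    debounce_frames = as.integer(debounce_frames)
  ), class = "trigger_config")
}

#' @rdname trigger_config
#' @param geom a [scene_geometry()].
#' @param ... further arguments passed to [trigger_config()].
#' @export
as_trigger_config <- function(geom, ...) {
  stopifnot(inherits(geom, "scene_geometry"))
  trigger_config(arrival_col = geom$arrival_col,
                 departure_row = geom$departure_row, ...)
}

#' Read and write scene geometry as YAML
#'
#' The geometry (and optionally trigger parameters) is serialized as a plain
#' YAML mapping so a scene set up once can be reused across runs.
#'
#' @param geom a [scene_geometry()].
#' @param path file path.
#' @return `read_scene_geometry()` returns a [scene_geometry()];
#'   `write_scene_geometry()` returns `path` invisibly.
#' @export
write_scene_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "scene_geometry"))
  fields <- geom[c("image_w", "image_h", "belt_row", "edge_col",
                   "roller_radius", "arrival_col", "departure_row",
                   "line_speed", "frame_rate")]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_scene_geometry
#' @export
read_scene_geometry <- function(path) {
  if (!file.exists(path)) stop_not_found(paste("no such file:", path))
  fields <- yaml::read_yaml(path)
  needed <- c("image_w", "image_h", "belt_row", "edge_col", "roller_radius",
              "arrival_col", "departure_row", "line_speed", "frame_rate")
  missing <- setdiff(needed, names(fields))
  if (length(missing)) {
    stop_format(paste("geometry file lacks fields:",
                      paste(missing, collapse = ", ")))
  }
  do.call(scene_geometry, fields[needed])
}
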