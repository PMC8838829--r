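# Software motion sensing: two trigger lines (one image column, one image
# row) emulate the optical sensors that delimit the tracking window of a
# fillet pass. A trigger fires when enough pixels on its line exceed the
# intensity threshold, and must hold for `debounce_frames` consecutive
# frames before being accepted.

.line_active <- function(values, cfg) {
  sum(values > cfg$intensity_threshold) >= cfg$min_active_pixels
}

#' Trigger-line tests on a single frame
#'
#' `arrival_triggered()` tests the vertical arrival line (a one-pixel-wide
#' image column); `departure_triggered()` tests the horizontal departure line
#' (an image row crossed by the fillet as it falls out of the field of view).
#'
#' @param frame an 8-bit grayscale matrix.
#' @param cfg a [trigger_config()].
#' @return `TRUE` if at least `min_active_pixels` pixels on the line exceed
#'   `intensity_threshold`.
#' @export
arrival_triggered <- function(frame, cfg) {
  stopifnot(inherits(cfg, "trigger_config"), is.matrix(frame))
  if (cfg$arrival_col > ncol(frame)) {
    stop_invalid("arrival trigger column lies outside the frame")
  }
  .line_active(frame[, cfg$arrival_col], cfg)
}

#' @rdname arrival_triggered
#' @export
departure_triggered <- function(frame, cfg) {
  stopifnot(inherits(cfg, "trigger_config"), is.matrix(frame))
  if (cfg$departure_row > nrow(frame)) {
    stop_invalid("departure trigger row lies outside the frame")
  }
  .line_active(frame[cfg$departure_row, ], cfg)
}

# First index at which `flags` holds for `n` consecutive frames, or NA.
.debounced_first <- function(flags, n) {
  if (n == 1L) return(which(flags)[1])
  run <- stats::filter(as.numeric(flags), rep(1, n), sides = 1)
  hit <- which(!is.na(run) & run == n)
  if (!length(hit)) return(NA_integer_)
  hit[1] - n + 1L
}

#' Delimit the tracking window of a single fillet pass
#'
#' The window starts at the first (debounced) arrival-trigger frame and ends
#' at the first (debounced) departure-trigger frame after it. If the
#' departure line never fires, the window ends at the last frame on which a
#' bright object is still present anywhere in the frame. Sequences are
#' assumed to contain at most one fillet (single-file presentation with a
#' spatial gap).
#'
#' @param seq a [frame_sequence()].
#' @param cfg a [trigger_config()].
#' @return an object of class `tracking_window` with `start_frame`,
#'   `end_frame` (both inclusive, `start_frame < end_frame`) and
#'   `sequence_id`.
#' @export
delimit_window <- function(seq, cfg) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(cfg, "trigger_config"))
  frames <- seq$frames
  arr <- vapply(frames, arrival_triggered, logical(1), cfg = cfg)
  start <- .debounced_first(arr, cfg$debounce_frames)
  if (is.na(start)) {
    stop_no_object("no fillet reached the arrival trigger line")
  }
  dep <- vapply(frames, departure_triggered, logical(1), cfg = cfg)
  dep[seq_len(start)] <- FALSE
  end <- .debounced_first(dep, cfg$debounce_frames)
  if (is.na(end)) {
    present <- vapply(frames, function(f)
      sum(f > cfg$intensity_threshold) >= cfg$min_active_pixels, logical(1))
    end <- max(which(present))
  }
  if (end <= start) end <- min(start + 1L, length(frames))
  structure(list(start_frame = as.integer(start), end_frame = as.integer(end),
                 sequence_id = seq$source_id),
            class = "tracking_window")
}

#' @export
print.tracking_window <- function(x, ...) {
  cat("Tracking window: frames", x$start_frame, "-", x$end_frame,
      if (nzchar(x$sequence_id)) paste0("(", x$sequence_id, ")") else "", "\n")
  invisible(x)
}
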