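# Per-fillet feature extraction: the ten sideview image features plus label.
#
# MAXH, AVGH, MAXL, AREA, PERIM, HTR, HBR come from the first tracking-window
# frame (fillet flat on the belt); MDM/NMDM from the distance trace and MBE
# from the bending-energy trace over the whole window.

#' Extract the sideview feature vector for one fillet pass
#'
#' Delimits the tracking window with the software motion sensor, segments
#' every window frame, and assembles the per-fillet features: first-frame
#' size/shape features (`MAXH`, `AVGH`, `MAXL`, `AREA`, `PERIM`, `HTR`,
#' `HBR`), the distance minima (`MDM`, `NMDM`) and the maximum bending
#' energy (`MBE`). Window frames where segmentation finds no object are
#' skipped with a warning.
#'
#' @param seq a [frame_sequence()] or [simulate_pass()] result containing
#'   exactly one fillet pass.
#' @param geom a [scene_geometry()].
#' @param params a [seg_params()].
#' @param trigger a [trigger_config()]; defaults to the geometry's trigger
#'   lines via [as_trigger_config()].
#' @param id row identifier placed in the `id` column.
#' @return a one-row data frame with columns `id`, the ten features, and
#'   `label` (from the pass metadata when available, otherwise `NA`).
#' @export
extract_features <- function(seq, geom, params = seg_params(),
                             trigger = NULL, id = NULL) {
  label <- NA_character_
  if (inherits(seq, "simulated_pass")) {
    label <- seq$label
    seq <- seq$frames
  }
  stopifnot(inherits(seq, "frame_sequence"), inherits(geom, "scene_geometry"))
  if (is.null(trigger)) trigger <- as_trigger_config(geom)
  win <- delimit_window(seq, trigger)
  idx <- win$start_frame:win$end_frame
  segs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    segs[[k]] <- tryCatch(segment_fillet(seq$frames[[idx[k]]], params),
                          fb_no_object = function(e) NULL)
  }
  n_missed <- sum(vapply(segs, is.null, logical(1)))
  if (n_missed == length(segs)) {
    stop_no_object("segmentation failed on every frame in the tracking window")
  }
  if (n_missed > 0L) {
    warning(sprintf("segmentation failed on %d of %d window frames",
                    n_missed, length(segs)))
  }
  first <- segs[[which(!vapply(segs, is.null, logical(1)))[1]]]
  hf <- height_features(first)
  sf <- alt_scale_factors(first, geom$roller_radius)
  dt <- run_distance_trace(segs, geom)
  bt <- suppressWarnings(max_bending_energy(segs))
  data.frame(
    id = if (is.null(id)) seq$source_id else as.character(id),
    NMDM = dt$NMDM,
    MDM = dt$MDM,
    MBE = bt$MBE,
    MAXH = first$max_height,
    AVGH = first$avg_height,
    MAXL = first$length,
    AREA = first$area,
    PERIM = first$perimeter,
    HTR = sf[["HTR"]],
    HBR = sf[["HBR"]],
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Batch-process a cohort of passes into a feature table
#'
#' @param passes list of [frame_sequence()] or [simulate_pass()] objects.
#' @param geom a [scene_geometry()].
#' @param params a [seg_params()].
#' @param ... further arguments passed to [extract_features()].
#' @return a data frame with one row per successfully processed pass.
#'   Failures are reported as warnings, not silently dropped; if every pass
#'   fails an error is raised.
#' @export
process_cohort <- function(passes, geom, params = seg_params(), ...) {
  if (!is.list(passes) || !length(passes)) {
    stop_invalid("`passes` must be a non-empty list")
  }
  rows <- vector("list", length(passes))
  failures <- character()
  for (i in seq_along(passes)) {
    rows[[i]] <- tryCatch(
      extract_features(passes[[i]], geom, params, id = i, ...),
      filletbend_error = function(e) {
        failures <<- c(failures, sprintf("pass %d: %s", i, conditionMessage(e)))
        NULL
      })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop_empty_out(paste("all passes failed:",
                         paste(failures, collapse = "; ")))
  }
  if (length(failures)) {
    warning(paste("some passes failed:", paste(failures, collapse = "; ")))
  }
  do.call(rbind, rows)
}

#' Simulate a balanced cohort and extract its feature table
#'
#' Streams `n_per_class` simulated passes per severity class through feature
#' extraction one at a time (full-resolution passes are large, so they are
#' discarded as soon as their feature row is computed). Pass seeds derive
#' reproducibly from `master_seed` with the same schedule as
#' [generate_cohort()].
#'
#' @param n_per_class fillets per severity class.
#' @param geom a [scene_geometry()].
#' @param master_seed integer master seed.
#' @param params a [seg_params()].
#' @param noise_sd pixel noise SD passed to [simulate_pass()].
#' @param profile_fun function `(class_label, seed)` drawing a
#'   [fillet_profile()]; defaults to [make_fillet_profile()].
#' @param quiet suppress per-pass progress messages.
#' @return a feature table data frame with `3 * n_per_class` rows.
#' @export
cohort_feature_table <- function(n_per_class, geom = scene_geometry(),
                                 master_seed = 1, params = seg_params(),
                                 noise_sd = 4,
                                 profile_fun = make_fillet_profile,
                                 quiet = TRUE) {
  plan <- cohort_plan(n_per_class, master_seed)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (!quiet) message("simulating pass ", plan$id[i])
    prof <- profile_fun(plan$label[i], seed = plan$profile_seed[i])
    pass <- simulate_pass(prof, geom, seed = plan$pass_seed[i],
                          label = plan$label[i], noise_sd = noise_sd)
    rows[[i]] <- extract_features(pass, geom, params, id = plan$id[i])
    rm(pass)
  }
  do.call(rbind, rows)
}
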