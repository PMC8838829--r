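# Reading and writing frame sequences, masks and per-fillet feature tables.

#' Frame sequence container
#'
#' An ordered list of equally sized 8-bit grayscale rasters (integer matrices
#' with values 0-255) belonging to one fillet pass.
#'
#' @param frames list of integer matrices, all with identical dimensions.
#' @param frame_rate acquisition rate in frames per second.
#' @param source_id free-form identifier of the sequence origin.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 200, source_id = "") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_invalid("`frames` must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop_format("all frames must be matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("all frames must share identical dimensions")
  }
  if (!is_number(frame_rate) || frame_rate <= 0) {
    stop_invalid("`frame_rate` must be > 0")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 source_id = as.character(source_id)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Frame sequence:", length(x$frames), "frames of", d[1], "x", d[2],
      "px @", x$frame_rate, "fps", if (nzchar(x$source_id))
        paste0("(", x$source_id, ")") else "", "\n")
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

.luma <- c(0.299, 0.587, 0.114)

# PNG/TIFF pixel arrays arrive in [0, 1]; convert to 8-bit integer grayscale.
.to_gray8 <- function(a) {
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc >= 3L) {
      a <- .luma[1] * a[, , 1] + .luma[2] * a[, , 2] + .luma[3] * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Read a frame sequence from a PNG stack or multi-page TIFF
#'
#' A directory is read as a stack of grayscale or RGB PNG files ordered by
#' file name (the order [write_frame_sequence()] produces); a `.tif`/`.tiff`
#' path is read as a multi-page TIFF ordered by page. RGB input is converted
#' to grayscale with luminance weights 0.299/0.587/0.114.
#'
#' @param path directory of PNG frames or a multi-page TIFF file.
#' @param frame_rate frames per second recorded on the returned sequence;
#'   if `path` is a directory containing a `meta.yaml` written by
#'   [write_frame_sequence()], the stored rate takes precedence.
#' @return a [frame_sequence()].
#' @export
read_frame_sequence <- function(path, frame_rate = 200) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop_not_found(paste("no PNG frames under", path))
    frames <- lapply(files, function(f) .to_gray8(png::readPNG(f)))
    source_id <- basename(path)
    meta_path <- file.path(path, "meta.yaml")
    if (file.exists(meta_path)) {
      meta <- yaml::read_yaml(meta_path)
      if (!is.null(meta$frame_rate)) frame_rate <- meta$frame_rate
      if (!is.null(meta$source_id)) source_id <- meta$source_id
    }
    return(frame_sequence(frames, frame_rate = frame_rate,
                          source_id = source_id))
  }
  if (!file.exists(path)) stop_not_found(paste("no such path:", path))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop_format("`path` must be a directory of PNGs or a .tif/.tiff file")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, .to_gray8)
  frame_sequence(frames, frame_rate = frame_rate, source_id = basename(path))
}

#' Write a frame sequence (and optional masks) as a PNG stack
#'
#' Frames are written as zero-padded `frame_0001.png, ...` 8-bit grayscale
#' files; optional ground-truth masks go to a parallel `masks/` stack and
#' sequence metadata to `meta.yaml`.
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if needed).
#' @param masks optional list of logical matrices, same length as `seq`.
#' @param meta named list of additional metadata stored in `meta.yaml`
#'   (e.g. label, seed).
#' @return `dir`, invisibly.
#' @export
write_frame_sequence <- function(seq, dir, masks = NULL, meta = list()) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  if (!is.null(masks)) {
    if (length(masks) != length(seq$frames)) {
      stop_invalid("`masks` must match the number of frames")
    }
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(masks)) {
      png::writePNG(masks[[i]] * 1,
                    file.path(mdir, sprintf("mask_%04d.png", i)))
    }
  }
  meta <- c(list(frame_rate = seq$frame_rate, source_id = seq$source_id,
                 n_frames = length(seq$frames)), meta)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Write a simulated pass to disk
#'
#' Writes frames, ground-truth masks and a `meta.yaml` carrying the label,
#' seeds and trigger ground truth, so a pass can be re-read with
#' [read_frame_sequence()] and processed like acquired data.
#'
#' @param pass a [simulate_pass()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pass <- function(pass, dir) {
  stopifnot(inherits(pass, "simulated_pass"))
  write_frame_sequence(pass$frames, dir, masks = pass$truth_masks,
                       meta = list(label = pass$label, seed = pass$seed,
                                   rigidity = pass$rigidity_used,
                                   truth_arrival_frame = pass$truth_arrival_frame,
                                   truth_departure_frame = pass$truth_departure_frame))
}

.feature_cols <- c("NMDM", "MDM", "MBE", "MAXH", "AVGH", "MAXL",
                   "AREA", "PERIM", "HTR", "HBR")

#' Read and write per-fillet feature tables as CSV
#'
#' The on-disk dialect is a comma-separated UTF-8 file with a header row and
#' '.' decimals; columns are `id`, the ten image features (`NMDM`, `MDM`,
#' `MBE`, `MAXH`, `AVGH`, `MAXL`, `AREA`, `PERIM`, `HTR`, `HBR`) and `label`.
#'
#' @param table a data frame with the feature columns.
#' @param path CSV file path.
#' @return `read_feature_table()` returns a data frame (with a warning and
#'   zero rows for a header-only file); `write_feature_table()` returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_invalid("`table` must be a non-empty data frame")
  }
  keep <- intersect(c("id", .feature_cols, "label"), names(table))
  utils::write.csv(table[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_not_found(paste("no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), c("id", .feature_cols, "label"))
  if (length(unknown)) {
    stop_format(paste("unknown feature-table column(s):",
                      paste(unknown, collapse = ", ")))
  }
  if (nrow(tab) == 0L) {
    warning("feature table file has a header but no rows")
    return(tab)
  }
  num <- intersect(.feature_cols, names(tab))
  if (anyNA(tab[num])) stop_format("missing values in feature columns")
  tab
}
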