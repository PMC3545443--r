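# Calibrated image stacks and tabular output.

#' Acquisition calibration
#'
#' @param fps acquisition rate, frames per second (e.g. 250 gives a
#'   temporal resolution of 4 ms per frame).
#' @param um_per_px spatial calibration, micrometers per pixel.
#' @return a `fw_calibration` object.
#' @export
calibration <- function(fps, um_per_px) {
  check_num(fps, "fps", positive = TRUE)
  check_num(um_per_px, "um_per_px", positive = TRUE)
  structure(list(fps = fps, um_per_px = um_per_px),
            class = "fw_calibration")
}

#' @export
print.fw_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g fps (%.3g ms/frame), %g um/px\n",
              x$fps, 1000 / x$fps, x$um_per_px))
  invisible(x)
}

#' Build a frame stack from matrices in memory
#'
#' Frames are grayscale intensity matrices normalized to `[0, 1]`,
#' indexed 0-based; frame `i` is stamped at `i * 1000 / fps` ms.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param calibration a [calibration()] object.
#' @return a `fw_frame_stack` object.
#' @export
frame_stack <- function(frames, calibration) {
  if (!inherits(calibration, "fw_calibration"))
    stop_fg("'calibration' must be a calibration() object")
  if (!is.list(frames) || !length(frames))
    stop_fg("'frames' must be a non-empty list of matrices")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L || is.null(dims[[1]]))
    stop_fg("all frames must be matrices of identical shape")
  structure(list(frames = frames, calibration = calibration,
                 n = length(frames), dim = dims[[1]]),
            class = "fw_frame_stack")
}

#' @export
print.fw_frame_stack <- function(x, ...) {
  cat(sprintf("<frame stack> %d frames of %d x %d px, %g fps, %g um/px\n",
              x$n, x$dim[1], x$dim[2], x$calibration$fps,
              x$calibration$um_per_px))
  invisible(x)
}

#' Timestamps of the frames in a stack (ms)
#' @param stack a `fw_frame_stack`.
#' @return numeric vector, `0, 1000/fps, 2000/fps, ...`.
#' @export
frame_times_ms <- function(stack) {
  (seq_len(stack$n) - 1) * 1000 / stack$calibration$fps
}

numeric_file_order <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  num <- suppressWarnings(as.numeric(
    sub(".*?(\\d+)\\D*$", "\\1", base)))
  if (anyNA(num)) order(base) else order(num, base)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    tif = , tiff = read_tiff(path),
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of gray RGB
      m
    },
    stop_fg("unsupported image format '%s' (%s)", ext, path)),
    error = function(e)
      stop_fg("could not read frame file '%s': %s", path,
              conditionMessage(e)))
  img
}

#' Load a calibrated image sequence
#'
#' `path` may be a directory of numbered TIFF/PNG frames (sorted by
#' the numeric part of the file name, not lexicographically) or a
#' single multi-page TIFF.  Intensities are normalized to `[0, 1]`.
#'
#' @param path directory of frames or a multi-page TIFF file.
#' @param calibration a [calibration()] object.
#' @return a `fw_frame_stack`.
#' @export
load_image_sequence <- function(path, calibration) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop_fg("no image frames found in '%s'", path)
    files <- files[numeric_file_order(files)]
    frames <- lapply(files, function(f) {
      img <- read_frame_file(f)
      if (is.list(img)) stop_fg(
        "'%s' is multi-page; use a single multi-page file, not a directory of them", f)
      img
    })
  } else if (file.exists(path)) {
    img <- read_tiff(path)
    frames <- if (is.list(img)) img else list(img)
  } else stop_fg("'%s' does not exist", path)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop_fg("frames in '%s' have mixed shapes", path)
  frame_stack(frames, calibration)
}

#' Write a frame stack as numbered 16-bit TIFF files
#'
#' @param stack a `fw_frame_stack`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are `<prefix>_<000i>.tif`.
#' @return character vector of written paths, invisibly.
#' @export
write_image_sequence <- function(stack, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  width <- max(4L, nchar(as.character(stack$n - 1L)))
  paths <- file.path(dir, sprintf("%s_%0*d.tif", prefix, width,
                                  seq_len(stack$n) - 1L))
  for (i in seq_len(stack$n)) write_tiff(stack$frames[[i]], paths[i])
  invisible(paths)
}

# tabular output -------------------------------------------------------

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the full analysis result set to disk
#'
#' Produces the spreadsheet-style outputs of an analysis run:
#' `steps.csv` (one row per stance event), `params.csv` (per-video
#' scalars), `gaitmap.csv` (per-frame combination code, class and gait
#' index), `combinations.csv` (combination frequency table),
#' `stance_traces.csv` and `summary.json`.  All values round-trip
#' losslessly through `utils::read.csv()` / `jsonlite::read_json()`.
#'
#' @param results an analysis result list as produced by
#'   [analyze_tracked()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_fg("cannot create output directory '%s'", out_dir)
  paths <- c(steps = file.path(out_dir, "steps.csv"),
             params = file.path(out_dir, "params.csv"),
             gaitmap = file.path(out_dir, "gaitmap.csv"),
             combinations = file.path(out_dir, "combinations.csv"),
             stance_traces = file.path(out_dir, "stance_traces.csv"),
             summary = file.path(out_dir, "summary.json"))
  write_csv_plain(results$steps, paths["steps"])
  write_csv_plain(results$params, paths["params"])
  write_csv_plain(results$gaitmap, paths["gaitmap"])
  write_csv_plain(results$combinations, paths["combinations"])
  write_csv_plain(results$stance_traces, paths["stance_traces"])
  jsonlite::write_json(results$summary, paths["summary"],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(paths)
}
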