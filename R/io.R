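#' Gaze recording container
#'
#' A single trial's raw gaze sample stream. Samples are stored as a
#' data frame with columns `time_ms`, `x_px`, `y_px`, `valid`; timestamps
#' must be strictly increasing. Invalid (blink) samples are flagged, never
#' dropped, so downstream stages can account for them.
#'
#' @param samples Data frame with columns `time_ms`, `x_px`, `y_px`, `valid`.
#' @param sample_rate_hz Nominal sampling rate (default 1000).
#' @param trial_id Optional trial identifier carried along for reporting.
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, sample_rate_hz = 1000, trial_id = NA) {
  need <- c("time_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  samples <- samples[order(samples$time_ms), need, drop = FALSE]
  if (nrow(samples) > 1 && any(diff(samples$time_ms) <= 0)) {
    stop(sprintf("non-monotone timestamps in trial '%s'", trial_id))
  }
  samples$valid <- as.logical(samples$valid)
  structure(list(samples = samples,
                 sample_rate_hz = sample_rate_hz,
                 trial_id = trial_id),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("gaze_recording '%s': %d samples at %g Hz, %.1f%% valid\n",
              x$trial_id, nrow(x$samples), x$sample_rate_hz,
              100 * mean(x$samples$valid)))
  invisible(x)
}

#' Column mapping for gaze tables
#'
#' Names the columns of a delimited gaze file. The canonical dialect is
#' comma-separated with a header, times in milliseconds, one file per
#' session, with a trial-id column.
#'
#' @param time,x,y,valid,trial Column names in the file.
#' @return A named list usable as the `schema` of [parse_gaze_table()].
#' @export
gaze_schema <- function(time = "time_ms", x = "x_px", y = "y_px",
                        valid = "valid", trial = "trial_id") {
  list(time = time, x = x, y = y, valid = valid, trial = trial)
}

#' Parse a delimited gaze table into per-trial recordings
#'
#' Reads a CSV of raw samples and splits it into one [gaze_recording()] per
#' trial id. Every input row is either assigned to a trial or reported as
#' discarded with a reason; the row count is conserved.
#'
#' @param path CSV file of gaze samples.
#' @param schema Column mapping from [gaze_schema()].
#' @param sample_rate_hz Nominal sampling rate recorded on each trial.
#'
#' @return A named list of `gaze_recording` objects (one per trial id, in
#'   order of first appearance), with attribute `"discarded"` holding a data
#'   frame of dropped rows and reasons (empty when none).
#' @export
parse_gaze_table <- function(path, schema = gaze_schema(),
                             sample_rate_hz = 1000) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(schema), names(tab))
  if (length(missing_cols)) {
    stop("gaze table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(time_ms = as.numeric(tab[[schema$time]]),
                   x_px = as.numeric(tab[[schema$x]]),
                   y_px = as.numeric(tab[[schema$y]]),
                   valid = as.logical(tab[[schema$valid]]),
                   trial = as.character(tab[[schema$trial]]),
                   stringsAsFactors = FALSE)
  drop <- is.na(df$trial) | is.na(df$time_ms)
  discarded <- data.frame(row = which(drop),
                          reason = rep("missing trial id or timestamp",
                                       sum(drop)))
  keep <- df[!drop, , drop = FALSE]
  ids <- unique(keep$trial)
  recs <- lapply(ids, function(id) {
    sub <- keep[keep$trial == id, c("time_ms", "x_px", "y_px", "valid")]
    sub <- sub[order(sub$time_ms), , drop = FALSE]
    if (anyDuplicated(sub$time_ms)) {
      stop(sprintf("gaze table data error: duplicated timestamp in trial '%s'", id))
    }
    gaze_recording(sub, sample_rate_hz = sample_rate_hz, trial_id = id)
  })
  names(recs) <- ids
  attr(recs, "discarded") <- discarded
  recs
}

#' Write per-trial recordings back to the canonical gaze CSV dialect
#'
#' @param recordings List of [gaze_recording()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  rows <- do.call(rbind, lapply(recordings, function(r) {
    cbind(r$samples, trial_id = r$trial_id)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scene image (PNG or JPEG)
#'
#' @param path Image file; format chosen by extension.
#' @return A `height x width x 3` array of values in `[0, 1]`.
#' @export
read_scene_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a scene image as PNG
#'
#' @param image `height x width x 3` array in `[0, 1]` (or a matrix, written
#'   as grayscale).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Reference colors for mask categories; sidecar color tables default to these.
roi_mask_colors <- function() {
  c(head = "#FF0000", body = "#FF00FF")
}

#' Write social ROI masks as a color-coded PNG with a sidecar color table
#'
#' Each category is painted in its own color on black background; the
#' color table (CSV: `color,category`) accompanies the image so readers do
#' not rely on hard-coded colors.
#'
#' @param masks Named list of logical matrices (e.g. `head`, `body`), all of
#'   identical dimensions. Overlaps are resolved in list order (first wins).
#' @param path Output PNG path; the color table is written to
#'   `<path>.colors.csv` unless `color_table_path` is given.
#' @param color_table_path Optional explicit path for the color table CSV.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(masks, path, color_table_path = NULL) {
  stopifnot(length(masks) >= 1)
  dm <- dim(masks[[1]])
  cols <- roi_mask_colors()
  extra <- setdiff(names(masks), names(cols))
  if (length(extra)) {
    pal <- grDevices::rainbow(length(extra))
    names(pal) <- extra
    cols <- c(cols, pal)
  }
  img <- array(0, c(dm, 3))
  taken <- matrix(FALSE, dm[1], dm[2])
  for (nm in names(masks)) {
    m <- masks[[nm]] & !taken
    rgb <- grDevices::col2rgb(cols[[nm]]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- rgb[ch]
      img[, , ch] <- plane
    }
    taken <- taken | m
  }
  png::writePNG(img, path)
  ctp <- if (is.null(color_table_path)) paste0(path, ".colors.csv") else color_table_path
  utils::write.csv(data.frame(color = unname(cols[names(masks)]),
                              category = names(masks)),
                   ctp, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a color-coded ROI mask PNG with its color table
#'
#' @param path Mask PNG.
#' @param color_table_path Color table CSV (`color,category`); defaults to
#'   `<path>.colors.csv`.
#' @param tol Per-channel color matching tolerance (8-bit PNG quantisation).
#' @return Named list of logical matrices, one per category in the table.
#'   Non-background pixels matching no table color raise a mask error.
#' @export
read_roi_mask <- function(path, color_table_path = NULL, tol = 2 / 255) {
  ctp <- if (is.null(color_table_path)) paste0(path, ".colors.csv") else color_table_path
  if (!file.exists(ctp)) stop("mask color table not found: ", ctp)
  ct <- utils::read.csv(ctp, stringsAsFactors = FALSE)
  img <- read_scene_image(path)
  out <- list()
  matched <- matrix(FALSE, dim(img)[1], dim(img)[2])
  for (i in seq_len(nrow(ct))) {
    rgb <- grDevices::col2rgb(ct$color[i]) / 255
    m <- abs(img[, , 1] - rgb[1]) <= tol &
      abs(img[, , 2] - rgb[2]) <= tol &
      abs(img[, , 3] - rgb[3]) <= tol
    out[[ct$category[i]]] <- m
    matched <- matched | m
  }
  background <- img[, , 1] <= tol & img[, , 2] <= tol & img[, , 3] <= tol
  if (any(!matched & !background)) {
    stop("mask error: mask contains colors not present in the color table")
  }
  out
}

#' Construct validated trial metadata
#'
#' @param subject_id,stimulus_id Opaque labels.
#' @param task One of `"free"`, `"define"`, `"count"`, `"estimate"`.
#' @param category `"social"` or `"nonsocial"`.
#' @param stimulus_onset_ms Stimulus onset time (ms, recording clock).
#' @param click_time_ms First mouse click time, or `NA` when no response was
#'   given. Must lie within the presentation window when present.
#' @param cross_position_px Length-2 (x, y) position of the pre-stimulus
#'   fixation cross; defaults to the center of the reference 1200 x 900 scene.
#' @param presentation_ms Stimulus duration (default 10000 ms).
#'
#' @return A one-row data frame of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, stimulus_id, task, category,
                       stimulus_onset_ms, click_time_ms = NA,
                       cross_position_px = c(599.5, 449.5),
                       presentation_ms = 10000) {
  task <- match.arg(task, c("free", "define", "count", "estimate"))
  category <- match.arg(category, c("social", "nonsocial"))
  if (!is.na(click_time_ms) &&
      (click_time_ms < stimulus_onset_ms ||
       click_time_ms > stimulus_onset_ms + presentation_ms)) {
    stop("click_time_ms outside the presentation window")
  }
  out <- data.frame(subject_id = as.character(subject_id),
                    stimulus_id = as.character(stimulus_id),
                    task = task, category = category,
                    stimulus_onset_ms = stimulus_onset_ms,
                    click_time_ms = click_time_ms,
                    cross_x_px = cross_position_px[1],
                    cross_y_px = cross_position_px[2],
                    presentation_ms = presentation_ms,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_meta", "data.frame")
  out
}
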