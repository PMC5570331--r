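#' Relative and area-normalized ROI fixation density
#'
#' The raw score of an ROI is its share of the scene's total fixation
#' density; the area-normalized score divides that share by the ROI's share
#' of the image area, so a score of 1 means "viewed exactly as much as its
#' size predicts". Raw proportions over the full partition sum to 1.
#'
#' @param map A [build_density_map()] result (or plain matrix).
#' @param roiset A [build_roiset()] result, or a character label matrix
#'   (e.g. from [split_social_by_saliency()]).
#' @param categories Categories to report; defaults to all categories of the
#'   partition.
#' @return Data frame with `roi`, `raw` (density proportion) and
#'   `normalized`. All-zero maps and empty ROIs yield `NA` (missing, not
#'   zero).
#' @export
roi_density_score <- function(map, roiset, categories = NULL) {
  vals <- if (inherits(map, "density_map")) map$values else map
  lab <- if (inherits(roiset, "roi_set")) roiset$labels else roiset
  if (is.null(categories)) {
    categories <- if (inherits(roiset, "roi_set")) roi_categories()
                  else sort(unique(as.vector(lab)))
  }
  stopifnot(all(dim(vals) == dim(lab)))
  total <- sum(vals)
  npix <- length(vals)
  has_idx <- inherits(roiset, "roi_set") &&
    all(categories %in% names(roiset$idx))
  raw <- vapply(categories, function(cat) {
    idx <- if (has_idx) roiset$idx[[cat]] else which(lab == cat)
    if (total == 0 || !length(idx)) NA_real_ else sum(vals[idx]) / total
  }, numeric(1))
  area <- vapply(categories, function(cat) {
    if (has_idx) length(roiset$idx[[cat]]) else sum(lab == cat)
  }, numeric(1))
  fast_df(roi = categories, raw = unname(raw),
          normalized = unname(ifelse(area > 0, raw / (area / npix),
                                     NA_real_)))
}

#' Area-normalized fixation-count proportions
#'
#' Like [roi_density_score()] but weighting every fixation equally (count
#' instead of duration, no smoothing). Each fixation is classified by the
#' ROI label at its rounded pixel position; off-image fixations are
#' excluded from numerator and denominator.
#'
#' @param fixations Corrected fixation data frame.
#' @param roiset A `roi_set` or character label matrix.
#' @param categories Categories to report (default: all of the partition).
#' @param discard_first Drop the first supplied fixation (default `FALSE`,
#'   assuming trial-level discarding already happened).
#' @return Data frame with `roi`, `raw` (count proportion), `normalized`.
#' @export
fixation_count_score <- function(fixations, roiset, categories = NULL,
                                 discard_first = FALSE) {
  lab <- if (inherits(roiset, "roi_set")) roiset$labels else roiset
  if (is.null(categories)) {
    categories <- if (inherits(roiset, "roi_set")) roi_categories()
                  else sort(unique(as.vector(lab)))
  }
  if (discard_first && nrow(fixations)) {
    fixations <- fixations[-1, , drop = FALSE]
  }
  cls <- classify_fixations(fixations, lab)
  cls <- cls[!is.na(cls)]
  npix <- length(lab)
  area <- if (inherits(roiset, "roi_set") &&
              all(categories %in% names(roiset$areas))) {
    roiset$areas[categories]
  } else {
    vapply(categories, function(cat) sum(lab == cat), numeric(1))
  }
  raw <- vapply(categories, function(cat) {
    if (!length(cls)) NA_real_ else mean(cls == cat)
  }, numeric(1))
  fast_df(roi = categories,
          raw = unname(ifelse(area > 0, raw, NA_real_)),
          normalized = unname(ifelse(area > 0, raw / (area / npix),
                                     NA_real_)))
}

# ROI label at each fixation's rounded 0-based pixel position; NA off-image.
classify_fixations <- function(fixations, lab) {
  h <- nrow(lab); w <- ncol(lab)
  cx <- round(fixations$x_px)
  cy <- round(fixations$y_px)
  on <- !is.na(cx) & !is.na(cy) & cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
  cls <- rep(NA_character_, length(cx))
  cls[on] <- lab[cbind(cy[on] + 1, cx[on] + 1)]
  cls
}

#' Relative frequencies of the first fixations per ROI
#'
#' For each of the first `n_fix` fixations after stimulus onset, each
#' trial's fixation is classified by the ROI category at its position; the
#' relative frequency of a category at fixation index `k` is the number of
#' trials whose `k`-th fixation fell in that category divided by the number
#' of trials with any classifiable `k`-th fixation. Scores are normalized
#' by the mean area share of the category across the supplied scenes.
#'
#' Trials flagged for exclusion (replaced baselines) must be filtered out by
#' the caller; the trial-initial overlapping fixation must already be
#' discarded.
#'
#' @param trial_fixations List of corrected fixation data frames, one per
#'   trial (first row = first scene-driven fixation).
#' @param trial_roisets List (parallel to `trial_fixations`) of `roi_set`s
#'   or label matrices for each trial's scene.
#' @param n_fix Number of initial fixations to analyze (default 3).
#' @param categories Categories to report (default four-way partition).
#' @return Data frame with `fix_index`, `roi`, `freq` (relative frequency)
#'   and `normalized` (freq divided by mean area share). Indices with zero
#'   classifiable fixations yield `NA`.
#' @export
first_fixation_frequencies <- function(trial_fixations, trial_roisets,
                                       n_fix = 3, categories = roi_categories()) {
  stopifnot(length(trial_fixations) == length(trial_roisets))
  labs <- lapply(trial_roisets, function(r) {
    if (inherits(r, "roi_set")) r$labels else r
  })
  # mean area share per category across scenes
  share <- sapply(categories, function(cat) {
    mean(vapply(labs, function(l) sum(l == cat) / length(l), numeric(1)))
  })
  # classify each trial's first n_fix fixations in one pass
  cls_mat <- vapply(seq_along(trial_fixations), function(i) {
    f <- trial_fixations[[i]]
    take <- seq_len(min(nrow(f), n_fix))
    cls <- rep(NA_character_, n_fix)
    if (length(take)) {
      cls[take] <- classify_fixations(
        list(x_px = f$x_px[take], y_px = f$y_px[take]), labs[[i]])
    }
    cls
  }, character(n_fix))
  cls_mat <- matrix(cls_mat, nrow = n_fix)   # n_fix x trials
  rows <- list()
  for (k in seq_len(n_fix)) {
    cls <- cls_mat[k, ]
    cls <- cls[!is.na(cls)]
    for (cat in categories) {
      freq <- if (length(cls)) mean(cls == cat) else NA_real_
      norm <- if (is.na(freq) || share[[cat]] == 0) NA_real_
              else freq / share[[cat]]
      rows[[length(rows) + 1]] <- data.frame(fix_index = k, roi = cat,
                                             freq = freq, normalized = norm)
    }
  }
  do.call(rbind, rows)
}

#' Per-component variant of the area-normalized score
#'
#' Further divides an area-normalized score by the number of connected
#' components of its category, accounting for the spatial fragmentation of
#' the ROI. On single-component partitions this preserves the ordering of
#' the plain scores.
#'
#' @param scores Data frame from [roi_density_score()] or
#'   [fixation_count_score()].
#' @param roiset The matching `roi_set`.
#' @param connectivity Component connectivity (default 8).
#' @return `scores` with an extra column `normalized_per_roi`.
#' @export
per_component_score <- function(scores, roiset, connectivity = 8) {
  counts <- count_rois(roiset, connectivity)
  n <- counts[scores$roi]
  scores$normalized_per_roi <- ifelse(n > 0, scores$normalized / n, NA_real_)
  scores
}

#' Reaction time of a trial
#'
#' Time from stimulus onset to the first mouse click; trials without a
#' click are scored as the full presentation time.
#'
#' @param meta A [trial_meta()] row (or data frame of rows).
#' @return Reaction time(s) in ms.
#' @export
reaction_time <- function(meta) {
  ifelse(is.na(meta$click_time_ms),
         meta$presentation_ms,
         meta$click_time_ms - meta$stimulus_onset_ms)
}
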