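#' Segment a gaze recording into saccades and fixations
#'
#' Angular velocity and acceleration are estimated from positions converted
#' to degrees (exact tangent mapping about the screen center). Velocity uses
#' a central difference over a 5-sample window; acceleration is the central
#' difference of the velocity. A sample is in-saccade when its velocity
#' exceeds `vel_thresh` OR its acceleration exceeds `acc_thresh`; maximal
#' runs of in-saccade samples form saccades and the complementary valid
#' intervals are fixations. Blink-flagged spans (padded by `blink_pad_ms` on
#' each side) belong to neither class.
#'
#' @param rec A [gaze_recording()].
#' @param geom A [screen_geometry()].
#' @param vel_thresh Saccade velocity threshold in degrees/s (default 30).
#' @param acc_thresh Saccade acceleration threshold in degrees/s^2
#'   (default 8000).
#' @param window Velocity differencing window in samples (odd, default 5:
#'   central difference across +/- 2 samples).
#' @param blink_pad_ms Samples within this margin of an invalid span are
#'   treated as invalid too (default 25 ms; set 0 to disable).
#'
#' @return A list of class `gaze_events` with data frames `fixations`
#'   (`onset_ms`, `offset_ms`, `duration_ms`, `x_px`, `y_px`, `corrected`)
#'   and `saccades` (`onset_ms`, `offset_ms`, `duration_ms`,
#'   `peak_velocity_deg_s`), plus `blink_ms` (total blink time) and
#'   `all_invalid` flag. All-invalid recordings yield empty event tables
#'   with the flag set.
#' @export
detect_events <- function(rec, geom = default_geometry(), vel_thresh = 30,
                          acc_thresh = 8000, window = 5, blink_pad_ms = 25) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  n <- nrow(s)
  empty_fix <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0), x_px = numeric(0),
                          y_px = numeric(0), corrected = logical(0))
  empty_sac <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0),
                          peak_velocity_deg_s = numeric(0))
  valid <- s$valid & is.finite(s$x_px) & is.finite(s$y_px)
  if (blink_pad_ms > 0 && any(!valid)) {
    pad <- ceiling(blink_pad_ms * rec$sample_rate_hz / 1000)
    bad <- which(!valid)
    for (off in seq_len(pad)) {
      valid[pmax(bad - off, 1)] <- FALSE
      valid[pmin(bad + off, n)] <- FALSE
    }
  }
  out_empty <- structure(list(fixations = empty_fix, saccades = empty_sac,
                              blink_ms = sum(!valid) * 1000 / rec$sample_rate_hz,
                              all_invalid = TRUE, trial_id = rec$trial_id),
                         class = "gaze_events")
  if (sum(valid) < 3) return(out_empty)

  xd <- position_to_degrees(s$x_px, "horizontal", geom)
  yd <- position_to_degrees(s$y_px, "vertical", geom)
  t_s <- s$time_ms / 1000
  half <- (window - 1) %/% 2
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1); hi <- pmin(idx + half, n)
  vel <- sqrt(((xd[hi] - xd[lo]) / (t_s[hi] - t_s[lo]))^2 +
              ((yd[hi] - yd[lo]) / (t_s[hi] - t_s[lo]))^2)
  l1 <- pmax(idx - 1, 1); h1 <- pmin(idx + 1, n)
  acc <- abs(vel[h1] - vel[l1]) / (t_s[h1] - t_s[l1])
  # classes: 0 blink, 1 fixation, 2 saccade
  cls <- integer(n)
  cls[valid] <- 1L
  insac <- valid & (vel > vel_thresh | acc > acc_thresh)
  # velocity windows touching invalid samples are unreliable: a valid sample
  # whose differencing window crosses a blink keeps its fixation label
  cumbad <- cumsum(!valid)
  win_ok <- (cumbad[hi] - cumbad[lo] + !valid[lo]) == 0
  insac[!win_ok] <- FALSE
  cls[insac] <- 2L

  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt_ms <- 1000 / rec$sample_rate_hz
  run_id <- rep.int(seq_along(r$values), r$lengths)
  onset <- s$time_ms[starts]
  offset <- s$time_ms[ends] + dt_ms
  is_fix <- r$values == 1L
  is_sac <- r$values == 2L
  fixations <- if (any(is_fix)) {
    mx <- rowsum(s$x_px, run_id)[, 1] / r$lengths
    my <- rowsum(s$y_px, run_id)[, 1] / r$lengths
    fast_df(onset_ms = onset[is_fix], offset_ms = offset[is_fix],
            duration_ms = (offset - onset)[is_fix],
            x_px = unname(mx[is_fix]), y_px = unname(my[is_fix]),
            corrected = rep(FALSE, sum(is_fix)))
  } else empty_fix
  saccades <- if (any(is_sac)) {
    pv <- vapply(which(is_sac),
                 function(k) max(vel[starts[k]:ends[k]]), numeric(1))
    fast_df(onset_ms = onset[is_sac], offset_ms = offset[is_sac],
            duration_ms = (offset - onset)[is_sac],
            peak_velocity_deg_s = pv)
  } else empty_sac
  structure(list(fixations = fixations, saccades = saccades,
                 blink_ms = sum(cls == 0L) * dt_ms,
                 all_invalid = FALSE, trial_id = rec$trial_id),
            class = "gaze_events")
}

#' @export
print.gaze_events <- function(x, ...) {
  cat(sprintf("gaze_events '%s': %d fixations, %d saccades, %.0f ms blink\n",
              x$trial_id, nrow(x$fixations), nrow(x$saccades), x$blink_ms))
  invisible(x)
}

#' Recursive outlier removal
#'
#' Iteratively tests the extremes of a sample: the current maximum and
#' minimum are temporarily removed, mean and SD (denominator `n - 1`) of the
#' remainder are computed, and a temporarily removed value falling outside
#' `mean +/- k * SD` is removed permanently; values inside the interval are
#' returned to the set. Iteration stops when a pass removes nothing.
#' Sequences of fewer than 3 values are returned unchanged (the SD of the
#' remainder would be undefined).
#'
#' @param values Numeric vector.
#' @param k SD multiplier (default 3).
#' @return List with `kept`, `removed` (values), and the corresponding
#'   `kept_idx` / `removed_idx` into the input.
#' @export
recursive_outlier_removal <- function(values, k = 3) {
  idx <- seq_along(values)
  keep <- !is.na(values)
  removed <- integer(0)
  if (sum(keep) < 3) {
    return(list(kept = values[keep], removed = values[removed],
                kept_idx = idx[keep], removed_idx = removed))
  }
  repeat {
    cur <- which(keep)
    if (length(cur) < 3) break
    v <- values[cur]
    i_max <- cur[which.max(v)]
    i_min <- cur[which.min(v)]
    rest <- setdiff(cur, c(i_max, i_min))
    if (length(rest) < 2) break   # SD of the remainder undefined
    m <- mean(values[rest]); s <- stats::sd(values[rest])
    out_now <- integer(0)
    for (i in unique(c(i_max, i_min))) {
      if (abs(values[i] - m) > k * s) out_now <- c(out_now, i)
    }
    if (!length(out_now)) break
    keep[out_now] <- FALSE
    removed <- c(removed, out_now)
  }
  list(kept = values[keep], removed = values[sort(removed)],
       kept_idx = idx[keep], removed_idx = sort(removed))
}

#' Per-trial baseline gaze position
#'
#' Mean gaze over the `window_ms` before stimulus onset, using valid samples
#' only.
#'
#' @param rec A [gaze_recording()].
#' @param onset_ms Stimulus onset time.
#' @param window_ms Baseline window length before onset (default 300).
#' @return One-row data frame (`trial_id`, `bx_px`, `by_px`, `status`);
#'   `status` is `"missing"` when no valid baseline samples exist.
#' @export
compute_baseline <- function(rec, onset_ms, window_ms = 300) {
  s <- rec$samples
  in_win <- s$time_ms >= onset_ms - window_ms & s$time_ms < onset_ms &
    s$valid & is.finite(s$x_px) & is.finite(s$y_px)
  if (!any(in_win)) {
    return(fast_df(trial_id = rec$trial_id, bx_px = NA_real_,
                   by_px = NA_real_, status = "missing"))
  }
  fast_df(trial_id = rec$trial_id,
          bx_px = mean(s$x_px[in_win]), by_px = mean(s$y_px[in_win]),
          status = "valid")
}

#' Finalize baselines for one participant
#'
#' Applies [recursive_outlier_removal()] separately to the x and y baseline
#' coordinates. A trial whose baseline had a removed x or y coordinate, or
#' missing baseline data, gets both coordinates replaced by the mean of all
#' valid baselines and `status = "replaced"`; such trials are flagged for
#' exclusion from first-fixation analyses.
#'
#' @param records Data frame as rows of [compute_baseline()] for all trials
#'   of one participant.
#' @param k SD multiplier passed to the outlier procedure (default 3).
#' @return `records` with finalized `bx_px`, `by_px`, `status` in
#'   `c("valid", "replaced")` and logical `exclude_first_fix`.
#' @export
resolve_baselines <- function(records, k = 3) {
  stopifnot(all(c("trial_id", "bx_px", "by_px", "status") %in% names(records)))
  measured <- records$status != "missing"
  bad <- !measured
  if (any(measured)) {
    rx <- recursive_outlier_removal(ifelse(measured, records$bx_px, NA), k)
    ry <- recursive_outlier_removal(ifelse(measured, records$by_px, NA), k)
    bad[rx$removed_idx] <- TRUE
    bad[ry$removed_idx] <- TRUE
  }
  if (all(bad)) {
    stop("participant-level data error: no valid baselines to replace from")
  }
  mx <- mean(records$bx_px[!bad]); my <- mean(records$by_px[!bad])
  records$bx_px[bad] <- mx
  records$by_px[bad] <- my
  records$status <- ifelse(bad, "replaced", "valid")
  records$exclude_first_fix <- bad
  records
}

#' Drift-correct fixation positions
#'
#' Shifts every fixation by `-(baseline - cross)`, i.e. removes the constant
#' offset between the pre-stimulus baseline gaze and the fixation-cross
#' position. Durations and inter-fixation distances are preserved exactly.
#'
#' @param fixations Fixation data frame from [detect_events()].
#' @param baseline Length-2 `(bx, by)` finalized baseline position (px).
#' @param cross Length-2 `(x, y)` fixation-cross position (px).
#' @return The fixations with shifted positions and `corrected = TRUE`.
#' @export
drift_correct <- function(fixations, baseline, cross) {
  fixations$x_px <- fixations$x_px - (baseline[1] - cross[1])
  fixations$y_px <- fixations$y_px - (baseline[2] - cross[2])
  fixations$corrected <- TRUE
  fixations
}

#' Apply trial- and participant-level exclusion rules
#'
#' Drops trials whose blink-free time is less than `min_blink_free` of the
#' presentation window, participants with missing responses in more than
#' `max_missing_resp` of their response trials, and participants with more
#' than `max_bad_baseline` missing-or-outlier baselines.
#'
#' @param trials Data frame with one row per trial and columns `subject_id`,
#'   `trial_id`, `task`, `blink_ms`, `presentation_ms`, `responded`
#'   (logical; `NA` for tasks without a required response, e.g. free
#'   viewing), `baseline_status` (`"valid"` / `"replaced"`).
#' @param min_blink_free Minimum blink-free fraction of a trial (default 0.8).
#' @param max_missing_resp Maximum tolerated fraction of missing responses
#'   (default 0.25).
#' @param max_bad_baseline Maximum tolerated fraction of replaced baselines
#'   (default 0.20).
#' @return List with `trials` (retained rows) and `report`, a data frame
#'   listing every dropped trial or participant with the rule that fired.
#' @export
apply_exclusions <- function(trials, min_blink_free = 0.8,
                             max_missing_resp = 0.25,
                             max_bad_baseline = 0.20) {
  report <- data.frame(level = character(0), id = character(0),
                       rule = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  blink_free <- 1 - trials$blink_ms / trials$presentation_ms
  drop_trial <- blink_free < min_blink_free
  if (any(drop_trial)) {
    report <- rbind(report, data.frame(
      level = "trial", id = as.character(trials$trial_id[drop_trial]),
      rule = sprintf("blink-free fraction < %.2f", min_blink_free),
      value = blink_free[drop_trial]))
  }
  kept <- trials[!drop_trial, , drop = FALSE]
  for (sub in unique(trials$subject_id)) {
    rows <- trials$subject_id == sub
    resp <- trials$responded[rows]
    resp <- resp[!is.na(resp)]
    miss_frac <- if (length(resp)) mean(!resp) else 0
    bad_base <- mean(trials$baseline_status[rows] != "valid")
    rule <- NULL
    if (miss_frac > max_missing_resp) {
      rule <- sprintf("missing responses > %.0f%%", 100 * max_missing_resp)
      val <- miss_frac
    } else if (bad_base > max_bad_baseline) {
      rule <- sprintf("missing/outlier baselines > %.0f%%",
                      100 * max_bad_baseline)
      val <- bad_base
    }
    if (!is.null(rule)) {
      report <- rbind(report, data.frame(level = "participant", id = sub,
                                         rule = rule, value = val))
      kept <- kept[kept$subject_id != sub, , drop = FALSE]
    }
  }
  list(trials = kept, report = report)
}
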