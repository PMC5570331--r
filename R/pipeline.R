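#' Run the full analysis pipeline over a dataset
#'
#' Chains every processing stage over a simulated (or equivalently, read
#' from disk) session: event detection, per-participant baseline resolution
#' with recursive outlier removal, drift correction, trial- and
#' participant-level exclusions, the trial-initial fixation discard,
#' response-window splitting, duration-weighted density maps, and the ROI
#' metrics. Returns tidy tables, one row per subject x stimulus x task x
#' ROI x window.
#'
#' @param dataset A [simulate_dataset()] result, or a list with the same
#'   shape (`trials` as lists holding `recording` + `meta`, `meta` data
#'   frame, `prepared_scenes`).
#' @param geom A [screen_geometry()].
#' @param sigma_px Density-map smoothing SD; when `NULL` (default) it is
#'   36 px scaled by the scene width relative to the 1200 px reference, so
#'   scaled-down scenes keep a proportionate kernel.
#' @param n_first_fix Number of initial fixations analyzed (default 3).
#' @param windows Analyze `"pre"`, `"post"` response windows, `"whole"`
#'   trial, or several (default `c("pre", "post")`).
#' @param vel_thresh,acc_thresh Saccade detection thresholds.
#' @return List of class `gaze_analysis`:
#'   `density` (tidy data frame of per-trial ROI density scores),
#'   `counts` (fixation-count scores), `first_fix` (per subject relative
#'   first-fixation frequencies), `rt` (per-trial reaction times),
#'   `exclusions` (report), `baselines`.
#' @export
analyze_dataset <- function(dataset, geom = default_geometry(),
                            sigma_px = NULL, n_first_fix = 3,
                            windows = c("pre", "post"),
                            vel_thresh = 30, acc_thresh = 8000) {
  meta <- dataset$meta
  scenes <- dataset$prepared_scenes
  n_trial <- nrow(meta)
  stopifnot(n_trial == length(dataset$trials))

  # stage 1: events + baselines per trial; the blink fraction that drives
  # trial exclusion is measured over the presentation window only
  events <- vector("list", n_trial)
  base_rows <- vector("list", n_trial)
  blink_pres <- numeric(n_trial)
  for (i in seq_len(n_trial)) {
    rec <- dataset$trials[[i]]$recording
    events[[i]] <- detect_events(rec, geom, vel_thresh = vel_thresh,
                                 acc_thresh = acc_thresh)
    s <- rec$samples
    in_pres <- s$time_ms >= meta$stimulus_onset_ms[i] &
      s$time_ms < meta$stimulus_onset_ms[i] + meta$presentation_ms[i]
    blink_pres[i] <- sum(!s$valid[in_pres]) * 1000 / rec$sample_rate_hz
    b <- compute_baseline(rec, meta$stimulus_onset_ms[i])
    b$trial_idx <- i
    base_rows[[i]] <- b
  }
  baselines <- do.call(rbind, base_rows)
  baselines$subject_id <- meta$subject_id

  # stage 2: per-participant baseline resolution
  resolved <- do.call(rbind, lapply(split(baselines, baselines$subject_id),
                                    resolve_baselines))
  resolved <- resolved[order(resolved$trial_idx), , drop = FALSE]

  # stage 3: exclusions
  trial_tab <- data.frame(
    subject_id = meta$subject_id,
    trial_id = vapply(events, function(e) as.character(e$trial_id),
                      character(1)),
    trial_idx = seq_len(n_trial),
    task = meta$task,
    blink_ms = blink_pres,
    presentation_ms = meta$presentation_ms,
    responded = ifelse(meta$task == "free", NA, !is.na(meta$click_time_ms)),
    baseline_status = resolved$status,
    stringsAsFactors = FALSE)
  excl <- apply_exclusions(trial_tab)
  keep_idx <- excl$trials$trial_idx

  dens_rows <- list(); count_rows <- list(); rt_rows <- list()
  ff_by_subj <- list()
  m_subject <- meta$subject_id; m_stim <- meta$stimulus_id
  m_task <- meta$task; m_onset <- meta$stimulus_onset_ms
  m_click <- meta$click_time_ms; m_pres <- meta$presentation_ms
  m_cx <- meta$cross_x_px; m_cy <- meta$cross_y_px
  m_scene <- meta$scene_index
  for (i in keep_idx) {
    ps <- scenes[[m_scene[i]]]
    dims <- dim(ps$scene$image)
    sig <- if (is.null(sigma_px)) 36 * dims[2] / 1200 else sigma_px
    fx <- events[[i]]$fixations
    if (!nrow(fx)) next
    fx <- drift_correct(fx, c(resolved$bx_px[i], resolved$by_px[i]),
                        c(m_cx[i], m_cy[i]))
    # scene-driven fixations: initial overlapping fixation discarded once
    fx <- fx[fx$offset_ms > m_onset[i], , drop = FALSE]
    fx <- discard_first_fixation(fx, m_onset[i])
    if (!nrow(fx)) next

    if (!resolved$exclude_first_fix[i]) {
      key <- m_subject[i]
      ff_by_subj[[key]]$fix <- c(ff_by_subj[[key]]$fix, list(fx))
      ff_by_subj[[key]]$roi <- c(ff_by_subj[[key]]$roi, list(ps$roiset))
      ff_by_subj[[key]]$task <- c(ff_by_subj[[key]]$task, m_task[i])
    }

    winsets <- list()
    if (any(c("pre", "post") %in% windows)) {
      sp <- split_by_response(fx, m_click[i])
      if ("pre" %in% windows) winsets$pre <- sp$pre
      if ("post" %in% windows) winsets$post <- sp$post
    }
    if ("whole" %in% windows) winsets$whole <- fx
    for (wname in names(winsets)) {
      wfx <- winsets[[wname]]
      if (!nrow(wfx)) next
      dm <- build_density_map(wfx, size = c(dims[2], dims[1]),
                              sigma_px = sig, discard_first = FALSE)
      sc <- roi_density_score(dm, ps$roiset)
      cc <- fixation_count_score(wfx, ps$roiset)
      k <- nrow(sc)
      info <- fast_df(subject_id = rep(m_subject[i], k),
                      stimulus_id = rep(m_stim[i], k),
                      task = rep(m_task[i], k),
                      category = rep(ps$category, k),
                      window = rep(wname, k))
      dens_rows[[length(dens_rows) + 1]] <- cbind(info, sc)
      count_rows[[length(count_rows) + 1]] <- cbind(info, cc)
    }
    rt_rows[[length(rt_rows) + 1]] <- fast_df(
      subject_id = m_subject[i], stimulus_id = m_stim[i], task = m_task[i],
      category = ps$category,
      rt_ms = if (is.na(m_click[i])) m_pres[i] else m_click[i] - m_onset[i])
  }

  ff_rows <- list()
  for (key in names(ff_by_subj)) {
    e <- ff_by_subj[[key]]
    for (task in unique(e$task)) {
      pick <- e$task == task
      ff <- first_fixation_frequencies(e$fix[pick], e$roi[pick],
                                       n_fix = n_first_fix)
      ff_rows[[length(ff_rows) + 1]] <-
        cbind(data.frame(subject_id = key, task = task,
                         stringsAsFactors = FALSE), ff)
    }
  }

  structure(list(
    density = if (length(dens_rows)) do.call(rbind, dens_rows) else NULL,
    counts = if (length(count_rows)) do.call(rbind, count_rows) else NULL,
    first_fix = if (length(ff_rows)) do.call(rbind, ff_rows) else NULL,
    rt = if (length(rt_rows)) do.call(rbind, rt_rows) else NULL,
    exclusions = excl$report, baselines = resolved),
    class = "gaze_analysis")
}

#' Group-mean area-normalized density scores per ROI
#'
#' Means over scenes are computed per participant (and window), then
#' averaged over participants -- the aggregation used for the headline
#' ROI-preference comparisons.
#'
#' @param analysis A [analyze_dataset()] result.
#' @param window Which window to summarize (default `"pre"`).
#' @param tasks Optional subset of tasks.
#' @return Data frame `roi`, `mean_normalized`, `n_subjects`.
#' @export
summarize_roi_preference <- function(analysis, window = "pre", tasks = NULL) {
  d <- analysis$density
  d <- d[d$window == window & !is.na(d$normalized), , drop = FALSE]
  if (!is.null(tasks)) d <- d[d$task %in% tasks, , drop = FALSE]
  per_subj <- stats::aggregate(normalized ~ subject_id + roi, data = d,
                               FUN = mean)
  out <- stats::aggregate(normalized ~ roi, data = per_subj, FUN = mean)
  names(out)[2] <- "mean_normalized"
  out$n_subjects <- length(unique(per_subj$subject_id))
  out[order(-out$mean_normalized), ]
}
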