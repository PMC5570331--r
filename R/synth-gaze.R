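#' Specification of the synthetic gaze process
#'
#' States the generative model behind simulated recordings: fixation
#' targets drawn from ROI-category preference weights with uniform landing
#' inside the category, gamma-distributed fixation durations, straight
#' saccades with a raised-cosine velocity profile, AR(1) fixational jitter,
#' a constant per-trial baseline drift offset, Poisson blinks, and per-task
#' response-time models.
#'
#' @param preference_weights Nonnegative weights over the four ROI
#'   categories, summing to 1. Default reflects a strong free-viewing head
#'   preference (0.6 head).
#' @param fixation_shape,fixation_mean_ms Gamma parameters of fixation
#'   durations (default shape 4, mean 250 ms: right-skewed, positive,
#'   typical of scene viewing).
#' @param saccade_vpeak_range Peak-velocity range in degrees/s of the
#'   raised-cosine saccade profile (default 200-400, far above the 30
#'   degrees/s detection threshold).
#' @param saccade_min_amp_deg Minimum saccade amplitude in degrees; targets
#'   closer than this are resampled so every simulated saccade reliably
#'   crosses the detection threshold (default 1).
#' @param noise_sd_px Stationary SD of the AR(1) fixational jitter in px
#'   (default 1).
#' @param noise_ar AR(1) coefficient of the jitter (default 0.95; smooth
#'   tremor rather than white noise, keeping fixation-phase sample-to-sample
#'   velocities below the saccade threshold).
#' @param drift_sd_px SD of the constant per-trial baseline drift offset
#'   (default 5 px per axis).
#' @param blink_rate_hz Blink rate per second (default 0.05).
#' @param blink_mean_ms,blink_shape Gamma parameters of blink durations
#'   (default mean 150 ms, shape 4).
#' @param click_models Named list of per-task reaction-time models; each a
#'   `c(meanlog, sdlog)` lognormal parameter pair in ms, or `NULL` for
#'   tasks without a response (free viewing). Defaults give median RTs of
#'   roughly 3 s (define), 6 s (count) and 4.5 s (estimate).
#' @param pre_ms Pre-stimulus phase length (default 2000 ms, fixating the
#'   cross, from which the 300 ms baseline is extracted).
#' @param sample_rate_hz Sampling rate (default 1000).
#' @return A list of class `gaze_sim_spec`.
#' @export
gaze_sim_spec <- function(preference_weights = c(head = 0.6, body = 0.2,
                                                 low_sal = 0.05,
                                                 high_sal = 0.15),
                          fixation_shape = 4, fixation_mean_ms = 250,
                          saccade_vpeak_range = c(200, 400),
                          saccade_min_amp_deg = 1,
                          noise_sd_px = 1, noise_ar = 0.95,
                          drift_sd_px = 5, blink_rate_hz = 0.05,
                          blink_mean_ms = 150, blink_shape = 4,
                          click_models = list(
                            free = NULL,
                            define = c(meanlog = log(3000), sdlog = 0.3),
                            count = c(meanlog = log(6000), sdlog = 0.25),
                            estimate = c(meanlog = log(4500), sdlog = 0.3)),
                          pre_ms = 2000, sample_rate_hz = 1000) {
  if (any(preference_weights < 0)) stop("preference weights must be nonnegative")
  if (abs(sum(preference_weights) - 1) > 1e-8) {
    stop("preference weights must sum to 1")
  }
  if (!all(names(preference_weights) %in% roi_categories())) {
    stop("preference weight names must be ROI categories")
  }
  structure(as.list(environment()), class = "gaze_sim_spec")
}

# child seed derived from a master seed and integer tags; kept below 2^31
child_seed <- function(master, ...) {
  tags <- c(master, ...)
  s <- 0
  for (t in tags) s <- (s * 69069 + as.numeric(t) + 1) %% 2147483647
  as.integer(s)
}

#' Simulate one trial's gaze recording with ground truth
#'
#' Emits samples at `sim$sample_rate_hz`: a `pre_ms` phase fixating the
#' cross (the trial-initial fixation deliberately overlaps stimulus onset),
#' then alternating scene fixations and saccades for the presentation. Each
#' fixation's target category is drawn from the preference weights and its
#' landing point uniformly inside that category; the constant per-trial
#' drift offset is added to all samples; blinks replace samples with
#' invalid flags. The ground truth (event boundaries, target categories and
#' landing points, drift, blink spans) is returned alongside.
#'
#' @param roiset The scene's [build_roiset()] partition (or label matrix).
#' @param meta A [trial_meta()] row; `cross_x_px`/`cross_y_px` give the
#'   fixation-cross position in scene pixel coordinates.
#' @param sim A [gaze_sim_spec()].
#' @param geom A [screen_geometry()] (converts saccade amplitudes to
#'   degrees).
#' @param seed Integer seed for this trial.
#' @return List of class `sim_trial`: `recording` (a [gaze_recording()]),
#'   `truth` (data frame of ground-truth events with `type`, `onset_ms`,
#'   `offset_ms`, `roi`, `x_px`, `y_px`), `drift` (length-2 offset),
#'   `meta`.
#' @export
simulate_trial <- function(roiset, meta, sim = gaze_sim_spec(),
                           geom = default_geometry(), seed = 1) {
  lab <- if (inherits(roiset, "roi_set")) roiset$labels else roiset
  with_seed(seed, simulate_trial_impl(lab, meta, sim, geom))
}

simulate_trial_impl <- function(lab, meta, sim, geom) {
  h <- nrow(lab); w <- ncol(lab)
  dt <- 1000 / sim$sample_rate_hz
  total_ms <- sim$pre_ms + meta$presentation_ms
  n <- round(total_ms / dt)
  t_ms <- (seq_len(n) - 1) * dt
  onset <- sim$pre_ms   # stimulus onset relative to recording start

  wts <- sim$preference_weights
  cat_pix <- lapply(names(wts), function(cat) which(lab == cat))
  names(cat_pix) <- names(wts)
  for (cat in names(wts)) {
    if (wts[[cat]] > 0 && !length(cat_pix[[cat]])) {
      stop("simulation error: nonzero preference weight for empty ROI '",
           cat, "'")
    }
  }
  deg_per_px <- c(pixels_to_degrees(1, "horizontal", geom),
                  pixels_to_degrees(1, "vertical", geom))
  draw_target <- function(from) {
    # resample until the saccade is long enough to be detectable
    for (i in 1:50) {
      cat <- sample(names(wts), 1, prob = wts)
      px <- cat_pix[[cat]][sample.int(length(cat_pix[[cat]]), 1)]
      x <- (px - 1) %/% h   # column-major index -> 0-based (x, y)
      y <- (px - 1) %% h
      amp <- sqrt(sum((((c(x, y) - from) * deg_per_px))^2))
      if (amp >= sim$saccade_min_amp_deg) {
        return(list(cat = cat, x = x, y = y, amp_deg = amp))
      }
    }
    list(cat = cat, x = x, y = y, amp_deg = amp)  # accept a short one
  }

  cross <- c(meta$cross_x_px[1], meta$cross_y_px[1])
  x <- numeric(n); y <- numeric(n)
  # truth accumulated in flat vectors; one data frame at the end
  tv_type <- character(0); tv_on <- numeric(0); tv_off <- numeric(0)
  tv_roi <- character(0); tv_x <- numeric(0); tv_y <- numeric(0)
  add_truth <- function(type, on, off, roi, tx, ty) {
    tv_type[length(tv_type) + 1] <<- type
    tv_on[length(tv_on) + 1] <<- on
    tv_off[length(tv_off) + 1] <<- off
    tv_roi[length(tv_roi) + 1] <<- roi
    tv_x[length(tv_x) + 1] <<- tx
    tv_y[length(tv_y) + 1] <<- ty
  }
  # sample indices covering [t0, t1): uniform sampling allows arithmetic
  seg_idx <- function(t0, t1) {
    i0 <- max(1L, as.integer(ceiling(t0 / dt)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 / dt)))
    if (i0 > i1) integer(0) else i0:i1
  }

  # trial-initial fixation: cross, through onset plus a residual duration
  residual <- stats::rgamma(1, shape = sim$fixation_shape,
                            scale = sim$fixation_mean_ms / sim$fixation_shape)
  t_cur <- min(onset + residual, total_ms)
  seg <- seg_idx(0, t_cur)
  x[seg] <- cross[1]; y[seg] <- cross[2]
  add_truth("fixation", 0, t_cur, NA_character_, cross[1], cross[2])
  pos <- cross

  while (t_cur < total_ms - dt) {
    tgt <- draw_target(pos)
    vp <- stats::runif(1, sim$saccade_vpeak_range[1], sim$saccade_vpeak_range[2])
    dur <- max(2 * tgt$amp_deg / vp * 1000, 2 * dt)  # ms
    t_end <- min(t_cur + dur, total_ms)
    seg <- seg_idx(t_cur, t_end)
    if (length(seg)) {
      frac <- (t_ms[seg] - t_cur) / dur
      # raised-cosine velocity => smooth displacement profile
      sfrac <- frac - sin(2 * pi * frac) / (2 * pi)
      x[seg] <- pos[1] + (tgt$x - pos[1]) * sfrac
      y[seg] <- pos[2] + (tgt$y - pos[2]) * sfrac
    }
    add_truth("saccade", t_cur, t_end, NA_character_, tgt$x, tgt$y)
    t_cur <- t_end
    if (t_cur >= total_ms - dt) { pos <- c(tgt$x, tgt$y); break }
    fdur <- stats::rgamma(1, shape = sim$fixation_shape,
                          scale = sim$fixation_mean_ms / sim$fixation_shape)
    t_end <- min(t_cur + fdur, total_ms)
    seg <- seg_idx(t_cur, t_end)
    x[seg] <- tgt$x; y[seg] <- tgt$y
    add_truth("fixation", t_cur, t_end, tgt$cat, tgt$x, tgt$y)
    pos <- c(tgt$x, tgt$y)
    t_cur <- t_end
  }
  # fill any trailing samples with the last position
  if (t_cur < total_ms) {
    seg <- seg_idx(t_cur, total_ms)
    x[seg] <- pos[1]; y[seg] <- pos[2]
  }

  # AR(1) fixational jitter (smooth tremor), applied to the whole stream
  if (sim$noise_sd_px > 0) {
    innov_sd <- sim$noise_sd_px * sqrt(1 - sim$noise_ar^2)
    x <- x + as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      sim$noise_ar, "recursive"))
    y <- y + as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      sim$noise_ar, "recursive"))
  }
  drift <- stats::rnorm(2, 0, sim$drift_sd_px)
  x <- x + drift[1]; y <- y + drift[2]

  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, sim$blink_rate_hz * total_ms / 1000)
  blinks <- list()
  if (n_blinks > 0) {
    for (b in seq_len(n_blinks)) {
      bdur <- stats::rgamma(1, shape = sim$blink_shape,
                            scale = sim$blink_mean_ms / sim$blink_shape)
      bstart <- stats::runif(1, 0, total_ms - bdur)
      hit <- t_ms >= bstart & t_ms < bstart + bdur
      valid[hit] <- FALSE
      blinks[[b]] <- c(bstart, bstart + bdur)
    }
  }
  x[!valid] <- NA; y[!valid] <- NA

  rec_start <- meta$stimulus_onset_ms - sim$pre_ms
  samples <- fast_df(time_ms = rec_start + t_ms, x_px = x, y_px = y,
                     valid = valid)
  truth_df <- fast_df(type = tv_type, onset_ms = tv_on + rec_start,
                      offset_ms = tv_off + rec_start, roi = tv_roi,
                      x_px = tv_x, y_px = tv_y)
  # samples are constructed in time order: build the recording directly
  rec <- structure(list(samples = samples, sample_rate_hz = sim$sample_rate_hz,
                        trial_id = paste(meta$subject_id, meta$stimulus_id,
                                         meta$task, sep = "_")),
                   class = "gaze_recording")
  structure(list(recording = rec, truth = truth_df, drift = drift,
                 blinks = blinks, meta = meta),
            class = "sim_trial")
}

#' Prepare a scene for simulation and analysis
#'
#' Computes the scene's saliency map and four-way ROI partition once, so
#' repeated simulations over the same stimulus set reuse them.
#'
#' @param scene A [generate_scene()] result.
#' @param q Saliency percentile cutoff (default 80).
#' @param ... Passed to [compute_saliency()].
#' @return List of class `prepared_scene`: `scene`, `saliency`, `roiset`,
#'   `category` (`"social"` if the scene has social pixels else
#'   `"nonsocial"`).
#' @export
prepare_scene <- function(scene, q = 80, ...) {
  sal <- compute_saliency(scene$image, ...)
  social <- any(scene$head_mask) || any(scene$body_mask)
  roiset <- build_roiset(sal,
                         social_mask = if (social)
                           list(head = scene$head_mask,
                                body = scene$body_mask) else NULL,
                         q = q)
  structure(list(scene = scene, saliency = sal, roiset = roiset,
                 category = if (social) "social" else "nonsocial"),
            class = "prepared_scene")
}

#' Simulate a full multi-subject session
#'
#' Every subject sees every prepared scene under every requested task (the
#' study-like layout: each task crossed with each stimulus). Per-trial
#' seeds are derived deterministically from the master seed, so the whole
#' session is reproducible end to end.
#'
#' @param n_subjects Number of subjects.
#' @param prepared_scenes List of [prepare_scene()] results.
#' @param tasks Character vector of tasks (subset of
#'   `c("free", "define", "count", "estimate")`).
#' @param sim A [gaze_sim_spec()].
#' @param geom A [screen_geometry()].
#' @param seed Master seed.
#' @param trial_gap_ms Spacing of recording starts (bookkeeping only).
#' @return List of class `sim_dataset`: `trials` (list of `sim_trial`),
#'   `meta` (data frame, one row per trial), `prepared_scenes`, `sim`,
#'   `seed`.
#' @export
simulate_dataset <- function(n_subjects, prepared_scenes,
                             tasks = c("free", "define", "count", "estimate"),
                             sim = gaze_sim_spec(), geom = default_geometry(),
                             seed = 1, trial_gap_ms = 20000) {
  stopifnot(n_subjects >= 1, length(prepared_scenes) >= 1)
  trials <- list()
  metas <- list()
  idx <- 0
  for (s in seq_len(n_subjects)) {
    trial_no <- 0
    for (task in tasks) {
      for (sc in seq_along(prepared_scenes)) {
        idx <- idx + 1; trial_no <- trial_no + 1
        ps <- prepared_scenes[[sc]]
        dims <- dim(ps$scene$image)
        onset <- sim$pre_ms + (trial_no - 1) * trial_gap_ms
        tseed <- child_seed(seed, s, trial_no)
        click <- NA
        cm <- sim$click_models[[task]]
        if (!is.null(cm) && !anyNA(cm)) {
          rt <- with_seed(child_seed(tseed, 7L),
                          stats::rlnorm(1, cm[["meanlog"]], cm[["sdlog"]]))
          # a draw beyond the presentation is a missed response, not a
          # click at the deadline
          if (rt <= 10000) click <- onset + rt
        }
        meta <- trial_meta(subject_id = sprintf("S%02d", s),
                           stimulus_id = sprintf("I%02d", sc),
                           task = task, category = ps$category,
                           stimulus_onset_ms = onset, click_time_ms = click,
                           cross_position_px = c((dims[2] - 1) / 2,
                                                 (dims[1] - 1) / 2))
        wts <- adapt_weights(sim$preference_weights, ps$roiset)
        sim_t <- sim
        sim_t$preference_weights <- wts
        trials[[idx]] <- simulate_trial(ps$roiset, meta, sim_t, geom,
                                        seed = tseed)
        meta$scene_index <- sc
        meta$trial_id <- trials[[idx]]$recording$trial_id
        metas[[idx]] <- meta
      }
    }
  }
  structure(list(trials = trials, meta = do.call(rbind, metas),
                 prepared_scenes = prepared_scenes, sim = sim, seed = seed),
            class = "sim_dataset")
}

# For non-social scenes the social weight mass is reallocated to the
# saliency categories in proportion to their weights (or split evenly when
# both are zero).
adapt_weights <- function(wts, roiset) {
  areas <- roiset$areas[names(wts)]
  empty <- is.na(areas) | areas == 0
  if (!any(empty)) return(wts)
  w <- wts
  lost <- sum(w[empty])
  w[empty] <- 0
  if (sum(w) == 0) {
    w[!empty] <- 1 / sum(!empty)
  } else {
    w[!empty] <- w[!empty] + lost * w[!empty] / sum(w[!empty])
  }
  w
}
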