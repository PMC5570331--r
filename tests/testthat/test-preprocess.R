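const_rec <- function(n = 1000, x = 500, y = 400, rate = 1000) {
  gaze_recording(data.frame(time_ms = seq_len(n) - 1, x_px = x, y_px = y,
                            valid = TRUE), rate, trial_id = "const")
}

test_that("constant gaze yields one long fixation and no saccade", {
  ev <- detect_events(const_rec(10000), ref_geom())
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(ev$fixations$duration_ms, 10000)
  expect_equal(ev$fixations$x_px, 500)
})

test_that("sub-threshold smooth motion is one fixation by the rule", {
  # 20 deg/s: below the 30 deg/s velocity threshold, zero acceleration
  geom <- ref_geom()
  px_per_deg <- degrees_to_pixels(1, "horizontal", geom)
  t <- 0:2000
  x <- 300 + 20 * px_per_deg * t / 1000
  rec <- gaze_recording(data.frame(time_ms = t, x_px = x, y_px = 400,
                                   valid = TRUE), 1000, "drift20")
  ev <- detect_events(rec, geom)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(nrow(ev$fixations), 1)
})

test_that("detector recovers simulator ground truth exactly without noise", {
  ps <- tiny_prepared_scene()
  meta <- tiny_meta()
  for (seed in c(2, 9, 23)) {
    # fixed 300 deg/s peaks: threshold crossing within 2 samples of onset
    tr <- simulate_trial(ps$roiset, meta,
                         quiet_sim(saccade_vpeak_range = c(300, 300)),
                         ref_geom(), seed = seed)
    ev <- detect_events(tr$recording, ref_geom())
    truth_sac <- tr$truth[tr$truth$type == "saccade", ]
    truth_fix <- tr$truth[tr$truth$type == "fixation", ]
    expect_equal(nrow(ev$saccades), nrow(truth_sac))
    expect_equal(nrow(ev$fixations), nrow(truth_fix))
    expect_true(all(abs(ev$saccades$onset_ms - truth_sac$onset_ms) <= 2))
    expect_true(all(ev$saccades$peak_velocity_deg_s >= 30))
    # default velocity range: event recall stays exact (onsets shift by
    # the slower threshold crossing of flatter velocity profiles)
    tr2 <- simulate_trial(ps$roiset, meta, quiet_sim(), ref_geom(),
                          seed = seed)
    ev2 <- detect_events(tr2$recording, ref_geom())
    expect_equal(nrow(ev2$saccades), sum(tr2$truth$type == "saccade"))
  }
})

test_that("event segmentation partitions the trial to sample resolution", {
  ps <- tiny_prepared_scene()
  tr <- simulate_trial(ps$roiset, tiny_meta(),
                       gaze_sim_spec(blink_rate_hz = 0.2), ref_geom(),
                       seed = 4)
  ev <- detect_events(tr$recording, ref_geom())
  total <- sum(ev$fixations$duration_ms) + sum(ev$saccades$duration_ms) +
    ev$blink_ms
  n <- nrow(tr$recording$samples)
  expect_equal(total, n)   # 1000 Hz: n samples = n ms
})

test_that("all-invalid recordings are flagged, not crashed", {
  rec <- gaze_recording(data.frame(time_ms = 0:99, x_px = NA_real_,
                                   y_px = NA_real_, valid = FALSE),
                        1000, "blinky")
  ev <- detect_events(rec, ref_geom())
  expect_true(ev$all_invalid)
  expect_equal(nrow(ev$fixations), 0)
})

test_that("recursive outlier removal matches its hand-traced cases", {
  r <- recursive_outlier_removal(c(1, 1, 1, 1, 100))
  expect_equal(r$kept, c(1, 1, 1, 1))
  expect_equal(r$removed, 100)
  expect_equal(recursive_outlier_removal(rep(5, 6))$removed, numeric(0))
  # fewer than 3 values: unchanged
  expect_equal(recursive_outlier_removal(c(0, 1e6))$kept, c(0, 1e6))
})

test_that("recursive outlier removal matches the scripted oracle and is idempotent", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    v <- rnorm(n)
    if (runif(1) < 0.5) v <- c(v, rnorm(sample(1:3, 1), 0, 50))
    got <- recursive_outlier_removal(v)
    expect_equal(sort(got$kept), sort(ror_oracle(v)))
    again <- recursive_outlier_removal(got$kept)
    expect_equal(again$removed, numeric(0))
  }
  expect_equal(sort(recursive_outlier_removal(c(0, 10, 10, 10, 10, 10, 20))$kept),
               sort(ror_oracle(c(0, 10, 10, 10, 10, 10, 20))))
})

test_that("baseline resolution replaces outliers and missing trials", {
  recs <- data.frame(trial_id = paste0("t", 1:10),
                     bx_px = c(rep(600, 9), 5000),
                     by_px = rep(450, 10),
                     status = "valid", stringsAsFactors = FALSE)
  out <- resolve_baselines(recs)
  expect_equal(out$status, c(rep("valid", 9), "replaced"))
  expect_equal(out$bx_px[10], 600)   # mean of the other 9
  expect_true(out$exclude_first_fix[10])

  # missing baseline is replaced regardless of the outlier test
  recs$bx_px[10] <- 600
  recs$status[3] <- "missing"; recs$bx_px[3] <- NA; recs$by_px[3] <- NA
  out2 <- resolve_baselines(recs)
  expect_equal(out2$status[3], "replaced")
  expect_equal(out2$bx_px[3], 600)

  # all missing: participant-level error
  recs$status <- "missing"; recs$bx_px <- NA; recs$by_px <- NA
  expect_error(resolve_baselines(recs), "participant")
})

test_that("untouched baselines stay valid", {
  recs <- data.frame(trial_id = paste0("t", 1:10),
                     bx_px = rnorm(10, 600, 2), by_px = rnorm(10, 450, 2),
                     status = "valid", stringsAsFactors = FALSE)
  out <- resolve_baselines(recs)
  expect_true(all(out$status == "valid"))
  expect_equal(out$bx_px, recs$bx_px)
})

test_that("drift correction shifts by the negative baseline offset and preserves structure", {
  fx <- data.frame(onset_ms = c(0, 500), offset_ms = c(400, 900),
                   duration_ms = c(400, 400), x_px = c(100, 200),
                   y_px = c(50, 80), corrected = FALSE)
  # identity when baseline equals the cross
  same <- drift_correct(fx, c(600, 450), c(600, 450))
  expect_equal(same$x_px, fx$x_px)
  # known offset
  cor <- drift_correct(fx, c(610, 445), c(600, 450))
  expect_equal(cor$x_px, fx$x_px - 10)
  expect_equal(cor$y_px, fx$y_px + 5)
  expect_true(all(cor$corrected))
  expect_equal(cor$duration_ms, fx$duration_ms)
  expect_equal(diff(cor$x_px), diff(fx$x_px))
})

test_that("drift correction recovers simulator landing points", {
  ps <- tiny_prepared_scene()
  meta <- tiny_meta()
  sim <- gaze_sim_spec(noise_sd_px = 0.3, drift_sd_px = 8, blink_rate_hz = 0)
  tr <- simulate_trial(ps$roiset, meta, sim, ref_geom(), seed = 12)
  ev <- detect_events(tr$recording, ref_geom())
  b <- compute_baseline(tr$recording, meta$stimulus_onset_ms)
  # mean pre-stimulus gaze minus cross approximates the planted drift
  expect_equal(c(b$bx_px - meta$cross_x_px, b$by_px - meta$cross_y_px),
               tr$drift, tolerance = 0.3)
  fx <- drift_correct(ev$fixations, c(b$bx_px, b$by_px),
                      c(meta$cross_x_px, meta$cross_y_px))
  fx <- fx[fx$onset_ms >= meta$stimulus_onset_ms & fx$duration_ms > 80, ]
  truth <- tr$truth[tr$truth$type == "fixation" & !is.na(tr$truth$roi), ]
  for (i in seq_len(nrow(fx))) {
    j <- which.min(abs(truth$onset_ms - fx$onset_ms[i]))
    expect_lt(abs(fx$x_px[i] - truth$x_px[j]), 2)
    expect_lt(abs(fx$y_px[i] - truth$y_px[j]), 2)
  }
})

test_that("exclusion rules fire at their stated boundaries", {
  base <- data.frame(subject_id = "s1", trial_id = paste0("t", 1:2),
                     task = "count", blink_ms = c(2500, 1900),
                     presentation_ms = 10000, responded = TRUE,
                     baseline_status = "valid", stringsAsFactors = FALSE)
  out <- apply_exclusions(base)
  # 2.5 s blinked: 75% blink-free < 80% -> dropped; 1.9 s retained
  expect_equal(out$trials$trial_id, "t2")
  expect_equal(out$report$level, "trial")

  # participant with 9 of 40 replaced baselines: 22.5% > 20% -> dropped
  many <- data.frame(subject_id = "s2", trial_id = paste0("t", 1:40),
                     task = "count", blink_ms = 0, presentation_ms = 10000,
                     responded = TRUE,
                     baseline_status = c(rep("replaced", 9), rep("valid", 31)),
                     stringsAsFactors = FALSE)
  out2 <- apply_exclusions(many)
  expect_equal(nrow(out2$trials), 0)
  expect_match(out2$report$rule, "baselines")

  # missing responses in more than 25% of response trials
  mr <- data.frame(subject_id = "s3", trial_id = paste0("t", 1:20),
                   task = "count", blink_ms = 0, presentation_ms = 10000,
                   responded = c(rep(FALSE, 6), rep(TRUE, 14)),
                   baseline_status = "valid", stringsAsFactors = FALSE)
  expect_equal(nrow(apply_exclusions(mr)$trials), 0)
  mr$responded <- c(rep(FALSE, 5), rep(TRUE, 15))   # exactly 25%: retained
  expect_equal(nrow(apply_exclusions(mr)$trials), 20)
})
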