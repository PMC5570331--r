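test_that("scene generation is byte-identical under a fixed seed", {
  s1 <- generate_scene(scene_spec(size_px = c(160, 120), seed = 1))
  s2 <- generate_scene(scene_spec(size_px = c(160, 120), seed = 1))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$head_mask, s2$head_mask)
  s3 <- generate_scene(scene_spec(size_px = c(160, 120), seed = 2))
  expect_false(identical(s1$image, s3$image))
})

test_that("degenerate social content still yields distractor contrast", {
  sc <- generate_scene(scene_spec(size_px = c(160, 120), n_heads = 0,
                                  n_bodies = 0, seed = 5))
  expect_equal(sum(sc$head_mask), 0)
  expect_equal(sum(sc$body_mask), 0)
  expect_gt(diff(range(sc$image)), 0.3)   # non-degenerate for saliency
})

test_that("impossible placements raise a placement error", {
  expect_error(generate_scene(scene_spec(size_px = c(60, 60), n_heads = 100,
                                         seed = 1), max_retries = 5),
               "placement")
})

test_that("scene files round-trip through the io layer", {
  sc <- generate_scene(scene_spec(size_px = c(80, 60), seed = 9))
  d <- tempfile()
  paths <- write_scene(sc, d)
  img <- read_scene_image(paths["image"])
  expect_equal(dim(img), dim(sc$image))
  expect_equal(img, sc$image, tolerance = 1 / 255)
  masks <- read_roi_mask(paths["mask"])
  expect_equal(masks$head, sc$head_mask)
  expect_equal(masks$body, sc$body_mask)
})

test_that("gaze_sim_spec validates its weights", {
  expect_error(gaze_sim_spec(preference_weights = c(head = 0.7, body = 0.2,
                                                    low_sal = 0.2,
                                                    high_sal = 0.1)),
               "sum to 1")
  expect_error(gaze_sim_spec(preference_weights = c(head = 1.2, body = -0.2,
                                                    low_sal = 0, high_sal = 0)),
               "nonnegative")
})

test_that("a pure head preference lands every scene fixation on a head", {
  ps <- tiny_prepared_scene()
  sim <- quiet_sim(preference_weights = c(head = 1, body = 0, low_sal = 0,
                                          high_sal = 0),
                   saccade_min_amp_deg = 0.2)
  tr <- simulate_trial(ps$roiset, tiny_meta(), sim, ref_geom(), seed = 3)
  fx <- tr$truth[tr$truth$type == "fixation" & !is.na(tr$truth$roi), ]
  expect_gt(nrow(fx), 5)
  expect_true(all(fx$roi == "head"))
  h <- nrow(ps$roiset$labels)
  for (i in seq_len(nrow(fx))) {
    expect_equal(ps$roiset$labels[fx$y_px[i] + 1, fx$x_px[i] + 1], "head")
  }
})

test_that("nonzero weight on an empty category is a simulation error", {
  lab <- matrix("low_sal", 50, 50)   # no heads anywhere
  sim <- quiet_sim()
  expect_error(simulate_trial(lab, tiny_meta(size = c(50, 50)), sim,
                              ref_geom(), seed = 1),
               "simulation error")
})

test_that("planted drift appears in the pre-stimulus baseline", {
  ps <- tiny_prepared_scene()
  sim <- gaze_sim_spec(noise_sd_px = 0.2, drift_sd_px = 0, blink_rate_hz = 0)
  tr <- simulate_trial(ps$roiset, tiny_meta(), sim, ref_geom(), seed = 6)
  tr$recording$samples$x_px <- tr$recording$samples$x_px + 10
  tr$recording$samples$y_px <- tr$recording$samples$y_px - 5
  b <- compute_baseline(tr$recording, 2000)
  meta <- tiny_meta()
  expect_equal(b$bx_px - meta$cross_x_px, 10, tolerance = 0.5)
  expect_equal(b$by_px - meta$cross_y_px, -5, tolerance = 0.5)
})

test_that("ground-truth velocities straddle the detection threshold", {
  ps <- tiny_prepared_scene()
  tr <- simulate_trial(ps$roiset, tiny_meta(), quiet_sim(), ref_geom(),
                       seed = 11)
  ev <- detect_events(tr$recording, ref_geom())
  expect_true(all(ev$saccades$peak_velocity_deg_s > 30))
  # noiseless recall is exact, so fixation-phase velocities stayed below
  expect_equal(nrow(ev$saccades), sum(tr$truth$type == "saccade"))
})

test_that("blinks are flagged invalid, never silently dropped", {
  ps <- tiny_prepared_scene()
  sim <- gaze_sim_spec(blink_rate_hz = 0.5)
  tr <- simulate_trial(ps$roiset, tiny_meta(), sim, ref_geom(), seed = 8)
  s <- tr$recording$samples
  expect_gt(sum(!s$valid), 0)
  expect_true(all(is.na(s$x_px[!s$valid])))
  expect_equal(nrow(s), 12000)
})

test_that("dataset layout counts and determinism hold end to end", {
  scenes <- lapply(1:2, function(i) {
    prepare_scene(generate_scene(scene_spec(size_px = c(160, 120),
                                            seed = 40 + i)))
  })
  ds1 <- simulate_dataset(2, scenes, tasks = c("free", "count"), seed = 5)
  expect_length(ds1$trials, 2 * 2 * 2)
  expect_equal(nrow(ds1$meta), 8)
  ds2 <- simulate_dataset(2, scenes, tasks = c("free", "count"), seed = 5)
  expect_identical(ds1$meta, ds2$meta)
  expect_identical(ds1$trials[[5]]$recording$samples,
                   ds2$trials[[5]]$recording$samples)
  an1 <- analyze_dataset(ds1, windows = "pre")
  an2 <- analyze_dataset(ds2, windows = "pre")
  expect_identical(an1$density, an2$density)
  # count tasks carry simulated clicks; free never does
  expect_true(all(is.na(ds1$meta$click_time_ms[ds1$meta$task == "free"])))
  expect_gt(sum(!is.na(ds1$meta$click_time_ms[ds1$meta$task == "count"])), 0)
})

test_that("stronger head preference yields a larger recovered head score", {
  scenes <- lapply(1:3, function(i) {
    prepare_scene(generate_scene(scene_spec(size_px = c(160, 120),
                                            seed = 60 + i)))
  })
  mk <- function(w_head, seed) {
    rest <- (1 - w_head) / 3
    sim <- gaze_sim_spec(preference_weights = c(head = w_head, body = rest,
                                                low_sal = rest,
                                                high_sal = rest))
    ds <- simulate_dataset(6, scenes, tasks = "free", sim = sim, seed = seed)
    an <- analyze_dataset(ds, windows = "pre")
    s <- summarize_roi_preference(an, "pre")
    s$mean_normalized[s$roi == "head"]
  }
  expect_gt(mk(0.6, 19), mk(0.2, 19))
})
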