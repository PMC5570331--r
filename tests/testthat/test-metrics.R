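test_that("uniform density gives area-normalized score 1 for every category", {
  set.seed(21)
  vals <- matrix(runif(400), 20, 20)
  head <- matrix(FALSE, 20, 20); head[2:5, 3:8] <- TRUE
  body <- matrix(FALSE, 20, 20); body[12:18, 12:19] <- TRUE
  rs <- build_roiset(vals, list(head = head, body = body))
  uni <- matrix(1, 20, 20)
  sc <- roi_density_score(uni, rs)
  expect_equal(sc$normalized, rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(sc$raw), 1, tolerance = 1e-9)
})

test_that("density concentrated in one ROI scores raw 1 and the area ratio", {
  vals <- matrix(runif(100), 10, 10)
  head <- matrix(FALSE, 10, 10); head[1:2, 1:5] <- TRUE   # 10% of the image
  rs <- build_roiset(vals, list(head = head))
  dens <- matrix(0, 10, 10); dens[head] <- 0.7
  sc <- roi_density_score(dens, rs)
  expect_equal(sc$raw[sc$roi == "head"], 1)
  expect_equal(sc$normalized[sc$roi == "head"], 10)
})

test_that("all-zero maps and empty ROIs report missing values", {
  vals <- matrix(runif(100), 10, 10)
  rs <- build_roiset(vals)   # no social mask: head empty
  sc <- roi_density_score(matrix(0, 10, 10), rs)
  expect_true(all(is.na(sc$raw)))
  sc2 <- roi_density_score(matrix(1, 10, 10), rs)
  expect_true(is.na(sc2$normalized[sc2$roi == "head"]))
})

test_that("count scores put one fixation per category at raw 0.25", {
  set.seed(44)
  vals <- matrix(runif(100), 10, 10)   # distinct values: all 4 categories occupied
  head <- matrix(FALSE, 10, 10); head[1:3, 1:3] <- TRUE
  body <- matrix(FALSE, 10, 10); body[8:10, 8:10] <- TRUE
  rs <- build_roiset(vals, list(head = head, body = body))
  pick <- function(cat) {
    i <- rs$idx[[cat]][1]
    c((i - 1) %/% 10, (i - 1) %% 10)
  }
  pts <- vapply(roi_categories(), pick, numeric(2))
  fx <- data.frame(onset_ms = 1:4, offset_ms = 2:5, duration_ms = 1,
                   x_px = pts[1, ], y_px = pts[2, ], corrected = TRUE)
  sc <- fixation_count_score(fx, rs)
  expect_equal(sc$raw, rep(0.25, 4))
})

test_that("count and density scores agree for equal durations as sigma -> 0", {
  set.seed(9)
  vals <- matrix(runif(900), 30, 30)
  rs <- build_roiset(vals)
  fx <- data.frame(onset_ms = seq(0, 900, 100), offset_ms = seq(100, 1000, 100),
                   duration_ms = 100,
                   x_px = sample(2:27, 10), y_px = sample(2:27, 10),
                   corrected = TRUE)
  dm <- build_density_map(fx, size = c(30, 30), sigma_px = 0.05,
                          discard_first = FALSE, normalize = FALSE)
  d_sc <- roi_density_score(dm, rs)
  c_sc <- fixation_count_score(fx, rs)
  expect_equal(d_sc$raw, c_sc$raw, tolerance = 1e-6)
})

test_that("uniform random fixations approach normalized scores of 1", {
  set.seed(61)
  vals <- matrix(runif(40 * 30), 30, 40)
  head <- matrix(FALSE, 30, 40); head[5:14, 5:14] <- TRUE
  body <- matrix(FALSE, 30, 40); body[20:29, 25:36] <- TRUE
  rs <- build_roiset(vals, list(head = head, body = body))
  n <- 12000
  fx <- data.frame(onset_ms = seq_len(n), offset_ms = seq_len(n) + 1,
                   duration_ms = 1,
                   x_px = sample(0:39, n, replace = TRUE),
                   y_px = sample(0:29, n, replace = TRUE), corrected = TRUE)
  sc <- fixation_count_score(fx, rs)
  # Monte-Carlo tolerance: binomial SE on the smallest category (~8%)
  expect_true(all(abs(sc$normalized - 1) < 0.2))
})

test_that("first-fixation frequencies recover a degenerate preference", {
  ps <- tiny_prepared_scene()
  lab <- ps$roiset$labels
  i_head <- ps$roiset$idx[["head"]][1]
  h <- nrow(lab)
  fx <- data.frame(onset_ms = 0, offset_ms = 100, duration_ms = 100,
                   x_px = (i_head - 1) %/% h, y_px = (i_head - 1) %% h,
                   corrected = TRUE)
  ff <- first_fixation_frequencies(list(fx, fx, fx),
                                   list(ps$roiset, ps$roiset, ps$roiset),
                                   n_fix = 1)
  expect_equal(ff$freq[ff$roi == "head"], 1)
  expect_equal(ff$freq[ff$roi == "body"], 0)
  # with a single fixation per trial, index 2 would be all-missing
  ff2 <- first_fixation_frequencies(list(fx), list(ps$roiset), n_fix = 2)
  expect_true(all(is.na(ff2$freq[ff2$fix_index == 2])))
})

test_that("uniformly landing first fixations give normalized frequencies near 1", {
  set.seed(14)
  vals <- matrix(runif(40 * 30), 30, 40)
  head <- matrix(FALSE, 30, 40); head[3:20, 4:20] <- TRUE
  body <- matrix(FALSE, 30, 40); body[22:29, 22:39] <- TRUE
  rs <- build_roiset(vals, list(head = head, body = body))
  trials <- lapply(1:4000, function(i) {
    data.frame(onset_ms = 0, offset_ms = 100, duration_ms = 100,
               x_px = sample(0:39, 1), y_px = sample(0:29, 1),
               corrected = TRUE)
  })
  ff <- first_fixation_frequencies(trials, rep(list(rs), 4000), n_fix = 1)
  # uniform-sampling oracle: freq ~ area share, so normalized ~ 1
  se <- sqrt(0.1 * 0.9 / 4000) / 0.1   # worst-case relative SE ~ 5%
  expect_true(all(abs(ff$normalized - 1) < 4 * se))
})

test_that("per-component normalization divides by the component count", {
  vals <- matrix(runif(400), 20, 20)
  head <- matrix(FALSE, 20, 20)
  head[2:4, 2:4] <- TRUE; head[10:12, 10:12] <- TRUE   # two components
  rs <- build_roiset(vals, list(head = head))
  sc <- roi_density_score(matrix(1, 20, 20), rs)
  pc <- per_component_score(sc, rs)
  expect_equal(pc$normalized_per_roi[pc$roi == "head"],
               pc$normalized[pc$roi == "head"] / 2)
})

test_that("reaction times follow the click-else-presentation rule", {
  m1 <- trial_meta("s", "i", "count", "social", 1000, click_time_ms = 4200)
  m2 <- trial_meta("s", "i", "free", "social", 1000)
  m3 <- trial_meta("s", "i", "count", "social", 1000, click_time_ms = 1000)
  expect_equal(reaction_time(m1), 3200)
  expect_equal(reaction_time(m2), 10000)
  expect_equal(reaction_time(m3), 0)
})
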