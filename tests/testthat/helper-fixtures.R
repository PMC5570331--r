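# Shared fixtures, all built in code at test time.

ref_geom <- function() screen_geometry(516.9, 323.1, 1920, 1200, 500)

# small scene + saliency + partition, cached per test run
tiny_prepared_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- generate_scene(scene_spec(size_px = c(160, 120), n_heads = 2,
                                      n_bodies = 2, n_distractors = 4,
                                      seed = 71))
      cache <<- prepare_scene(sc)
    }
    cache
  }
})

tiny_meta <- function(task = "free", onset = 2000, click = NA,
                      size = c(160, 120)) {
  trial_meta("S01", "I01", task, "social", stimulus_onset_ms = onset,
             click_time_ms = click,
             cross_position_px = c((size[1] - 1) / 2, (size[2] - 1) / 2))
}

quiet_sim <- function(...) {
  gaze_sim_spec(noise_sd_px = 0, drift_sd_px = 0, blink_rate_hz = 0, ...)
}

# independent step-by-step oracle of the recursive outlier procedure,
# written directly from its verbal description
ror_oracle <- function(v, k = 3) {
  vals <- v[!is.na(v)]
  repeat {
    if (length(vals) < 3) break
    hi <- which.max(vals); lo <- which.min(vals)
    tmp <- vals[-unique(c(hi, lo))]
    if (length(tmp) < 2) break
    m <- mean(tmp)
    s <- sqrt(sum((tmp - m)^2) / (length(tmp) - 1))
    removed_any <- FALSE
    drop <- logical(length(vals))
    for (i in unique(c(hi, lo))) {
      if (abs(vals[i] - m) > k * s) { drop[i] <- TRUE; removed_any <- TRUE }
    }
    vals <- vals[!drop]
    if (!removed_any) break
  }
  vals
}

# dense eigenvector oracle for the chain equilibrium
eigen_equilibrium <- function(W, teleport = 1e-6) {
  n <- nrow(W)
  rs <- rowSums(W)
  P <- W
  P[rs > 0, ] <- P[rs > 0, , drop = FALSE] / rs[rs > 0]
  P[rs == 0, ] <- 1 / n
  P <- (1 - teleport) * P + teleport / n
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
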