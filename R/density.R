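#' Discard the trial-initial fixation
#'
#' The first fixation whose onset follows stimulus onset is removed once per
#' trial: it usually continues the pre-stimulus fixation of the central
#' cross and carries no scene-driven information. Applied before any
#' pre/post-response split.
#'
#' @param fixations Fixation data frame (time-ordered).
#' @param onset_ms Stimulus onset time; fixations at or after this time are
#'   candidates (a fixation spanning the onset also counts as the initial
#'   one).
#' @return The fixations without the trial-initial one.
#' @export
discard_first_fixation <- function(fixations, onset_ms = -Inf) {
  if (!nrow(fixations)) return(fixations)
  cand <- which(fixations$offset_ms > onset_ms)
  if (length(cand)) fixations <- fixations[-cand[1], , drop = FALSE]
  fixations
}

#' Split fixations at the response click
#'
#' Fixations ending before the click belong to the task-relevant (pre)
#' window, fixations starting after it to the task-irrelevant (post)
#' window; a fixation spanning the click is split into two events at the
#' click, durations apportioned. With no click (free viewing) everything is
#' pre: the task-relevant window is the whole presentation.
#'
#' @param fixations Time-ordered fixation data frame.
#' @param click_ms Click time or `NA`.
#' @return List with data frames `pre` and `post`.
#' @export
split_by_response <- function(fixations, click_ms = NA) {
  if (is.na(click_ms) || !nrow(fixations)) {
    return(list(pre = fixations, post = fixations[0, , drop = FALSE]))
  }
  pre <- fixations[fixations$offset_ms <= click_ms, , drop = FALSE]
  post <- fixations[fixations$onset_ms >= click_ms, , drop = FALSE]
  span <- fixations$onset_ms < click_ms & fixations$offset_ms > click_ms
  if (any(span)) {
    sp <- fixations[span, , drop = FALSE]
    a <- sp; a$offset_ms <- click_ms; a$duration_ms <- click_ms - a$onset_ms
    b <- sp; b$onset_ms <- click_ms; b$duration_ms <- b$offset_ms - click_ms
    pre <- rbind(pre, a); post <- rbind(b, post)
  }
  pre <- pre[order(pre$onset_ms), , drop = FALSE]
  post <- post[order(post$onset_ms), , drop = FALSE]
  list(pre = pre, post = post)
}

#' Duration-weighted, Gaussian-smoothed fixation density map
#'
#' Starts from a zero grid of the scene size, adds each retained fixation's
#' duration (ms) at its rounded pixel position, convolves with an isotropic
#' Gaussian (SD `sigma_px`, truncated at 4 SD, no boundary renormalization:
#' mass falling off-image is lost), and divides by the grid maximum so the
#' map ranges from 0 to 1.
#'
#' Fixation positions use the 0-based pixel convention. Fixations whose
#' kernel support lies wholly off-grid contribute nothing and are counted in
#' the `n_dropped_offgrid` diagnostic.
#'
#' @param fixations Corrected fixation data frame.
#' @param size Scene size as `c(width, height)` in px (default 1200 x 900).
#' @param sigma_px Gaussian SD in px (default 36, about 1 degree on the
#'   reference setup).
#' @param discard_first Drop the first fixation of the supplied set
#'   (default `TRUE`; set `FALSE` when [discard_first_fixation()] was
#'   already applied at the trial level).
#' @param normalize Divide by the maximum (default `TRUE`); `FALSE` returns
#'   the raw duration-weighted smoothed grid.
#' @return An object of class `density_map`: list with `values`
#'   (height x width matrix), `n_fixations_used`, `n_dropped_offgrid`.
#' @export
build_density_map <- function(fixations, size = c(1200, 900), sigma_px = 36,
                              discard_first = TRUE, normalize = TRUE) {
  w <- size[1]; h <- size[2]
  stopifnot(w > 0, h > 0)
  if (discard_first && nrow(fixations)) {
    fixations <- fixations[-1, , drop = FALSE]
  }
  grid <- matrix(0, h, w)
  taps <- gauss_taps(sigma_px, trunc = 4)
  r <- (length(taps) - 1) / 2
  dropped <- 0L
  used <- 0L
  for (i in seq_len(nrow(fixations))) {
    cx <- round(fixations$x_px[i])
    cy <- round(fixations$y_px[i])
    xs <- (cx - r):(cx + r)   # 0-based pixel coordinates under the kernel
    ys <- (cy - r):(cy + r)
    inx <- xs >= 0 & xs <= w - 1
    iny <- ys >= 0 & ys <= h - 1
    if (!any(inx) || !any(iny)) {
      dropped <- dropped + 1L
      next
    }
    patch <- fixations$duration_ms[i] * outer(taps[iny], taps[inx])
    grid[ys[iny] + 1, xs[inx] + 1] <- grid[ys[iny] + 1, xs[inx] + 1] + patch
    used <- used + 1L
  }
  if (normalize) {
    mx <- max(grid)
    if (mx > 0) grid <- grid / mx
  }
  structure(list(values = grid, n_fixations_used = used,
                 n_dropped_offgrid = dropped, sigma_px = sigma_px),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d px, %d fixations used, max %.3f\n",
              ncol(x$values), nrow(x$values), x$n_fixations_used,
              max(x$values)))
  invisible(x)
}
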