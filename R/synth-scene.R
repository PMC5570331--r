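#' Specification of a synthetic scene
#'
#' Describes the stand-in stimuli used throughout testing: a textured
#' background with planted "social" regions (heads and bodies) and
#' high-contrast non-social distractor blobs, so the saliency stage has
#' genuine luminance/color structure to work with.
#'
#' @param size_px Scene size as `c(width, height)` (default 1200 x 900).
#' @param n_heads,n_bodies Numbers of planted heads/bodies (defaults 6 each,
#'   matching the magnitude of social regions in naturalistic scene sets).
#' @param n_distractors Number of non-social blobs (default 8).
#' @param head_radius_frac Head radius as a fraction of image width
#'   (default 0.03).
#' @param distractor_radius_frac Distractor radius fraction (default 0.045).
#' @param seed Integer seed making the scene deterministic.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(size_px = c(1200, 900), n_heads = 6, n_bodies = 6,
                       n_distractors = 8, head_radius_frac = 0.03,
                       distractor_radius_frac = 0.045, seed = 1) {
  stopifnot(length(size_px) == 2, all(size_px > 0),
            n_heads >= 0, n_bodies >= 0, n_distractors >= 0)
  structure(list(size_px = size_px, n_heads = n_heads, n_bodies = n_bodies,
                 n_distractors = n_distractors,
                 head_radius_frac = head_radius_frac,
                 distractor_radius_frac = distractor_radius_frac,
                 seed = seed),
            class = "scene_spec")
}

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic scene with planted social regions
#'
#' Deterministic for a fixed seed: two calls with the same spec return
#' byte-identical images and masks. Placement is rejection sampling with
#' bounded retries; if the requested regions cannot be placed without
#' overlap a placement error is raised.
#'
#' @param spec A [scene_spec()].
#' @param max_retries Placement attempts per region (default 200).
#' @return A list of class `scene`: `image` (h x w x 3 array in `[0, 1]`),
#'   `head_mask`, `body_mask` (logical h x w matrices) and `spec`.
#' @export
generate_scene <- function(spec = scene_spec(), max_retries = 200) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec, max_retries))
}

generate_scene_impl <- function(spec, max_retries) {
  w <- spec$size_px[1]; h <- spec$size_px[2]
  xg <- matrix(rep(0:(w - 1), each = h), h, w)   # 0-based pixel centers
  yg <- matrix(rep(0:(h - 1), times = w), h, w)

  # mid-gray background with smooth low-contrast luminance texture
  base <- 0.45 + 0.08 * sin(2 * pi * xg / (w / 3) + stats::runif(1, 0, 2 * pi)) *
    cos(2 * pi * yg / (h / 3) + stats::runif(1, 0, 2 * pi))
  img <- array(rep(base, 3), c(h, w, 3))

  occupied <- matrix(FALSE, h, w)
  head_mask <- matrix(FALSE, h, w)
  body_mask <- matrix(FALSE, h, w)

  place <- function(rx, ry) {
    # returns center of a free ellipse of radii (rx, ry), or NULL
    for (i in seq_len(max_retries)) {
      cx <- stats::runif(1, rx + 2, w - rx - 3)
      cy <- stats::runif(1, ry + 2, h - ry - 3)
      m <- ((xg - cx) / (rx + 2))^2 + ((yg - cy) / (ry + 2))^2 <= 1
      if (!any(m & occupied)) return(list(cx = cx, cy = cy))
    }
    NULL
  }
  paint <- function(m, col, soften = TRUE) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- col[ch]
      img[, , ch] <<- plane
    }
  }
  ellipse <- function(cx, cy, rx, ry) {
    ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
  }

  rh <- max(3, spec$head_radius_frac * w)
  for (i in seq_len(spec$n_heads)) {
    p <- place(rh, rh * 1.15)
    if (is.null(p)) stop("placement error: could not place head ", i,
                         " without overlap")
    m <- ellipse(p$cx, p$cy, rh, rh * 1.15)
    # skin-like tone with slight per-head variation
    paint(m, c(0.85, 0.65, 0.5) + stats::runif(3, -0.05, 0.05))
    head_mask <- head_mask | m
    occupied <- occupied | m
  }
  rb <- rh * 1.6
  for (i in seq_len(spec$n_bodies)) {
    p <- place(rb, rb * 1.8)
    if (is.null(p)) stop("placement error: could not place body ", i,
                         " without overlap")
    m <- ellipse(p$cx, p$cy, rb, rb * 1.8)
    paint(m, c(0.35, 0.35, 0.55) + stats::runif(3, -0.05, 0.05))
    body_mask <- body_mask | m
    occupied <- occupied | m
  }
  rd <- max(3, spec$distractor_radius_frac * w)
  palette <- list(c(1, 0.1, 0.1), c(0.1, 0.3, 1), c(1, 0.9, 0.1),
                  c(0.05, 0.05, 0.05), c(1, 1, 1), c(0.1, 0.8, 0.2))
  for (i in seq_len(spec$n_distractors)) {
    r1 <- rd * stats::runif(1, 0.6, 1.4)
    p <- place(r1, r1)
    if (is.null(p)) stop("placement error: could not place distractor ", i,
                         " without overlap")
    m <- ellipse(p$cx, p$cy, r1, r1)
    paint(m, palette[[(i - 1) %% length(palette) + 1]])
    occupied <- occupied | m
  }
  structure(list(image = img, head_mask = head_mask, body_mask = body_mask,
                 spec = spec),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d x %d px, %d head px, %d body px (seed %d)\n",
              ncol(x$image), nrow(x$image), sum(x$head_mask),
              sum(x$body_mask), x$spec$seed))
  invisible(x)
}

#' Write a synthetic scene to disk in the pipeline's input formats
#'
#' Scene as PNG, masks as a color-coded PNG plus sidecar color table, so
#' the analysis pipeline cannot tell synthetic from real input.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"scene"`).
#' @return Named character vector of paths written, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_mask.png"))
  write_scene_image(scene$image, img_path)
  write_roi_mask(list(head = scene$head_mask, body = scene$body_mask),
                 mask_path)
  invisible(c(image = img_path, mask = mask_path))
}
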