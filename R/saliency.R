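#' Saliency map container
#'
#' @param values Matrix of per-pixel saliency in `[0, 1]`, same dimensions as
#'   the source image.
#' @param uniform Logical flag: `TRUE` when the source image was constant and
#'   the map is a degenerate all-zero grid.
#' @param channel_maps Optional list of per-channel activation matrices kept
#'   for diagnostics.
#' @return An object of class `saliency_map`.
#' @export
saliency_map <- function(values, uniform = FALSE, channel_maps = NULL) {
  structure(list(values = values, uniform = uniform,
                 channel_maps = channel_maps),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map: %d x %d px, range [%.3f, %.3f]%s\n",
              ncol(x$values), nrow(x$values), min(x$values), max(x$values),
              if (x$uniform) " (degenerate uniform input)" else ""))
  invisible(x)
}

#' Multi-scale low-level feature maps of a scene
#'
#' Decomposes an RGB image into the classic pre-attentive channels:
#' intensity (mean of R, G, B), color opponency (red-green and blue-yellow
#' contrast), and orientation (even Gabor energy at 0, 45, 90 and 135
#' degrees). Each map is computed at `scales` pyramid levels (successive
#' Gaussian blurs) and downsampled to the working resolution on which the
#' graph stage operates.
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param channels Subset of `c("intensity", "color", "orientation")`.
#' @param scales Number of pyramid levels (>= 1).
#' @param work_dim Working resolution as `c(width, height)`; default 32 x 24
#'   preserves the 4:3 aspect of the reference stimuli.
#' @return Named list of feature matrices at working resolution; names are
#'   `<channel>[.<subchannel>].s<scale>`.
#' @export
compute_feature_maps <- function(image,
                                 channels = c("intensity", "color", "orientation"),
                                 scales = 2, work_dim = c(32, 24)) {
  channels <- match.arg(channels, c("intensity", "color", "orientation"),
                        several.ok = TRUE)
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) stop("image must be an RGB array")
  if (d[1] < work_dim[2] || d[2] < work_dim[1]) {
    stop(sprintf("image (%d x %d) smaller than working resolution (%d x %d)",
                 d[2], d[1], work_dim[1], work_dim[2]))
  }
  wh <- work_dim[2]; ww <- work_dim[1]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  out <- list()
  base <- list(r = r, g = g, b = b)
  for (s in seq_len(scales)) {
    if (s > 1) base <- lapply(base, gauss_blur, sigma = 2^(s - 1))
    rw <- resize_to(base$r, wh, ww)
    gw <- resize_to(base$g, wh, ww)
    bw <- resize_to(base$b, wh, ww)
    inten <- (rw + gw + bw) / 3
    if ("intensity" %in% channels) {
      out[[sprintf("intensity.s%d", s)]] <- inten
    }
    if ("color" %in% channels) {
      # broadly tuned opponency, normalised by local intensity where sensible
      out[[sprintf("color.rg.s%d", s)]] <- abs(rw - gw)
      out[[sprintf("color.by.s%d", s)]] <- abs(bw - (rw + gw) / 2)
    }
    if ("orientation" %in% channels) {
      for (th in c(0, 45, 90, 135)) {
        k <- gabor_kernel(th)
        out[[sprintf("orientation.%d.s%d", th, s)]] <-
          abs(conv2_same(inten, k))
      }
    }
  }
  out
}

#' Stationary distribution of a row-normalized Markov chain
#'
#' Given a nonnegative weight matrix over map locations, row-normalizes it
#' into a transition matrix (with a tiny uniform teleportation mass to
#' guarantee irreducibility) and returns the equilibrium distribution by
#' power iteration.
#'
#' @param weights Nonnegative square matrix of edge weights.
#' @param tol Convergence tolerance on the max-norm change (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @param teleport Uniform teleportation mass (default 1e-6).
#' @return Probability vector: nonnegative, sums to 1 within `tol`.
#' @export
markov_equilibrium <- function(weights, tol = 1e-10, max_iter = 10000,
                               teleport = 1e-6) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  n <- nrow(weights)
  if (n == 1) return(1)
  rs <- rowSums(weights)
  P <- weights
  zero <- rs == 0
  P[!zero, ] <- P[!zero, , drop = FALSE] / rs[!zero]
  if (any(zero)) P[zero, ] <- 1 / n
  # teleportation keeps the chain irreducible and aperiodic
  tP <- t((1 - teleport) * P)
  pi_v <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    nxt <- as.vector(tP %*% pi_v) + teleport / n
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_v)) < tol) return(nxt)
    pi_v <- nxt
  }
  stop("markov_equilibrium: power iteration failed to converge; ",
       sprintf("last residual %.3g after %d iterations",
               max(abs(nxt - pi_v)), max_iter))
}

# Pairwise squared grid distances for an h x w working grid (column-major
# over [row, col] like as.vector of a matrix).
grid_dist2 <- function(h, w) {
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  outer(ys, ys, "-")^2 + outer(xs, xs, "-")^2
}

# Feature dissimilarity: |log ratio| where both values are safely positive,
# absolute difference otherwise (orientation/color maps touch zero).
feature_dissimilarity <- function(f, eps = 1e-8) {
  v <- as.vector(f)
  if (all(v > eps)) {
    lv <- log(v)
    abs(outer(lv, lv, "-"))
  } else {
    abs(outer(v, v, "-"))
  }
}

#' Graph-based visual saliency map
#'
#' Computes a conspicuity map in `[0, 1]` by the graph-based scheme: per
#' feature map a fully connected graph over working-resolution locations is
#' built with edge weights `dissimilarity x Gaussian falloff in grid
#' distance`; the activation is the Markov-chain equilibrium of that graph.
#' A second (concentration) pass re-weights edges by the target node's
#' activation and takes the equilibrium again, which sharpens mass onto
#' conspicuous locations. Channel maps are summed, upsampled bilinearly to
#' image size, and min-max normalized.
#'
#' An Itti-Koch-style center-surround alternative is available behind the
#' same interface via `method = "itti"`; the graph method is the default
#' analysis path.
#'
#' @inheritParams compute_feature_maps
#' @param sigma_frac Gaussian falloff SD as a fraction of the working grid
#'   width (default 1/8).
#' @param method `"gbvs"` (default) or `"itti"`.
#' @param keep_channels Keep per-channel maps for diagnostics.
#' @return A [saliency_map()]. Constant images yield an all-zero map with
#'   `uniform = TRUE` and a warning.
#' @export
compute_saliency <- function(image,
                             channels = c("intensity", "color", "orientation"),
                             scales = 2, work_dim = c(32, 24),
                             sigma_frac = 1 / 8, method = c("gbvs", "itti"),
                             keep_channels = FALSE) {
  method <- match.arg(method)
  d <- dim(image)
  fmaps <- compute_feature_maps(image, channels = channels, scales = scales,
                                work_dim = work_dim)
  spreads <- vapply(fmaps, function(f) diff(range(f)), numeric(1))
  if (all(spreads < 1e-12)) {
    warning("constant image: returning a uniform all-zero saliency map")
    return(saliency_map(matrix(0, d[1], d[2]), uniform = TRUE))
  }
  if (method == "itti") {
    work <- itti_fuse(fmaps, work_dim)
  } else {
    work <- gbvs_fuse(fmaps, work_dim, sigma_frac)
  }
  up <- resize_bilinear(work, d[1], d[2])
  rng <- range(up)
  vals <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else matrix(0, d[1], d[2])
  saliency_map(vals, uniform = FALSE,
               channel_maps = if (keep_channels) fmaps else NULL)
}

gbvs_fuse <- function(fmaps, work_dim, sigma_frac) {
  wh <- work_dim[2]; ww <- work_dim[1]
  sigma <- sigma_frac * ww
  fall <- exp(-grid_dist2(wh, ww) / (2 * sigma^2))
  channel_of <- sub("\\..*$", "", names(fmaps))
  acts <- list()
  for (ch in unique(channel_of)) {
    a_sum <- 0
    for (nm in names(fmaps)[channel_of == ch]) {
      f <- fmaps[[nm]]
      if (diff(range(f)) < 1e-12) next   # flat map carries no graph signal
      W <- feature_dissimilarity(f) * fall
      a_sum <- a_sum + markov_equilibrium(W)
    }
    if (identical(a_sum, 0)) next
    # concentration pass: edges weighted by target-node activation
    W2 <- fall * rep(a_sum, each = length(a_sum))
    conc <- markov_equilibrium(W2)
    acts[[ch]] <- matrix(conc, wh, ww)
  }
  Reduce(`+`, acts)
}

# Center-surround fallback: difference of fine and coarse scales per channel.
itti_fuse <- function(fmaps, work_dim) {
  wh <- work_dim[2]; ww <- work_dim[1]
  total <- matrix(0, wh, ww)
  channel_of <- sub("\\.s[0-9]+$", "", names(fmaps))
  for (ch in unique(channel_of)) {
    maps <- fmaps[channel_of == ch]
    for (m in maps) {
      cs <- abs(m - gauss_blur(m, sigma = 3))
      rng <- range(cs)
      if (diff(rng) > 0) total <- total + (cs - rng[1]) / diff(rng)
    }
  }
  total
}

#' Scene-level saliency summary
#'
#' @param map A [saliency_map()].
#' @return Named numeric vector `c(mean, sd)` over all pixels (SD uses the
#'   conventional `n - 1` denominator).
#' @export
scene_saliency_summary <- function(map) {
  stopifnot(inherits(map, "saliency_map"))
  v <- as.vector(map$values)
  c(mean = mean(v), sd = stats::sd(v))
}
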