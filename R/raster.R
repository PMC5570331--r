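# data.frame constructor without the per-call deparse/row-name overhead;
# used on hot per-trial paths where thousands of small frames are built.
fast_df <- function(...) {
  l <- list(...)
  structure(l, class = "data.frame",
            row.names = c(NA_integer_, -length(l[[1]])))
}

# Small raster utilities shared by the saliency and density modules.
# Matrices are indexed [row = y, col = x]; pixel coordinates in the public
# API are 0-based with the origin at the top-left and centers on integers.

# Bilinear resize of a matrix to new dimensions.
resize_bilinear <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == new_h && w == new_w) return(m)
  # map target pixel centers into source coordinates (align centers)
  ys <- (seq_len(new_h) - 0.5) * h / new_h - 0.5
  xs <- (seq_len(new_w) - 0.5) * w / new_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ys - y0; fy[fy < 0] <- 0
  fx <- xs - x0; fx[fx < 0] <- 0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  d <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a + b + c_ + d
}

# Block-mean downsample (anti-aliased) used when shrinking feature maps;
# falls back to bilinear when the ratio is not integral.
resize_area <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  if (h %% new_h == 0 && w %% new_w == 0) {
    fy <- h / new_h; fx <- w / new_w
    gy <- rep(seq_len(new_h), each = fy)
    gx <- rep(seq_len(new_w), each = fx)
    t(rowsum(t(rowsum(m, gy)), gx)) / (fy * fx)
  } else {
    resize_bilinear(m, new_h, new_w)
  }
}

resize_to <- function(m, new_h, new_w) {
  if (new_h <= nrow(m) && new_w <= ncol(m)) resize_area(m, new_h, new_w)
  else resize_bilinear(m, new_h, new_w)
}

# 2-D convolution, "same" size, edge-replicate padding (zero padding would
# fabricate contrast at the borders of otherwise uniform images); kernels
# are small so the shift-and-add formulation is adequate at working
# resolutions.
conv2_same <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  h <- nrow(m); w <- ncol(m)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  yi <- pmin(pmax(seq_len(h + kh - 1) - ry, 1), h)
  xi <- pmin(pmax(seq_len(w + kw - 1) - rx, 1), w)
  pad <- m[yi, xi, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] *
        pad[(kh - i) + seq_len(h), (kw - j) + seq_len(w), drop = FALSE]
    }
  }
  out
}

# 1-D Gaussian taps truncated at `trunc` SDs, not renormalised.
gauss_taps <- function(sigma, trunc = 4) {
  r <- ceiling(trunc * sigma)
  x <- (-r):r
  exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

# Separable Gaussian blur (edge-replicate padding), used to build pyramid
# levels.
gauss_blur <- function(m, sigma, trunc = 3) {
  taps <- gauss_taps(sigma, trunc)
  taps <- taps / sum(taps)
  k <- length(taps); r <- (k - 1) / 2
  blur1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], r), v, rep(v[n], r))
    out <- numeric(n)
    for (i in seq_len(k)) out <- out + taps[i] * padded[i + seq_len(n) - 1]
    out
  }
  t(apply(t(apply(m, 1, blur1)), 1, blur1))
}

# Odd-sized even (cosine) Gabor kernel, zero mean, for orientation channels.
gabor_kernel <- function(theta_deg, wavelength = 4, sigma = 2, size = 9) {
  r <- (size - 1) / 2
  g <- expand.grid(x = (-r):r, y = (-r):r)
  th <- theta_deg * pi / 180
  xr <- g$x * cos(th) + g$y * sin(th)
  yr <- -g$x * sin(th) + g$y * cos(th)
  k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength)
  k <- matrix(k, size, size)
  k - mean(k)
}
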