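#' Four-way ROI partition of a scene
#'
#' Builds the mutually exclusive, jointly exhaustive label grid over
#' `{head, body, low_sal, high_sal}`. Head and body pixels are taken
#' verbatim from the social mask (head wins where hand-drawn masks overlap);
#' the saliency percentile is computed over the remaining pixels only (the
#' whole scene for non-social stimuli), and remaining pixels with saliency
#' less than or equal to the cutoff become `low_sal`, the rest `high_sal`.
#'
#' The percentile is the nearest-rank value on the sorted saliency values;
#' ties at the cutoff go to `low_sal` ("smaller or equal"). With a constant
#' saliency map every unmasked pixel is `low_sal`.
#'
#' @param saliency A [saliency_map()] (or plain matrix).
#' @param social_mask Optional named list of logical matrices `head`, `body`
#'   congruent with the saliency dimensions; `NULL` for non-social scenes.
#' @param q Percentile cutoff in percent (default 80: the lowest 80% of the
#'   saliency distribution is "low saliency").
#' @return An object of class `roi_set`: list with `labels` (factor matrix
#'   levels `head, body, low_sal, high_sal`), `areas` (named pixel counts)
#'   and the cutoff used.
#' @export
build_roiset <- function(saliency, social_mask = NULL, q = 80) {
  sal <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  h <- nrow(sal); w <- ncol(sal)
  lab <- matrix("", h, w)
  if (!is.null(social_mask)) {
    head <- social_mask$head
    body <- social_mask$body
    if (is.null(head)) head <- matrix(FALSE, h, w)
    if (is.null(body)) body <- matrix(FALSE, h, w)
    if (!all(dim(head) == c(h, w)) || !all(dim(body) == c(h, w))) {
      stop("social mask dimensions must match the saliency map")
    }
    body <- body & !head   # head has priority over body on overlap
    lab[head] <- "head"
    lab[body] <- "body"
  }
  rest <- lab == ""
  cutoff <- NA_real_
  if (any(rest)) {
    cutoff <- nearest_rank_percentile(sal[rest], q)
    lab[rest & sal <= cutoff] <- "low_sal"
    lab[rest & sal > cutoff] <- "high_sal"
  }
  roi_set(lab, q = q, cutoff = cutoff)
}

#' @rdname build_roiset
#' @export
roi_categories <- function() c("head", "body", "low_sal", "high_sal")

# labels is a character matrix over roi_categories(); stored as such so
# matrix subsetting keeps working (factors do not survive matrix()).
# Per-category pixel indices are precomputed: scoring sums reuse them on
# every trial of the same scene.
roi_set <- function(labels, q = NA, cutoff = NA) {
  idx <- lapply(roi_categories(), function(cat) which(labels == cat))
  names(idx) <- roi_categories()
  structure(list(labels = labels,
                 areas = vapply(idx, length, integer(1)),
                 idx = idx, q = q, cutoff = cutoff),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d x %d px, q = %s\n", ncol(x$labels), nrow(x$labels),
              format(x$q)))
  print(x$areas)
  invisible(x)
}

# Nearest-rank percentile: value at rank ceiling(q/100 * n) of the sorted
# sample (q = 0 maps to the minimum).
nearest_rank_percentile <- function(v, q) {
  n <- length(v)
  r <- max(1L, as.integer(ceiling(q / 100 * n)))
  sort(v, partial = r)[r]
}

#' Dissociate social ROIs by their own saliency distribution
#'
#' Within each social category (head, body), applies the same
#' nearest-rank less-or-equal percentile rule to that category's own
#' saliency values, yielding sub-labels `head_low`/`head_high` and
#' `body_low`/`body_high`; background pixels keep their existing low/high
#' split as `bg_low`/`bg_high`. Empty social categories simply have empty
#' sub-labels.
#'
#' @param roiset A [build_roiset()] result.
#' @param saliency The same scene's [saliency_map()] (or matrix).
#' @param q Percentile cutoff (default 80).
#' @return Character matrix over the categories listed by
#'   `social_saliency_sublabels()`.
#' @export
split_social_by_saliency <- function(roiset, saliency, q = 80) {
  sal <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  lab <- roiset$labels
  out <- matrix("", nrow(sal), ncol(sal))
  for (cat in c("head", "body")) {
    m <- lab == cat
    if (!any(m)) next
    cutoff <- nearest_rank_percentile(sal[m], q)
    out[m & sal <= cutoff] <- paste0(cat, "_low")
    out[m & sal > cutoff] <- paste0(cat, "_high")
  }
  out[lab == "low_sal"] <- "bg_low"
  out[lab == "high_sal"] <- "bg_high"
  out
}

#' @rdname split_social_by_saliency
#' @export
social_saliency_sublabels <- function() {
  c("head_low", "head_high", "body_low", "body_high", "bg_low", "bg_high")
}

#' Count connected components per ROI category
#'
#' @param roiset A `roi_set`, or a logical matrix (counted as one category).
#' @param connectivity 4 or 8 (default 8: hand-drawn masks have diagonal
#'   stair-steps).
#' @return Named integer vector of component counts per category.
#' @export
count_rois <- function(roiset, connectivity = 8) {
  if (is.logical(roiset) && is.matrix(roiset)) {
    return(c(mask = n_components(roiset, connectivity)))
  }
  stopifnot(inherits(roiset, "roi_set"))
  vapply(roi_categories(), function(cat) {
    n_components(roiset$labels == cat, connectivity)
  }, integer(1))
}

# Connected components of a logical matrix via an igraph lattice of the
# TRUE pixels.
n_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  on <- which(mask)
  if (!length(on)) return(0L)
  id <- matrix(NA_integer_, h, w)
  id[on] <- seq_along(on)
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  edges <- integer(0)
  for (sft in shifts) {
    dy <- sft[1]; dx <- sft[2]
    # source window and shifted window over the grid
    sy <- seq_len(h - dy)
    sx <- if (dx >= 0) seq_len(w - dx) else seq(1 - dx, w)
    a <- id[sy, sx, drop = FALSE]
    b <- id[sy + dy, sx + dx, drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    if (any(both)) edges <- c(edges, rbind(a[both], b[both]))
  }
  g <- igraph::make_graph(edges = edges, n = length(on), directed = FALSE)
  as.integer(igraph::count_components(g))
}

#' ROI saliency relative to the whole scene
#'
#' Mean saliency within each category divided by the mean saliency over all
#' pixels. Empty categories are reported as `NA`, not zero.
#'
#' @param roiset A `roi_set`.
#' @param saliency The scene's [saliency_map()] (or matrix).
#' @return Named numeric vector of ratios per category.
#' @export
relative_roi_saliency <- function(roiset, saliency) {
  sal <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  overall <- mean(sal)
  vapply(roi_categories(), function(cat) {
    m <- roiset$labels == cat
    if (!any(m)) return(NA_real_)
    mean(sal[m]) / overall
  }, numeric(1))
}
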