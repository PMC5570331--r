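#' Default analysis configuration
#'
#' Every threshold and tunable of the pipeline as a nested key-value list,
#' with the conventional analysis values as defaults. A configuration file
#' (JSON, same nesting) overrides any subset of keys and is validated at
#' load time.
#'
#' @return Nested named list of configuration sections: `geometry`,
#'   `detection`, `baseline`, `exclusion`, `saliency`, `roi`, `density`.
#' @export
default_config <- function() {
  list(
    geometry = list(width_mm = 516.9, height_mm = 323.1,
                    width_px = 1920, height_px = 1200, distance_mm = 500),
    detection = list(vel_thresh_deg_s = 30, acc_thresh_deg_s2 = 8000,
                     window_samples = 5, blink_pad_ms = 25),
    baseline = list(window_ms = 300, outlier_sd = 3),
    exclusion = list(min_blink_free = 0.8, max_missing_resp = 0.25,
                     max_bad_baseline = 0.20),
    saliency = list(work_width = 32, work_height = 24, sigma_frac = 1 / 8,
                    scales = 2, channels = c("intensity", "color",
                                             "orientation")),
    roi = list(q = 80, connectivity = 8),
    density = list(sigma_px = 36, discard_first = TRUE)
  )
}

#' Load and validate a configuration file
#'
#' Reads a JSON configuration, overlays it on [default_config()], and
#' validates types, ranges and key names at startup so misconfiguration
#' fails early and loudly.
#'
#' @param path JSON file with any subset of the default keys; `NULL`
#'   returns the defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (sec in names(user)) {
      if (!sec %in% names(cfg)) {
        stop("config error: unknown section '", sec, "'")
      }
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]])) {
          stop("config error: unknown key '", sec, ".", key, "'")
        }
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- function(sec, key) {
    v <- cfg[[sec]][[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("config error: ", sec, ".", key, " must be a positive number")
    }
  }
  for (key in names(cfg$geometry)) pos("geometry", key)
  pos("detection", "vel_thresh_deg_s")
  pos("detection", "acc_thresh_deg_s2")
  pos("baseline", "window_ms")
  pos("baseline", "outlier_sd")
  pos("density", "sigma_px")
  frac <- function(sec, key) {
    v <- cfg[[sec]][[key]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("config error: ", sec, ".", key, " must be in (0, 1]")
    }
  }
  frac("exclusion", "min_blink_free")
  frac("exclusion", "max_missing_resp")
  frac("exclusion", "max_bad_baseline")
  if (!cfg$roi$q > 0 || cfg$roi$q > 100) {
    stop("config error: roi.q must be a percentile in (0, 100]")
  }
  if (!cfg$roi$connectivity %in% c(4, 8)) {
    stop("config error: roi.connectivity must be 4 or 8")
  }
  bad <- setdiff(cfg$saliency$channels,
                 c("intensity", "color", "orientation"))
  if (length(bad)) {
    stop("config error: unknown saliency channel(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Screen geometry from a configuration
#'
#' @param cfg A [load_config()] result.
#' @return A [screen_geometry()].
#' @export
config_geometry <- function(cfg = default_config()) {
  g <- cfg$geometry
  screen_geometry(g$width_mm, g$height_mm, g$width_px, g$height_px,
                  g$distance_mm)
}
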