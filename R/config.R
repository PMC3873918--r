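#' Acquisition configuration
#'
#' Bundles the microscope metadata every unit conversion depends on: the pixel
#' size, the frame interval, and the overlapping-interval size `a` used for
#' angular calculations (metrics are computed between frames `n` and `n + a`,
#' sliding `n` one frame at a time).
#'
#' Defaults reproduce a common wide-field time-lapse regime: 1.314 um per pixel
#' (10x objective, 2x2 binning) and one frame every 7 minutes, with an interval
#' size of 3 frames (21 minutes), which suppresses sub-cellular positional
#' jitter without erasing genuine turns.
#'
#' @param pixel_size_um Physical size of one pixel, in micrometers. Positive.
#' @param frame_interval_min Minutes between consecutive frames. Positive.
#' @param interval_size Interval size `a`, in frames (integer >= 1).
#' @return An object of class `acq_config` (a named list).
#' @examples
#' acquisition()
#' acquisition(pixel_size_um = 0.65, frame_interval_min = 5, interval_size = 1)
#' @export
acquisition <- function(pixel_size_um = 1.314,
                        frame_interval_min = 7,
                        interval_size = 3) {
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1, pixel_size_um > 0,
    is.numeric(frame_interval_min), length(frame_interval_min) == 1,
    frame_interval_min > 0,
    is.numeric(interval_size), length(interval_size) == 1,
    interval_size >= 1, interval_size == as.integer(interval_size)
  )
  structure(
    list(
      pixel_size_um = as.numeric(pixel_size_um),
      frame_interval_min = as.numeric(frame_interval_min),
      interval_size = as.integer(interval_size)
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>",
      sprintf(" pixel size       : %.4g um/px", x$pixel_size_um),
      sprintf(" frame interval   : %.4g min", x$frame_interval_min),
      sprintf(" interval size (a): %d frames", x$interval_size),
      sep = "\n")
  invisible(x)
}

#' Detection parameters
#'
#' Parameters of the nucleus detector: the expected outer radius of a nucleus
#' in pixels (`w`), the fraction of image pixels expected to carry nuclear
#' signal (the percentile threshold), and a minimum effective-radius cutoff
#' used to discard single-pixel noise by its intensity moments.
#'
#' @param cell_outer_radius_px Integer radius `w` >= 1, in pixels. Restoration,
#'   local-maximum suppression and centroid refinement all use this scale.
#' @param percentile Fraction in (0, 1) of each frame's pixels treated as
#'   nuclear signal; the intensity threshold is the (1 - percentile) quantile,
#'   taken per frame so photobleaching does not starve late frames.
#' @param min_radius_cutoff Non-negative; detections whose effective radius
#'   `sqrt(m2 / m0)` falls below the cutoff are discarded. 0 disables.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(cell_outer_radius_px = 6,
                             percentile = 0.01,
                             min_radius_cutoff = 0) {
  stopifnot(
    cell_outer_radius_px >= 1,
    cell_outer_radius_px == as.integer(cell_outer_radius_px),
    is.numeric(percentile), percentile > 0, percentile < 1,
    is.numeric(min_radius_cutoff), min_radius_cutoff >= 0
  )
  structure(
    list(
      cell_outer_radius_px = as.integer(cell_outer_radius_px),
      percentile = as.numeric(percentile),
      min_radius_cutoff = as.numeric(min_radius_cutoff)
    ),
    class = "detection_params"
  )
}

#' Linking parameters
#'
#' @param max_disp_px_per_frame Maximum displacement (pixels) a nucleus is
#'   tolerated to move between consecutive frames; links over a gap of `g`
#'   frames are gated at `g * max_disp_px_per_frame`.
#' @param min_track_length Minimum number of points a track must have to be
#'   kept (integer >= 2).
#' @param link_range Number of frames a link may skip (integer >= 1). 1 means
#'   no gap closing.
#' @return An object of class `linking_params`.
#' @export
linking_params <- function(max_disp_px_per_frame = 10,
                           min_track_length = 2,
                           link_range = 1) {
  stopifnot(
    is.numeric(max_disp_px_per_frame), max_disp_px_per_frame > 0,
    min_track_length >= 2, min_track_length == as.integer(min_track_length),
    link_range >= 1, link_range == as.integer(link_range)
  )
  structure(
    list(
      max_disp_px_per_frame = as.numeric(max_disp_px_per_frame),
      min_track_length = as.integer(min_track_length),
      link_range = as.integer(link_range)
    ),
    class = "linking_params"
  )
}

#' Read a run configuration file
#'
#' Reads a YAML configuration holding acquisition metadata plus detection and
#' linking parameters. Recognized top-level keys are `acquisition`,
#' `detection`, `linking` (each a mapping whose entries are passed to
#' [acquisition()], [detection_params()], [linking_params()]) and `seed`.
#' Missing sections fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `acquisition`, `detection`, `linking`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  list(
    acquisition = do.call(acquisition, as.list(raw$acquisition)),
    detection = do.call(detection_params, as.list(raw$detection)),
    linking = do.call(linking_params, as.list(raw$linking)),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
}
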