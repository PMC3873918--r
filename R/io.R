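#' Construct a frame stack
#'
#' A frame stack is the raw input to the pipeline: an ordered list of 2-D
#' grayscale intensity matrices (all the same size, finite, non-negative)
#' together with the acquisition metadata. Coordinates throughout the package
#' are in pixels, origin at the center of the top-left pixel, x rightward,
#' y downward, frames 0-based.
#'
#' @param frames List of numeric matrices (rows = y, columns = x).
#' @param config An [acquisition()] object.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, config = acquisition()) {
  stopifnot(inherits(config, "acq_config"), is.list(frames))
  if (length(frames) < 2) {
    stop("a frame stack needs at least 2 frames, got ", length(frames),
         call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  ok <- vapply(frames, function(f) all(is.finite(f)) && all(f >= 0), logical(1))
  if (!all(ok)) {
    stop("frame intensities must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(frames = lapply(frames, function(f) {
      storage.mode(f) <- "double"
      f
    }), config = config),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.4g um/px, %.4g min/frame\n",
              length(x$frames), d[1], d[2],
              x$config$pixel_size_um, x$config$frame_interval_min))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Read an image stack from disk
#'
#' Reads a multi-page TIFF or an uncompressed grayscale AVI into a
#' [frame_stack()]. Stored 8/16-bit integer intensities are preserved without
#' rescaling. The container does not matter: a TIFF and a losslessly encoded
#' AVI of the same frames produce identical stacks.
#'
#' @param path Path to a `.tif`/`.tiff` or `.avi` file.
#' @param config An [acquisition()] object.
#' @return A `frame_stack`.
#' @export
read_stack <- function(path, config = acquisition()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  frames <- switch(
    ext,
    "tif" = ,
    "tiff" = read_tiff_frames(path),
    "avi" = read_avi_frames(path),
    stop("unsupported stack format: .", ext, " (expected TIFF or AVI)",
         call. = FALSE)
  )
  if (length(frames) < 2) {
    stop("stack has fewer than 2 frames: ", path, call. = FALSE)
  }
  frame_stack(frames, config)
}

read_tiff_frames <- function(path) {
  frames <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e),
                             ")", call. = FALSE)
  )
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]   # collapse greyscale-as-RGB
    storage.mode(f) <- "double"
    f
  })
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are stored as 8- or 16-bit samples; values must already lie in
#' the corresponding integer range.
#'
#' @param stack A `frame_stack`.
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16) {
  stopifnot(inherits(stack, "frame_stack"), bits_per_sample %in% c(8, 16))
  top <- 2^bits_per_sample - 1
  mx <- max(vapply(stack$frames, max, numeric(1)))
  if (mx > top) {
    stop("intensities exceed ", bits_per_sample, "-bit range", call. = FALSE)
  }
  tiff::writeTIFF(lapply(stack$frames, function(f) f / top), path,
                  bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a track table from CSV
#'
#' The table must contain columns `cell_id`, `frame`, `x`, `y` (extra columns
#' are kept). Rows are sorted by cell and frame; duplicate (cell_id, frame)
#' records are an error.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per cell per frame.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_tracks(df)
}

#' Validate and canonicalize a track table
#'
#' @param tracks A data frame with columns `cell_id`, `frame`, `x`, `y`.
#' @return The table as a tibble, sorted by (cell_id, frame).
#' @export
validate_tracks <- function(tracks) {
  needed <- c("cell_id", "frame", "x", "y")
  missing <- setdiff(needed, names(tracks))
  if (length(missing) > 0) {
    stop("track table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tracks) == 0) {
    stop("track table is empty", call. = FALSE)
  }
  if (anyDuplicated(tracks[c("cell_id", "frame")]) > 0) {
    stop("duplicate (cell_id, frame) records in track table", call. = FALSE)
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  tracks |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$cell_id, .data$frame)
}

#' Write a track table to CSV
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(validate_tracks(tracks), path, progress = FALSE)
  invisible(path)
}

#' Write the per-cell and population report tables
#'
#' Writes `percell.csv` (cell_id, frame, x, y, displacement_px,
#' theta_trajectory_deg, theta_deflection_deg, msd_px2) and `population.csv`
#' (frame, avg_displacement_px, avg_theta_trajectory_deg, pct_turning_gt_90,
#' avg_abs_deflection_deg, dir_000 .. dir_359, n_tracks), mirroring the
#' classic per-cell / per-population output sheet.
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()].
#' @param summary A population summary from [summarize_population()].
#' @param out_dir Output directory (created if missing).
#' @param prefix Optional filename prefix.
#' @return Named character vector of the two paths written.
#' @export
write_report <- function(kinematics, summary, out_dir, prefix = "") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  percell <- kinematics |>
    dplyr::select("cell_id", "frame", "x", "y", "displacement_px",
                  "theta_trajectory_deg", "theta_deflection_deg", "msd_px2")
  hist_cols <- sprintf("dir_%03d", 0:359)
  if (nrow(summary) > 0) {
    hist_mat <- do.call(rbind, summary$direction_histogram)
    colnames(hist_mat) <- hist_cols
    pop <- dplyr::bind_cols(
      summary |>
        dplyr::select("frame", "avg_displacement_px", "avg_theta_trajectory_deg",
                      "pct_turning_gt_90", "avg_abs_deflection_deg"),
      tibble::as_tibble(hist_mat),
      summary |> dplyr::select("n_tracks")
    )
  } else {
    pop <- tibble::as_tibble(matrix(numeric(0), nrow = 0, ncol = 366,
                                    dimnames = list(NULL, c(
                                      "frame", "avg_displacement_px",
                                      "avg_theta_trajectory_deg",
                                      "pct_turning_gt_90",
                                      "avg_abs_deflection_deg", hist_cols,
                                      "n_tracks"))))
  }
  percell_path <- file.path(out_dir, paste0(prefix, "percell.csv"))
  pop_path <- file.path(out_dir, paste0(prefix, "population.csv"))
  readr::write_csv(percell, percell_path, progress = FALSE)
  readr::write_csv(pop, pop_path, progress = FALSE)
  invisible(c(percell = percell_path, population = pop_path))
}
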