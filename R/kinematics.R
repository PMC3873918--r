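# Angular kinematics of migration. Coordinates arrive in image convention
# (y down); angles are reported compass-style in a y-up frame so that "up on
# screen" is 90 degrees. The flip happens in exactly one place:
# angle_of_trajectory().

#' Angle of trajectory of a displacement
#'
#' Direction of the displacement vector, in degrees counterclockwise from the
#' +x axis in a y-up frame, mapped to \[0, 360). Input `dy` is in screen
#' (y-down) convention and is negated internally, so a cell moving up and to
#' the right at equal rates has a trajectory angle of 45 degrees. A zero
#' displacement has no direction and yields `NA`.
#'
#' @param dx,dy Displacement components in pixels (screen convention).
#' @return Angle(s) in degrees in \[0, 360), `NA` for zero displacements.
#' @export
angle_of_trajectory <- function(dx, dy) {
  theta <- atan2(-dy, dx) * 180 / pi
  theta <- theta %% 360
  theta[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  theta
}

#' Signed angle of deflection between two trajectory legs
#'
#' The smallest rotation taking the previous trajectory direction to the
#' current one, wrapped to (-180, 180\]. A clockwise turn (decreasing y-up
#' angle) is positive, a counterclockwise turn negative; an exact reversal is
#' +180 by convention. Undefined (`NA`) if either angle is undefined.
#'
#' @param theta_prev,theta_curr Trajectory angles in degrees, \[0, 360).
#' @return Signed deflection(s) in degrees in (-180, 180\].
#' @export
angle_of_deflection <- function(theta_prev, theta_curr) {
  d <- (theta_prev - theta_curr) %% 360  # in [0, 360)
  d[!is.na(d) & d > 180] <- d[!is.na(d) & d > 180] - 360
  d
}

#' Overlapping interval pairs of a track
#'
#' All frame pairs (n, n + a) present in the track, with n advancing one frame
#' at a time (overlapping intervals, not disjoint blocks). A track of L
#' contiguous frames yields L - a pairs.
#'
#' @param frames Integer vector of the track's frame indices.
#' @param a Interval size in frames (>= 1).
#' @return Tibble with columns `start`, `end`.
#' @export
interval_pairs <- function(frames, a) {
  stopifnot(a >= 1)
  frames <- sort(unique(as.integer(frames)))
  start <- frames[(frames + a) %in% frames]
  tibble::tibble(start = start, end = start + as.integer(a))
}

#' Convert a pixel displacement over an interval to speed
#'
#' @param displacement_px Euclidean displacement in pixels over `a` frames.
#' @param config An [acquisition()] object.
#' @param a Interval size in frames; defaults to `config$interval_size`.
#' @return Speed in micrometers per hour.
#' @export
speed_um_per_hr <- function(displacement_px, config, a = config$interval_size) {
  displacement_px * config$pixel_size_um * 60 / (config$frame_interval_min * a)
}

#' Mean squared displacement of one track
#'
#' MSD at each requested lag, averaged over all overlapping start frames
#' (every pair of observations separated by exactly `lag` frames contributes).
#'
#' @param track_df Data frame with `frame`, `x`, `y` for a single cell.
#' @param lags Integer lags in frames (>= 1); default all available lags.
#' @return Tibble with `lag_frames`, `msd_px2`, `n_pairs`; lags with no
#'   observation pair get `NA`.
#' @export
msd_track <- function(track_df, lags = NULL) {
  stopifnot(all(c("frame", "x", "y") %in% names(track_df)))
  ord <- order(track_df$frame)
  f <- as.integer(track_df$frame[ord])
  x <- track_df$x[ord]
  y <- track_df$y[ord]
  if (is.null(lags)) lags <- seq_len(max(f) - min(f))
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1))
  dfr <- outer(f, f, `-`)
  sq <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
  up <- dfr > 0
  msd <- vapply(lags, function(L) {
    sel <- up & dfr == L
    if (!any(sel)) NA_real_ else mean(sq[sel])
  }, numeric(1))
  n <- vapply(lags, function(L) sum(up & dfr == L), integer(1))
  tibble::tibble(lag_frames = lags, msd_px2 = msd, n_pairs = n)
}

#' Per-cell, per-frame migration kinematics
#'
#' For every track row at frame n computes, at interval size `a`:
#' \describe{
#'   \item{displacement_px}{Euclidean displacement from frame n to n + a.}
#'   \item{speed_um_per_hr}{That displacement converted to um/hour.}
#'   \item{theta_trajectory_deg}{Direction of the (n, n+a) leg; `NA` when the
#'     displacement is zero (a stationary cell has no direction).}
#'   \item{theta_deflection_deg}{Signed turn between the (n, n+a) and
#'     (n+a, n+2a) legs — consecutive non-overlapping legs sharing endpoint
#'     n + a, sliding n one frame at a time.}
#'   \item{msd_px2}{Mean squared displacement at lag (n - first frame),
#'     averaged over all overlapping start pairs; `NA` on the first frame.}
#' }
#' Values whose flanking frames are absent are `NA`.
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`).
#' @param config An [acquisition()] object; `config$interval_size` is `a`.
#' @return A kinematics tibble (class `mig_kinematics`), one row per track
#'   point, with the acquisition config attached as attribute `config`.
#' @export
compute_kinematics <- function(tracks, config = acquisition()) {
  stopifnot(inherits(config, "acq_config"))
  a <- config$interval_size
  cols <- c("cell_id", "frame", "x", "y")
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(cell_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0),
                          displacement_px = numeric(0),
                          speed_um_per_hr = numeric(0),
                          theta_trajectory_deg = numeric(0),
                          theta_deflection_deg = numeric(0),
                          msd_px2 = numeric(0))
    return(new_kinematics(out, config))
  }
  tracks <- validate_tracks(tracks)
  per_cell <- function(d) {
    f <- d$frame
    i_a <- match(f + a, f)       # row of frame n + a, NA when absent
    i_2a <- match(f + 2L * a, f)
    dx <- d$x[i_a] - d$x
    dy <- d$y[i_a] - d$y
    disp <- sqrt(dx^2 + dy^2)
    theta <- angle_of_trajectory(dx, dy)
    theta_next <- theta[i_a]     # angle of the (n+a, n+2a) leg
    theta_next[is.na(i_2a)] <- NA_real_
    defl <- angle_of_deflection(theta, theta_next)
    lag <- f - f[1]
    msd <- rep(NA_real_, length(f))
    pos <- lag >= 1
    if (any(pos)) {
      m <- msd_track(d, lags = unique(lag[pos]))
      msd[pos] <- m$msd_px2[match(lag[pos], m$lag_frames)]
    }
    tibble::tibble(
      cell_id = d$cell_id, frame = f, x = d$x, y = d$y,
      displacement_px = disp,
      speed_um_per_hr = speed_um_per_hr(disp, config, a),
      theta_trajectory_deg = theta,
      theta_deflection_deg = defl,
      msd_px2 = msd
    )
  }
  out <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(per_cell) |>
    dplyr::bind_rows()
  new_kinematics(out, config)
}

new_kinematics <- function(df, config) {
  structure(df, config = config,
            class = c("mig_kinematics", class(tibble::tibble())))
}

#' Circular mean of angles in degrees
#'
#' @param theta Angles in degrees; `NA`s dropped.
#' @return Mean direction in \[0, 360), or `NA` if no defined angles.
#' @export
circular_mean_deg <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0) return(NA_real_)
  r <- theta * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

#' Population summary of a kinematics table
#'
#' Per-frame aggregates over cells with defined values: mean displacement,
#' arithmetic mean trajectory angle (the classic output field; the circular
#' mean is also reported under `circ_mean_theta_deg` since the arithmetic
#' mean is discontinuous at the 0/360 wrap), the percentage of cells turning
#' by more than 90 degrees, the mean absolute angle of deflection, a 360-bin
#' direction histogram (integer-degree bins \[k, k+1)), and the number of
#' tracks present in the frame.
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()].
#' @return Tibble with one row per frame; `direction_histogram` is a
#'   list-column of length-360 integer vectors summing to the number of cells
#'   with a defined trajectory angle that frame.
#' @export
summarize_population <- function(kinematics) {
  if (nrow(kinematics) == 0) {
    return(tibble::tibble(frame = integer(0), avg_displacement_px = numeric(0),
                          avg_theta_trajectory_deg = numeric(0),
                          circ_mean_theta_deg = numeric(0),
                          pct_turning_gt_90 = numeric(0),
                          avg_abs_deflection_deg = numeric(0),
                          direction_histogram = list(), n_tracks = integer(0)))
  }
  kinematics |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      avg_displacement_px = mean(.data$displacement_px, na.rm = TRUE),
      avg_theta_trajectory_deg = mean(.data$theta_trajectory_deg, na.rm = TRUE),
      circ_mean_theta_deg = circular_mean_deg(.data$theta_trajectory_deg),
      pct_turning_gt_90 =
        100 * mean(abs(.data$theta_deflection_deg[
          !is.na(.data$theta_deflection_deg)]) > 90),
      avg_abs_deflection_deg = mean(abs(.data$theta_deflection_deg),
                                    na.rm = TRUE),
      direction_histogram = list(tabulate(
        floor(.data$theta_trajectory_deg[
          !is.na(.data$theta_trajectory_deg)]) + 1L, nbins = 360L)),
      n_tracks = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(
      c("avg_displacement_px", "avg_theta_trajectory_deg",
        "pct_turning_gt_90", "avg_abs_deflection_deg"),
      \(v) ifelse(is.nan(v), NA_real_, v)))
}

#' Per-cell fraction of right (clockwise) turns
#'
#' @param deflections Signed deflection angles in degrees; `NA`s dropped.
#' @return Percentage of nonzero deflections that are clockwise (positive),
#'   or `NA` when no nonzero deflection is defined.
#' @export
right_turn_fraction <- function(deflections) {
  d <- deflections[!is.na(deflections) & deflections != 0]
  if (length(d) == 0) return(NA_real_)
  100 * mean(d > 0)
}
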