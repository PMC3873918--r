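# Ground-truth generators: persistent random walks (PRW), optionally with
# neighbor alignment (collective flow), and a renderer that draws nuclei as
# Gaussian spots on a noisy background. Everything is a pure function of
# (parameters, seed), so full-pipeline tests can compare against exact truth.
#
# Wrapped-normal turning noise is used because its directional correlation is
# closed-form: <cos(dtheta)> = exp(-sigma_rad^2 / 2) per step, hence
# persistence time P = -dt / log<cos(dtheta)> = 2 dt / sigma_rad^2. That makes
# persistence-fit recovery tests analytic.

#' PRW simulation parameters
#'
#' Defaults emulate a low-density epithelial migration assay: 300 cells in a
#' 1 mm^2 field (300 cells/mm^2), one frame every 7 minutes at 1.314 um/px, a
#' speed of 0.5 um/min, and turning noise of 39.14 degrees/step, which
#' corresponds to a persistence time of ~30 minutes at this frame interval.
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames (>= 2).
#' @param speed_um_per_min Constant cell speed S, micrometers per minute.
#' @param turn_sigma_deg Wrapped-normal per-step turning noise, degrees.
#' @param arena_um `c(width, height)` of the arena in micrometers; boundaries
#'   are reflective (a field of view that cells do not wrap around).
#' @param config An [acquisition()] object (frame interval and pixel size).
#' @return An object of class `prw_params`.
#' @export
prw_params <- function(n_cells = 300, n_frames = 100,
                       speed_um_per_min = 0.5, turn_sigma_deg = 39.14,
                       arena_um = c(1000, 1000), config = acquisition()) {
  stopifnot(n_cells >= 1, n_frames >= 2, speed_um_per_min > 0,
            turn_sigma_deg >= 0, length(arena_um) == 2, all(arena_um > 0),
            inherits(config, "acq_config"))
  structure(list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
                 speed_um_per_min = speed_um_per_min,
                 turn_sigma_deg = turn_sigma_deg,
                 arena_um = arena_um, config = config),
            class = "prw_params")
}

#' Turning noise for a target persistence time
#'
#' Inverts `P = 2 dt / sigma_rad^2`.
#'
#' @param P_min Target persistence time, minutes.
#' @param dt_min Frame interval, minutes.
#' @return Wrapped-normal turning sigma in degrees per step.
#' @export
turn_sigma_for_persistence <- function(P_min, dt_min) {
  stopifnot(P_min > 0, dt_min > 0)
  sqrt(2 * dt_min / P_min) * 180 / pi
}

#' Simulate persistent-random-walk tracks
#'
#' Each cell starts at a uniform position with a uniform heading; every frame
#' the heading gains wrapped-normal noise and the cell advances by
#' `S * dt`. Reflective boundaries flip the position and the heading
#' component normal to the wall. Pure function of (params, seed).
#'
#' @param params A [prw_params()] object.
#' @param seed Integer seed.
#' @return Track tibble (`cell_id`, `frame`, `x`, `y`) in pixels, image
#'   convention (y down), with the acquisition config as attribute `config`.
#' @export
simulate_prw <- function(params = prw_params(), seed = 1) {
  simulate_engine(params, alignment_weight = 0, coupling_radius_um = 0,
                  edge_gradient = 0, seed = seed)
}

#' Collective simulation parameters
#'
#' Extends [prw_params()] with neighbor alignment: each step a cell's heading
#' relaxes toward the circular-mean heading of cells within
#' `coupling_radius_um` by fraction `alignment_weight`, before the turning
#' noise is added. With `edge_gradient > 0` the noise grows linearly with
#' distance from the x = 0 edge (`sigma_eff = sigma + edge_gradient * d_um`),
#' emulating collective order decaying away from a sheet's leading edge.
#'
#' @param prw A [prw_params()] object.
#' @param coupling_radius_um Alignment interaction radius, micrometers.
#' @param alignment_weight Relaxation weight in \[0, 1\] (0 = plain PRW).
#' @param edge_gradient Noise gradient, degrees per micrometer (default 0).
#' @return An object of class `collective_params`.
#' @export
collective_params <- function(prw = prw_params(), coupling_radius_um = 100,
                              alignment_weight = 0.5, edge_gradient = 0) {
  stopifnot(inherits(prw, "prw_params"), coupling_radius_um >= 0,
            alignment_weight >= 0, alignment_weight <= 1, edge_gradient >= 0)
  structure(c(unclass(prw),
              list(coupling_radius_um = coupling_radius_um,
                   alignment_weight = alignment_weight,
                   edge_gradient = edge_gradient)),
            class = "collective_params")
}

#' Simulate collectively migrating tracks
#'
#' @param params A [collective_params()] object.
#' @param seed Integer seed.
#' @return Track tibble as in [simulate_prw()]. With `alignment_weight = 0`
#'   the output is identical to [simulate_prw()] under the same seed.
#' @export
simulate_collective <- function(params = collective_params(), seed = 1) {
  simulate_engine(params, alignment_weight = params$alignment_weight,
                  coupling_radius_um = params$coupling_radius_um,
                  edge_gradient = params$edge_gradient, seed = seed)
}

wrap_angle <- function(rad) {
  ((rad + pi) %% (2 * pi)) - pi
}

simulate_engine <- function(params, alignment_weight, coupling_radius_um,
                            edge_gradient, seed) {
  cfg <- params$config
  n <- params$n_cells
  nf <- params$n_frames
  dt <- cfg$frame_interval_min
  step_um <- params$speed_um_per_min * dt
  sigma0 <- params$turn_sigma_deg * pi / 180
  W <- params$arena_um[1]
  H <- params$arena_um[2]

  withr::with_seed(seed, {
    x <- stats::runif(n, 0, W)     # micrometers, y up during simulation
    y <- stats::runif(n, 0, H)
    heading <- stats::runif(n, 0, 2 * pi)
    xs <- matrix(0, nf, n)
    ys <- matrix(0, nf, n)
    xs[1, ] <- x
    ys[1, ] <- y
    for (f in 2:nf) {
      if (alignment_weight > 0 && coupling_radius_um > 0) {
        dmat <- as.matrix(stats::dist(cbind(x, y)))
        near <- dmat <= coupling_radius_um   # includes self (diag 0)
        target <- vapply(seq_len(n), function(i) {
          h <- heading[near[i, ]]
          atan2(mean(sin(h)), mean(cos(h)))
        }, numeric(1))
        heading <- heading + alignment_weight * wrap_angle(target - heading)
      }
      sigma <- sigma0 + edge_gradient * (pi / 180) * x
      heading <- heading + stats::rnorm(n, 0, 1) * sigma
      x <- x + step_um * cos(heading)
      y <- y + step_um * sin(heading)
      # reflective walls: mirror position and the normal heading component
      bx <- x < 0 | x > W
      x[x < 0] <- -x[x < 0]
      x[x > W] <- 2 * W - x[x > W]
      heading[bx] <- pi - heading[bx]
      by <- y < 0 | y > H
      y[y < 0] <- -y[y < 0]
      y[y > H] <- 2 * H - y[y > H]
      heading[by] <- -heading[by]
      xs[f, ] <- x
      ys[f, ] <- y
    }
  })
  px <- cfg$pixel_size_um
  out <- tibble::tibble(
    cell_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf) - 1L, times = n),
    x = as.vector(xs) / px,
    y = (H - as.vector(ys)) / px    # to image convention (y down)
  )
  attr(out, "config") <- cfg
  out
}

#' Render tracks as a fluorescence video
#'
#' Draws each nucleus as an isotropic Gaussian spot of width
#' `nucleus_sigma_px` at its sub-pixel position, on a constant background with
#' additive Gaussian noise, clipped to the 16-bit range and rounded to
#' integers. Pure function of (arguments, seed).
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`) in pixels; all
#'   positions must lie inside the image.
#' @param size_px `c(width, height)` of the frames in pixels.
#' @param config An [acquisition()] object.
#' @param nucleus_sigma_px Gaussian width of a rendered nucleus.
#' @param peak_intensity Peak counts added by one nucleus.
#' @param background_mean Constant background level.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return A [frame_stack()].
#' @export
render_video <- function(tracks, size_px, config = acquisition(),
                         nucleus_sigma_px = 3, peak_intensity = 5000,
                         background_mean = 1000, noise_sd = 500, seed = 1) {
  tracks <- validate_tracks(tracks)
  w <- size_px[1]
  h <- size_px[2]
  if (any(tracks$x < 0 | tracks$x > w - 1 | tracks$y < 0 | tracks$y > h - 1)) {
    stop("track positions fall outside the ", w, " x ", h, " px image; ",
         "arena and image size disagree", call. = FALSE)
  }
  frames_idx <- sort(unique(tracks$frame))
  half <- ceiling(4 * nucleus_sigma_px)
  frames <- withr::with_seed(seed, {
    lapply(frames_idx, function(f) {
      img <- matrix(background_mean, h, w)
      pts <- tracks[tracks$frame == f, ]
      for (i in seq_len(nrow(pts))) {
        cx <- pts$x[i]
        cy <- pts$y[i]
        cols <- max(0, floor(cx) - half):min(w - 1, ceiling(cx) + half)
        rows <- max(0, floor(cy) - half):min(h - 1, ceiling(cy) + half)
        gx <- exp(-(cols - cx)^2 / (2 * nucleus_sigma_px^2))
        gy <- exp(-(rows - cy)^2 / (2 * nucleus_sigma_px^2))
        img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
          peak_intensity * outer(gy, gx)
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      }
      img <- round(img)
      img[img < 0] <- 0
      img[img > 65535] <- 65535
      img
    })
  })
  frame_stack(frames, config)
}
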