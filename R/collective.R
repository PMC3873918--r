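# Collective migration via the paired random migration index (PRMI): the mean
# over neighboring cell pairs of the pairwise sample standard deviation of
# their trajectory angles. 0 = perfectly collective; iid uniform directions
# give the null ceiling E|delta| / sqrt(2) = 120 / sqrt(2) = 84.85 degrees.

#' Pairwise sample standard deviation of two angles
#'
#' The n-1 (sample) standard deviation of two values, i.e.
#' `|theta_a - theta_b| / sqrt(2)`, computed on raw angle values with no
#' circular wrapping — the wrap pathology (e.g. 10 vs 350 degrees) is handled
#' by the exclusion rule, not here.
#'
#' @param theta_a,theta_b Angles in degrees, \[0, 360).
#' @return Degrees (vectorized).
#' @export
pair_angle_sd <- function(theta_a, theta_b) {
  abs(theta_a - theta_b) / sqrt(2)
}

#' Drop angle pairs straddling the 0/360 discontinuity
#'
#' Removes pairs in which one cell migrates with a direction in \[0, 90\] and
#' the other in \[270, 360): such pairs have a falsely high raw standard
#' deviation purely because of the wrap. For uniform random directions about
#' 1/8 of pairs are excluded.
#'
#' @param pairs Tibble with `theta_a`, `theta_b` columns (degrees).
#' @return The tibble without straddling pairs.
#' @export
apply_exclusion <- function(pairs) {
  low <- function(t) t >= 0 & t <= 90
  high <- function(t) t >= 270 & t < 360
  bad <- (low(pairs$theta_a) & high(pairs$theta_b)) |
    (high(pairs$theta_a) & low(pairs$theta_b))
  pairs[!bad, , drop = FALSE]
}

#' Neighbor pairs within one frame
#'
#' In `"nearest"` pairing (the default), each cell is paired with its single
#' nearest other cell by centroid distance and the pair is kept when that
#' distance is at most `radius_um`; reciprocal duplicates are collapsed to
#' unordered pairs. In `"all_within"` pairing every unordered pair within
#' `radius_um` is kept.
#'
#' @param cells Tibble with one row per cell: `cell_id`, `x`, `y` (pixels),
#'   `theta` (trajectory angle, degrees; rows with `NA` are ignored).
#' @param radius_um Neighbor radius in micrometers (default 100).
#' @param config An [acquisition()] object (for the pixel size).
#' @param pairing `"nearest"` or `"all_within"`.
#' @return Tibble of pairs: `cell_a`, `cell_b`, `distance_um`, `theta_a`,
#'   `theta_b`.
#' @export
neighbor_pairs <- function(cells, radius_um = 100, config = acquisition(),
                           pairing = c("nearest", "all_within")) {
  pairing <- match.arg(pairing)
  cells <- dplyr::filter(cells, !is.na(.data$theta))
  empty <- tibble::tibble(cell_a = integer(0), cell_b = integer(0),
                          distance_um = numeric(0), theta_a = numeric(0),
                          theta_b = numeric(0))
  n <- nrow(cells)
  if (n < 2) return(empty)
  px <- config$pixel_size_um
  dmat <- as.matrix(stats::dist(cbind(cells$x * px, cells$y * px)))
  diag(dmat) <- Inf
  if (pairing == "nearest") {
    j <- apply(dmat, 1, which.min)
    d <- dmat[cbind(seq_len(n), j)]
    keep <- d <= radius_um
    i <- which(keep)
    j <- j[keep]
    d <- d[keep]
    a <- pmin(i, j)
    b <- pmax(i, j)
    dup <- duplicated(cbind(a, b))
    a <- a[!dup]; b <- b[!dup]; d <- d[!dup]
  } else {
    sel <- which(upper.tri(dmat) & dmat <= radius_um, arr.ind = TRUE)
    a <- sel[, 1]; b <- sel[, 2]
    d <- dmat[sel]
  }
  tibble::tibble(cell_a = cells$cell_id[a], cell_b = cells$cell_id[b],
                 distance_um = d, theta_a = cells$theta[a],
                 theta_b = cells$theta[b])
}

frame_cells <- function(kinematics, frames = NULL) {
  k <- tibble::as_tibble(kinematics)
  if (!is.null(frames)) {
    k <- dplyr::filter(k, .data$frame >= frames[1], .data$frame <= frames[2])
  }
  k |>
    dplyr::transmute(frame = .data$frame, cell_id = .data$cell_id,
                     x = .data$x, y = .data$y,
                     theta = .data$theta_trajectory_deg)
}

#' Paired random migration index (PRMI)
#'
#' Pools neighbor pairs over all frames in the analysis window and averages
#' the pairwise sample standard deviation of trajectory angles. Three modes:
#' \describe{
#'   \item{nearest_neighbor}{Nearest-neighbor pairs gated at `radius_um`,
#'     wrap-exclusion applied.}
#'   \item{random_pairing}{Each cell's partner is re-drawn uniformly among the
#'     other cells with a defined angle in the same frame, distance ignored;
#'     wrap-exclusion applied. Distinguishes local from global alignment.}
#'   \item{random_angles}{Nearest-neighbor pair structure but every cell's
#'     angle replaced by an iid uniform draw on \[0, 360); exclusion NOT
#'     applied (its analytic ceiling with exclusion would be ~70 degrees, not
#'     the ~85-degree null this control establishes). Pure null: independent
#'     of positions and of the true angles.}
#' }
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()] (or any
#'   tibble with `frame`, `cell_id`, `x`, `y`, `theta_trajectory_deg`).
#' @param mode One of `"nearest_neighbor"`, `"random_pairing"`,
#'   `"random_angles"`.
#' @param config An [acquisition()] object.
#' @param radius_um Neighbor radius in micrometers (default 100).
#' @param frames Optional `c(first, last)` frame window; default all frames.
#' @param seed Integer seed, required by the two random modes.
#' @param pairing Pair definition for the neighbor modes, see
#'   [neighbor_pairs()].
#' @return One-row tibble: `prmi_deg`, `n_pairs`, `mode`, `exclusion_applied`,
#'   `frame_start`, `frame_end`. Fewer than 100 pairs triggers a warning
#'   (`prmi_deg` is `NA` at 0 pairs).
#' @export
prmi <- function(kinematics,
                 mode = c("nearest_neighbor", "random_pairing", "random_angles"),
                 config = acquisition(), radius_um = 100, frames = NULL,
                 seed = NULL, pairing = c("nearest", "all_within")) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  if (mode != "nearest_neighbor" && is.null(seed)) {
    stop("mode '", mode, "' needs an explicit seed", call. = FALSE)
  }
  cells <- frame_cells(kinematics, frames)
  by_frame <- cells |>
    dplyr::filter(!is.na(.data$theta)) |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_split()

  collect_pairs <- function() {
    purrr::map(by_frame, function(d) {
      if (mode == "random_pairing") {
        n <- nrow(d)
        if (n < 2) return(NULL)
        partner <- vapply(seq_len(n), function(i) {
          sample(setdiff(seq_len(n), i), 1)
        }, integer(1))
        tibble::tibble(cell_a = d$cell_id, cell_b = d$cell_id[partner],
                       distance_um = NA_real_, theta_a = d$theta,
                       theta_b = d$theta[partner])
      } else {
        if (mode == "random_angles") d$theta <- stats::runif(nrow(d), 0, 360)
        neighbor_pairs(d, radius_um, config, pairing)
      }
    }) |>
      dplyr::bind_rows()
  }
  pairs <- if (mode == "nearest_neighbor") collect_pairs() else
    withr::with_seed(seed, collect_pairs())

  exclusion <- mode != "random_angles"
  if (exclusion && nrow(pairs) > 0) pairs <- apply_exclusion(pairs)
  n_pairs <- nrow(pairs)
  if (n_pairs == 0) {
    warning("no neighbor pairs in window; PRMI undefined", call. = FALSE)
    val <- NA_real_
  } else {
    if (n_pairs <= 100) {
      warning("PRMI computed from only ", n_pairs,
              " pairs (> 100 recommended)", call. = FALSE)
    }
    val <- mean(pair_angle_sd(pairs$theta_a, pairs$theta_b))
  }
  fr <- if (is.null(frames)) range(cells$frame) else frames
  tibble::tibble(prmi_deg = val, n_pairs = n_pairs, mode = mode,
                 exclusion_applied = exclusion,
                 frame_start = fr[1], frame_end = fr[2])
}

#' PRMI profile with distance from the leading edge
#'
#' For sheet geometries: cells are assigned to distance bins measured from the
#' leading edge along `edge_axis` at each window's start frame (the edge is
#' the extreme occupied coordinate on the `edge_side` of that frame), and a
#' nearest-neighbor PRMI is computed within each bin, pooling the window's
#' frames. Bins with fewer than `min_pairs` pairs are reported as `NA`.
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()].
#' @param config An [acquisition()] object.
#' @param windows List of `c(first, last)` frame windows; default one window
#'   covering all frames.
#' @param edge_axis `"x"` or `"y"`: the axis along which distance from the
#'   edge is measured.
#' @param edge_side `"min"` or `"max"`: which extreme of the occupied
#'   coordinates is the free edge.
#' @param bin_width_um Bin width in micrometers (default 100).
#' @param radius_um Neighbor radius passed to [neighbor_pairs()].
#' @param min_pairs Minimum pairs for a reportable bin (default 5).
#' @return Tibble: `window_start`, `window_end`, `bin` (0-based), `bin_start_um`,
#'   `prmi_deg`, `n_pairs`.
#' @export
leading_edge_profile <- function(kinematics, config = acquisition(),
                                 windows = NULL, edge_axis = c("x", "y"),
                                 edge_side = c("min", "max"),
                                 bin_width_um = 100, radius_um = 100,
                                 min_pairs = 5) {
  edge_axis <- match.arg(edge_axis)
  edge_side <- match.arg(edge_side)
  cells <- frame_cells(kinematics)
  if (is.null(windows)) windows <- list(range(cells$frame))
  px <- config$pixel_size_um

  purrr::map(windows, function(win) {
    wcells <- dplyr::filter(cells, .data$frame >= win[1],
                            .data$frame <= win[2])
    start_pos <- dplyr::filter(wcells, .data$frame == win[1])
    coord <- start_pos[[edge_axis]] * px
    edge <- if (edge_side == "min") min(coord) else max(coord)
    dist_edge <- abs(coord - edge)
    bin_of <- tibble::tibble(cell_id = start_pos$cell_id,
                             bin = as.integer(dist_edge %/% bin_width_um))
    wcells <- dplyr::inner_join(wcells, bin_of, by = "cell_id")
    wcells |>
      dplyr::group_by(.data$bin) |>
      dplyr::group_split() |>
      purrr::map(function(bc) {
        pairs <- bc |>
          dplyr::group_by(.data$frame) |>
          dplyr::group_split() |>
          purrr::map(neighbor_pairs, radius_um = radius_um, config = config) |>
          dplyr::bind_rows()
        if (nrow(pairs) > 0) pairs <- apply_exclusion(pairs)
        np <- nrow(pairs)
        tibble::tibble(
          window_start = win[1], window_end = win[2], bin = bc$bin[1],
          bin_start_um = bc$bin[1] * bin_width_um,
          prmi_deg = if (np >= min_pairs)
            mean(pair_angle_sd(pairs$theta_a, pairs$theta_b)) else NA_real_,
          n_pairs = np)
      }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$window_start, .data$bin)
}
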