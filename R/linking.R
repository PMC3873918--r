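# Frame-to-frame linking: greedy ascending-cost assignment between active
# track ends and detections, gated by a maximum per-frame displacement.
# At the nuclear densities this pipeline targets (inter-nucleus spacing far
# above per-frame motion) greedy assignment agrees with a global optimum and
# is easy to reason about.

#' Link per-frame detections into tracks
#'
#' Processes frames in temporal order. At each frame, candidate links between
#' active track ends and new detections are enumerated (a link over a gap of
#' `g` frames is allowed only when `g <= link_range` and the displacement is
#' at most `g * max_disp_px_per_frame`), sorted by squared displacement, and
#' assigned greedily. Ties are broken by detection order after canonical
#' (y, x) sorting, so the result does not depend on the input row order.
#' Unmatched detections seed new tracks; track ends older than `link_range`
#' frames are closed. Tracks shorter than `min_track_length` are dropped.
#'
#' @param detections Tibble with columns `frame`, `x`, `y` (extra columns
#'   ignored), e.g. from [detect_nuclei()].
#' @param params A [linking_params()] object.
#' @return Track tibble (`cell_id`, `frame`, `x`, `y`), cell ids numbered in
#'   order of track birth.
#' @export
link_tracks <- function(detections, params = linking_params()) {
  stopifnot(inherits(params, "linking_params"))
  if (nrow(detections) == 0) {
    return(tibble::tibble(cell_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  det <- detections |>
    dplyr::select("frame", "x", "y") |>
    dplyr::arrange(.data$frame, .data$y, .data$x)

  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)

  tracks <- list()       # closed + active track point lists
  active_id <- integer(0)
  active_frame <- integer(0)
  active_x <- numeric(0)
  active_y <- numeric(0)
  next_id <- 1L

  for (f in frames) {
    d <- by_frame[[as.character(f)]]
    nd <- nrow(d)
    # retire stale track ends
    alive <- active_frame >= f - params$link_range
    active_id <- active_id[alive]
    active_frame <- active_frame[alive]
    active_x <- active_x[alive]
    active_y <- active_y[alive]
    na <- length(active_id)

    assigned_det <- rep(FALSE, nd)
    if (na > 0 && nd > 0) {
      gap <- f - active_frame
      dx <- outer(active_x, d$x, `-`)
      dy <- outer(active_y, d$y, `-`)
      cost <- dx^2 + dy^2
      gate <- (gap * params$max_disp_px_per_frame)^2
      ok <- which(cost <= matrix(gate, na, nd), arr.ind = TRUE)
      if (nrow(ok) > 0) {
        costs <- cost[ok]
        ord <- order(costs, ok[, 2], ok[, 1])
        used_a <- rep(FALSE, na)
        for (k in ord) {
          ia <- ok[k, 1]; jd <- ok[k, 2]
          if (used_a[ia] || assigned_det[jd]) next
          used_a[ia] <- TRUE
          assigned_det[jd] <- TRUE
          id <- active_id[ia]
          tracks[[id]]$frame <- c(tracks[[id]]$frame, f)
          tracks[[id]]$x <- c(tracks[[id]]$x, d$x[jd])
          tracks[[id]]$y <- c(tracks[[id]]$y, d$y[jd])
          active_frame[ia] <- f
          active_x[ia] <- d$x[jd]
          active_y[ia] <- d$y[jd]
        }
      }
    }
    if (any(!assigned_det)) {
      for (jd in which(!assigned_det)) {
        tracks[[next_id]] <- list(frame = f, x = d$x[jd], y = d$y[jd])
        active_id <- c(active_id, next_id)
        active_frame <- c(active_frame, f)
        active_x <- c(active_x, d$x[jd])
        active_y <- c(active_y, d$y[jd])
        next_id <- next_id + 1L
      }
    }
  }

  out <- purrr::imap(tracks, function(tr, id) {
    tibble::tibble(cell_id = as.integer(id), frame = as.integer(tr$frame),
                   x = tr$x, y = tr$y)
  }) |>
    dplyr::bind_rows()
  filter_tracks(out, params$min_track_length)
}

#' Drop tracks shorter than a minimum length
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`).
#' @param min_track_length Minimum number of points per track.
#' @return Filtered track tibble (possibly zero rows).
#' @export
filter_tracks <- function(tracks, min_track_length) {
  stopifnot(min_track_length >= 0)
  if (nrow(tracks) == 0) return(tibble::as_tibble(tracks))
  tracks |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::n() >= min_track_length) |>
    dplyr::ungroup()
}
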