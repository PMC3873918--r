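# Nucleus detection: image restoration -> percentile-thresholded local maxima
# -> iterative intensity-weighted centroid refinement -> moment-based
# discrimination. The chain follows the classic single-particle tracking
# recipe for fluorescent point-like objects.

#' Restore (background-subtract and low-pass) one frame
#'
#' Subtracts a boxcar background estimate over a (2w+1)^2 window and applies
#' Gaussian smoothing of scale `w/3` (half-width `w`), clamping negative values
#' to zero. A constant frame restores to all zeros; noise shorter than the
#' nucleus scale is suppressed while blobs of radius ~`w` survive.
#'
#' @param frame Numeric matrix (rows = y, columns = x).
#' @param w Cell outer radius in pixels (integer >= 1).
#' @return Restored matrix, same size, non-negative.
#' @export
restore_frame <- function(frame, w) {
  stopifnot(is.matrix(frame), w >= 1)
  w <- as.integer(w)
  if (2L * w + 1L > min(dim(frame))) {
    stop("cell radius w = ", w, " too large for a ", nrow(frame), " x ",
         ncol(frame), " frame", call. = FALSE)
  }
  off <- -w:w
  gauss <- exp(-off^2 / (2 * (w / 3)^2))
  gauss <- gauss / sum(gauss)
  box <- rep(1 / (2 * w + 1), 2 * w + 1)
  out <- conv_sep(frame, gauss) - conv_sep(frame, box)
  out[out < 0] <- 0
  out
}

# Separable 2-D convolution with replicate padding (kernel applied along
# rows then columns).
conv_sep <- function(m, k) {
  conv_cols(conv_rows(m, k), k)
}

conv_rows <- function(m, k) {
  w <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (i in seq_along(k)) {
    idx <- pmin(pmax(seq_len(nr) + (i - 1L - w), 1L), nr)
    out <- out + k[i] * m[idx, , drop = FALSE]
  }
  out
}

conv_cols <- function(m, k) {
  w <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  for (i in seq_along(k)) {
    idx <- pmin(pmax(seq_len(nc) + (i - 1L - w), 1L), nc)
    out <- out + k[i] * m[, idx, drop = FALSE]
  }
  out
}

#' Find candidate nucleus pixels in a restored frame
#'
#' Candidates are pixels that lie in the top `percentile` fraction of the
#' frame's intensity distribution and are local maxima within a (2w+1)^2
#' neighborhood. Plateau ties are broken by keeping the lexicographically
#' smallest (y, x) pixel, so a flat-topped blob yields one candidate.
#'
#' Because the threshold is a per-frame quantile, the candidate set is
#' invariant under affine rescaling of intensities (gain > 0).
#'
#' @param frame Restored frame matrix.
#' @param percentile Fraction of pixels assumed to carry nuclear signal.
#' @param w Cell outer radius in pixels.
#' @return Tibble with 0-based pixel coordinates `x`, `y` (one row per
#'   candidate), ordered by (y, x).
#' @export
find_candidates <- function(frame, percentile, w) {
  stopifnot(is.matrix(frame), percentile > 0, percentile < 1, w >= 1)
  w <- as.integer(w)
  thr <- stats::quantile(frame, probs = 1 - percentile, names = FALSE)
  local_max <- frame
  nr <- nrow(frame)
  nc <- ncol(frame)
  for (dy in -w:w) {
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    for (dx in -w:w) {
      ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      local_max <- pmax(local_max, frame[ri, ci])
    }
  }
  idx <- which(frame > thr & frame == local_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(x = integer(0), y = integer(0)))
  }
  # lexicographic (y, x) tie-break on plateaus: keep a candidate only if no
  # equal-valued pixel earlier in (y, x) order sits in its neighborhood
  ord <- order(idx[, "row"], idx[, "col"])
  idx <- idx[ord, , drop = FALSE]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, "row"]; c <- idx[i, "col"]
    v <- frame[r, c]
    rr <- max(1L, r - w):min(nr, r + w)
    cc <- max(1L, c - w):min(nc, c + w)
    win <- frame[rr, cc, drop = FALSE]
    ties <- which(win == v, arr.ind = TRUE)
    ty <- rr[ties[, 1]]; tx <- cc[ties[, 2]]
    first <- order(ty, tx)[1]
    keep[i] <- (ty[first] == r && tx[first] == c)
  }
  idx <- idx[keep, , drop = FALSE]
  tibble::tibble(x = as.integer(idx[, "col"] - 1L),
                 y = as.integer(idx[, "row"] - 1L))
}

disk_offsets <- function(w) {
  g <- expand.grid(dy = -w:w, dx = -w:w)
  g[g$dx^2 + g$dy^2 <= w^2, ]
}

#' Refine a candidate to a sub-pixel centroid
#'
#' Computes the intensity-weighted centroid within the disk of radius `w`
#' around the candidate, re-centering the window and iterating while the
#' shift exceeds half a pixel. Also returns the intensity moments `m0` (total
#' intensity on the disk) and `m2` (second moment, `sum I * r^2`), used
#' downstream to discriminate real nuclei from hot pixels.
#'
#' @param frame Restored frame matrix.
#' @param x,y Candidate pixel (0-based).
#' @param w Cell outer radius in pixels.
#' @return A one-row tibble (`x`, `y`, `m0`, `m2`), or NULL when the window
#'   has zero intensity or the candidate sits closer than `w` to the border.
#' @export
refine_centroid <- function(frame, x, y, w) {
  w <- as.integer(w)
  nr <- nrow(frame)
  nc <- ncol(frame)
  offs <- disk_offsets(w)
  r0 <- as.integer(y) + 1L
  c0 <- as.integer(x) + 1L
  for (iter in 1:11) {
    if (r0 - w < 1L || r0 + w > nr || c0 - w < 1L || c0 + w > nc) {
      return(NULL)  # too close to the border for a full window
    }
    vals <- frame[cbind(r0 + offs$dy, c0 + offs$dx)]
    m0 <- sum(vals)
    if (m0 <= 0) return(NULL)
    ex <- sum(vals * offs$dx) / m0
    ey <- sum(vals * offs$dy) / m0
    if ((abs(ex) <= 0.5 && abs(ey) <= 0.5) || iter == 11) break
    c0 <- c0 + as.integer(round(ex))
    r0 <- r0 + as.integer(round(ey))
  }
  m2 <- sum(vals * ((offs$dx - ex)^2 + (offs$dy - ey)^2))
  tibble::tibble(x = c0 - 1 + ex, y = r0 - 1 + ey, m0 = m0, m2 = m2)
}

#' Discard detections below a minimum effective radius
#'
#' The effective radius of a detection is `sqrt(m2 / m0)`, the intensity rms
#' radius. Single-pixel noise has effective radius near zero; real nuclei of
#' Gaussian width sigma have effective radius ~ sigma * sqrt(2). A cutoff of 0
#' disables the filter.
#'
#' @param detections Tibble with `m0`, `m2` columns.
#' @param min_radius_cutoff Non-negative cutoff in pixels.
#' @return Filtered tibble.
#' @export
discriminate_detections <- function(detections, min_radius_cutoff) {
  stopifnot(min_radius_cutoff >= 0)
  if (min_radius_cutoff == 0 || nrow(detections) == 0) return(detections)
  dplyr::filter(detections, sqrt(.data$m2 / .data$m0) >= min_radius_cutoff)
}

#' Detect nuclei in every frame of a stack
#'
#' Runs restoration, candidate finding, centroid refinement and moment
#' discrimination on each frame.
#'
#' @param stack A [frame_stack()].
#' @param params A [detection_params()] object.
#' @return Tibble of detections: `frame` (0-based), sub-pixel `x`, `y`, and
#'   moments `m0`, `m2`, ordered by (frame, y, x).
#' @export
detect_nuclei <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(params, "detection_params"))
  w <- params$cell_outer_radius_px
  per_frame <- purrr::imap(stack$frames, function(fr, i) {
    restored <- restore_frame(fr, w)
    cand <- find_candidates(restored, params$percentile, w)
    if (nrow(cand) == 0) return(NULL)
    dets <- purrr::pmap(cand, function(x, y) refine_centroid(restored, x, y, w))
    dets <- dplyr::bind_rows(dets)
    if (nrow(dets) == 0) return(NULL)
    dets <- discriminate_detections(dets, params$min_radius_cutoff)
    if (nrow(dets) == 0) return(NULL)
    dplyr::mutate(dets, frame = i - 1L, .before = 1)
  })
  out <- dplyr::bind_rows(per_frame)
  if (nrow(out) == 0) {
    return(tibble::tibble(frame = integer(0), x = numeric(0), y = numeric(0),
                          m0 = numeric(0), m2 = numeric(0)))
  }
  dplyr::arrange(out, .data$frame, .data$y, .data$x)
}
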