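# Shared fixtures, built in code. Heavier objects are cached so several test
# files can reuse them without re-rendering.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

acq1 <- function(a = 1) acquisition(interval_size = a)

# straight tracks at random headings with isotropic positional jitter
jittered_straight_tracks <- function(n = 200, len = 40, speed_px = 3,
                                     jitter_sd = 0.5, seed = 9) {
  withr::with_seed(seed, {
    ang <- stats::runif(n, 0, 2 * pi)
    purrr::map(seq_len(n), function(i) {
      t <- 0:(len - 1)
      tibble::tibble(cell_id = i, frame = t,
                     x = 100 + speed_px * t * cos(ang[i]) +
                       stats::rnorm(len, 0, jitter_sd),
                     y = 100 + speed_px * t * sin(ang[i]) +
                       stats::rnorm(len, 0, jitter_sd))
    }) |>
      dplyr::bind_rows()
  })
}

# one Gaussian nucleus rendered at a sub-pixel position on a clean background
render_single_nucleus <- function(cx, cy, size = 64, sigma = 3, peak = 1000) {
  tr <- tibble::tibble(cell_id = 1L, frame = c(0L, 1L), x = cx, y = cy)
  render_video(tr, size_px = c(size, size), config = acq1(),
               nucleus_sigma_px = sigma, peak_intensity = peak,
               background_mean = 0, noise_sd = 0, seed = 1)
}

# nuclei on a jittered grid with guaranteed spacing, rendered at a given SNR
grid_nuclei_stack <- function(n_side = 4, spacing_px = 40, sigma = 3,
                              peak = 5000, noise_sd = 1000, seed = 14) {
  pos <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  withr::with_seed(seed, {
    pos$x <- 20 + (pos$ix - 1) * spacing_px + stats::runif(nrow(pos), -2, 2)
    pos$y <- 20 + (pos$iy - 1) * spacing_px + stats::runif(nrow(pos), -2, 2)
  })
  size <- 40 + (n_side - 1) * spacing_px
  tr <- tibble::tibble(cell_id = rep(seq_len(nrow(pos)), each = 2),
                       frame = rep(c(0L, 1L), nrow(pos)),
                       x = rep(pos$x, each = 2), y = rep(pos$y, each = 2))
  list(truth = pos,
       stack = render_video(tr, size_px = c(size, size), config = acq1(),
                            nucleus_sigma_px = sigma, peak_intensity = peak,
                            background_mean = 500, noise_sd = noise_sd,
                            seed = seed + 1))
}

# match detections/links against ground truth by nearest position
match_to_truth <- function(dets, truth_frame, tol_px = 2.5) {
  vapply(seq_len(nrow(dets)), function(i) {
    d2 <- (truth_frame$x - dets$x[i])^2 + (truth_frame$y - dets$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= tol_px) truth_frame$cell_id[j] else NA_integer_
  }, integer(1))
}

# fraction of ground-truth (frame f -> f+1) links recovered by linked tracks
link_recall <- function(linked, truth, tol_px = 2.5) {
  lab <- linked
  lab$truth_id <- NA_integer_
  for (f in unique(lab$frame)) {
    sel <- lab$frame == f
    lab$truth_id[sel] <- match_to_truth(lab[sel, ], truth[truth$frame == f, ],
                                        tol_px)
  }
  lab <- lab[order(lab$cell_id, lab$frame), ]
  ok <- 0L
  for (tr in split(lab, lab$cell_id)) {
    if (nrow(tr) < 2) next
    consec <- diff(tr$frame) == 1
    a <- tr$truth_id[-nrow(tr)]
    b <- tr$truth_id[-1]
    same <- !is.na(a) & !is.na(b) & a == b
    ok <- ok + sum(consec & same)
  }
  n_truth <- sum(unlist(lapply(split(truth, truth$cell_id),
                               function(g) sum(diff(sort(g$frame)) == 1))))
  ok / n_truth
}
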