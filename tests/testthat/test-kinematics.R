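test_that("overlapping interval pairs slide by one frame", {
  p <- interval_pairs(0:9, 3)
  expect_equal(nrow(p), 7)
  expect_equal(p$start, 0:6)
  expect_equal(p$end, 3:9)
  expect_equal(nrow(interval_pairs(0:1, 1)), 1)
  expect_equal(nrow(interval_pairs(0:2, 3)), 0)
})

test_that("displacement converts to um/hour through the acquisition config", {
  cfg <- acquisition(pixel_size_um = 1.314, frame_interval_min = 7,
                     interval_size = 1)
  expect_equal(speed_um_per_hr(1, cfg), 1.314 * 60 / 7, tolerance = 1e-12)
  expect_equal(speed_um_per_hr(1, cfg), 11.262857, tolerance = 1e-6)
  expect_equal(speed_um_per_hr(0, cfg), 0)
  cfg2 <- acquisition(pixel_size_um = 2 * 1.314, frame_interval_min = 7,
                      interval_size = 1)
  expect_equal(speed_um_per_hr(1, cfg2), 2 * speed_um_per_hr(1, cfg))
  # interval size divides: the same pixel displacement over a frames is slower
  cfg3 <- acquisition(pixel_size_um = 1.314, frame_interval_min = 7,
                      interval_size = 3)
  expect_equal(speed_um_per_hr(1, cfg3), speed_um_per_hr(1, cfg) / 3)
})

test_that("trajectory angles follow the y-up compass convention", {
  expect_equal(angle_of_trajectory(1, -1), 45)   # up-right on screen
  expect_equal(angle_of_trajectory(1, 0), 0)
  expect_equal(angle_of_trajectory(0, -1), 90)   # up on screen
  expect_equal(angle_of_trajectory(-1, 0), 180)
  expect_equal(angle_of_trajectory(0, 1), 270)
  expect_true(is.na(angle_of_trajectory(0, 0)))
})

# independent oracle: the explicit quadrant/axis case family
oracle_angle <- function(dx, dy_screen) {
  u <- -dy_screen
  if (dx == 0 && u == 0) return(NA_real_)
  if (dx > 0 && u >= 0) return(atan(u / dx) * 180 / pi)
  if (dx == 0 && u > 0) return(90)
  if (dx < 0) return(180 + atan(u / dx) * 180 / pi)
  if (dx == 0 && u < 0) return(270)
  360 + atan(u / dx) * 180 / pi   # dx > 0, u < 0
}

test_that("trajectory angle matches the quadrant-case oracle on a dense grid", {
  theta <- seq(0, 359.9, by = 0.1)
  dx <- cos(theta * pi / 180)
  dy <- -sin(theta * pi / 180)
  got <- angle_of_trajectory(dx, dy)
  want <- vapply(seq_along(dx), function(i) oracle_angle(dx[i], dy[i]),
                 numeric(1))
  expect_equal(got, want %% 360, tolerance = 1e-9)
  expect_equal(got, theta, tolerance = 1e-9)
})

test_that("deflection is the signed smallest rotation, clockwise positive", {
  expect_equal(angle_of_deflection(90, 45), 45)    # clockwise turn
  expect_equal(angle_of_deflection(45, 90), -45)
  expect_equal(angle_of_deflection(123.4, 123.4), 0)
  expect_equal(angle_of_deflection(350, 10), -20)  # across the wrap
  expect_equal(angle_of_deflection(10, 350), 20)
  expect_equal(angle_of_deflection(0, 180), 180)   # exact reversal -> +180
  expect_true(is.na(angle_of_deflection(NA, 10)))
})

test_that("deflection agrees with brute-force wrap selection on a 1-degree grid", {
  g <- expand.grid(a = seq(0, 359, by = 1), b = seq(0, 359, by = 1))
  got <- angle_of_deflection(g$a, g$b)
  raw <- g$a - g$b
  cand <- cbind(raw, raw - 360, raw + 360)
  want <- cand[cbind(seq_len(nrow(cand)),
                     max.col(-abs(cand), ties.method = "first"))]
  want[want == -180] <- 180
  expect_equal(got, want)
  expect_true(all(got > -180 & got <= 180))
  # rotating both legs leaves the deflection unchanged
  expect_equal(angle_of_deflection((g$a + 77) %% 360, (g$b + 77) %% 360), got)
})

test_that("rotating all displacements shifts trajectory angles, not deflections", {
  tr <- jittered_straight_tracks(n = 20, len = 15, jitter_sd = 1, seed = 4)
  phi <- 33 * pi / 180
  rot <- tr
  rot$x <- cos(phi) * tr$x + sin(phi) * tr$y   # y-down frame: clockwise-free
  rot$y <- -sin(phi) * tr$x + cos(phi) * tr$y  # rotation by +phi (y-up CCW)
  k1 <- compute_kinematics(tr, acq1())
  k2 <- compute_kinematics(rot, acq1())
  ok <- !is.na(k1$theta_trajectory_deg)
  expect_equal(k2$theta_trajectory_deg[ok],
               (k1$theta_trajectory_deg[ok] + 33) %% 360, tolerance = 1e-6)
  okd <- !is.na(k1$theta_deflection_deg)
  expect_equal(k2$theta_deflection_deg[okd], k1$theta_deflection_deg[okd],
               tolerance = 1e-6)
})

test_that("signed deflections around a closed polygon sum to -360 (CCW, y-up)", {
  m <- 12
  ang <- 2 * pi * (0:(m - 1)) / m
  poly <- tibble::tibble(cell_id = 1L, frame = 0:m,
                         x = 50 + 10 * cos(c(ang, 0)),
                         y = 50 - 10 * sin(c(ang, 0)))  # CCW in y-up coords
  k <- compute_kinematics(poly, acq1())
  # complete the turn sequence with the wrap leg between last and first
  thetas <- k$theta_trajectory_deg[!is.na(k$theta_trajectory_deg)]
  defl <- angle_of_deflection(thetas, c(thetas[-1], thetas[1]))
  expect_equal(sum(defl), -360, tolerance = 1e-9)
  cw <- poly
  cw$y <- 100 - poly$y  # mirror -> clockwise
  kc <- compute_kinematics(cw, acq1())
  th <- kc$theta_trajectory_deg[!is.na(kc$theta_trajectory_deg)]
  expect_equal(sum(angle_of_deflection(th, c(th[-1], th[1]))), 360,
               tolerance = 1e-9)
})

test_that("MSD has the ballistic closed form and vanishes for stationary cells", {
  v <- 2.5
  tr <- tibble::tibble(cell_id = 1L, frame = 0:20, x = v * (0:20), y = 3)
  m <- msd_track(tr)
  expect_equal(m$msd_px2, (v * m$lag_frames)^2, tolerance = 1e-12)
  still <- tibble::tibble(cell_id = 1L, frame = 0:20, x = 5, y = 5)
  expect_equal(msd_track(still)$msd_px2, rep(0, 20))
})

test_that("MSD of a lattice random walk is diffusive", {
  n <- 10000
  withr::with_seed(12, {
    ax <- sample(c(TRUE, FALSE), n, TRUE)
    sgn <- sample(c(-1, 1), n, TRUE)
  })
  tr <- tibble::tibble(cell_id = 1L, frame = 0:n,
                       x = cumsum(c(0, ifelse(ax, sgn, 0))),
                       y = cumsum(c(0, ifelse(ax, 0, sgn))))
  m <- msd_track(tr, lags = 1:10)
  expect_equal(m$msd_px2, m$lag_frames, tolerance = 0.05)
})

test_that("population summary aggregates defined values only", {
  kin <- tibble::tibble(
    cell_id = 1:5, frame = 1L, x = 0, y = 0,
    displacement_px = c(2, 2, 2, 2, 0),
    theta_trajectory_deg = c(10, 100, 200, 300, NA),  # stationary cell: NA
    theta_deflection_deg = c(100, -120, 10, -20, NA),
    msd_px2 = 1
  )
  s <- summarize_population(kin)
  expect_equal(s$pct_turning_gt_90, 50)
  expect_equal(s$avg_abs_deflection_deg, 62.5)
  expect_equal(s$n_tracks, 5L)
  expect_equal(sum(s$direction_histogram[[1]]), 4)  # NA angle not binned
  expect_equal(which(s$direction_histogram[[1]] == 1) - 1, c(10, 100, 200, 300))

  straight <- dplyr::mutate(kin, theta_deflection_deg = c(0, 0, 0, 0, NA))
  s2 <- summarize_population(straight)
  expect_equal(s2$pct_turning_gt_90, 0)
  expect_equal(s2$avg_abs_deflection_deg, 0)
})

test_that("direction histogram of uniform angles is flat", {
  n <- 1e5
  kin <- tibble::tibble(
    cell_id = seq_len(n), frame = 1L, x = 0, y = 0, displacement_px = 1,
    theta_trajectory_deg = withr::with_seed(77, stats::runif(n, 0, 360)),
    theta_deflection_deg = NA_real_, msd_px2 = NA_real_)
  h <- summarize_population(kin)$direction_histogram[[1]]
  expect_equal(sum(h), n)
  p <- 1 / 360
  sigma <- sqrt(n * p * (1 - p))
  dev <- abs(h - n * p)
  expect_true(all(dev <= 4.5 * sigma))
  # multinomial goodness of fit against the flat distribution
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("noise suppression improves with interval size on jittered tracks", {
  tr <- cached("jitter200", jittered_straight_tracks())
  stats_by_a <- vapply(1:5, function(a) {
    k <- compute_kinematics(tr, acq1(a))
    d <- abs(k$theta_deflection_deg)
    d <- d[!is.na(d)]
    c(mean(d), stats::sd(d))
  }, numeric(2))
  expect_true(all(diff(stats_by_a[1, ]) <= 0))
  expect_true(all(diff(stats_by_a[2, ]) <= 0))
  expect_gt(stats_by_a[1, 1] - stats_by_a[1, 3],
            stats_by_a[1, 3] - stats_by_a[1, 5])
})

test_that("mean absolute deflection increases with simulator turning noise", {
  cfg <- acq1()
  vals <- vapply(c(10, 30, 60, 120), function(sig) {
    tr <- simulate_prw(prw_params(n_cells = 80, n_frames = 40,
                                  turn_sigma_deg = sig, config = cfg),
                       seed = 101)
    k <- compute_kinematics(tr, cfg)
    mean(abs(k$theta_deflection_deg), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
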