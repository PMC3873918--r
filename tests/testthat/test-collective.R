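test_that("pairwise angle SD is |difference| / sqrt(2)", {
  expect_equal(pair_angle_sd(123, 123), 0)
  expect_equal(pair_angle_sd(0, 90), 90 / sqrt(2))
  expect_equal(pair_angle_sd(0, 90), 63.64, tolerance = 1e-4)
  # the wrap pathology the exclusion rule exists for
  expect_equal(pair_angle_sd(10, 350), 340 / sqrt(2))
  expect_equal(pair_angle_sd(10, 350), 240.4, tolerance = 1e-3)
})

test_that("the exclusion rule drops wrap-straddling pairs only", {
  pairs <- tibble::tibble(theta_a = c(45, 45, 300, 91, 89),
                          theta_b = c(300, 135, 45, 350, 271))
  kept <- apply_exclusion(pairs)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$theta_a, c(45, 91))  # (45,135) kept; 91 is outside 0-90
  withr::with_seed(8, {
    u <- tibble::tibble(theta_a = stats::runif(1e5, 0, 360),
                        theta_b = stats::runif(1e5, 0, 360))
  })
  frac <- 1 - nrow(apply_exclusion(u)) / nrow(u)
  sigma <- sqrt(0.125 * 0.875 / 1e5)
  expect_lt(abs(frac - 1 / 8), 3 * sigma)  # analytic 2 * (90/360)^2
})

test_that("nearest-neighbor pairs are gated, unordered and deduplicated", {
  cfg <- acquisition(pixel_size_um = 1)
  cells <- tibble::tibble(cell_id = 1:2, x = c(0, 50), y = 0, theta = c(10, 20))
  expect_equal(nrow(neighbor_pairs(cells, 100, cfg)), 1)
  far <- dplyr::mutate(cells, x = c(0, 150))
  expect_equal(nrow(neighbor_pairs(far, 100, cfg)), 0)
  # three collinear cells at 0, 60, 120 um: middle cell shared
  tri <- tibble::tibble(cell_id = 1:3, x = c(0, 60, 120), y = 0, theta = 0)
  p <- neighbor_pairs(tri, 100, cfg)
  expect_equal(nrow(p), 2)
  expect_equal(p[, c("cell_a", "cell_b")],
               tibble::tibble(cell_a = 1:2, cell_b = 2:3))
  # all-pairs mode keeps every pair within the radius
  expect_equal(nrow(neighbor_pairs(tri, 100, cfg, pairing = "all_within")), 2)
  expect_equal(nrow(neighbor_pairs(tri, 200, cfg, pairing = "all_within")), 3)
})

make_kin <- function(theta_fun, n = 60, frames = 3, spacing = 30, seed = 1) {
  # cells on a grid (spacing in px) with per-cell angles from theta_fun
  side <- ceiling(sqrt(n))
  g <- expand.grid(ix = 0:(side - 1), iy = 0:(side - 1))[1:n, ]
  withr::with_seed(seed, {
    purrr::map(0:(frames - 1), function(f) {
      tibble::tibble(cell_id = 1:n, frame = f,
                     x = g$ix * spacing, y = g$iy * spacing,
                     displacement_px = 1,
                     theta_trajectory_deg = theta_fun(n),
                     theta_deflection_deg = NA_real_, msd_px2 = NA_real_)
    }) |> dplyr::bind_rows()
  })
}

test_that("perfect alignment gives PRMI 0; uniform angles give ~84.85", {
  cfg <- acquisition(pixel_size_um = 1)
  aligned <- make_kin(function(n) rep(77, n), n = 100)
  expect_equal(prmi(aligned, "nearest_neighbor", cfg)$prmi_deg, 0)
  expect_equal(prmi(aligned, "random_pairing", cfg, seed = 3)$prmi_deg, 0)
  unif <- make_kin(function(n) stats::runif(n, 0, 360), n = 900, frames = 12)
  r <- prmi(unif, "random_angles", cfg, seed = 4)
  expect_gte(r$n_pairs, 1e4)
  expect_equal(r$prmi_deg, 120 / sqrt(2), tolerance = 0.015)
  expect_false(r$exclusion_applied)
})

test_that("PRMI with wrapped-normal noise matches its Monte-Carlo expectation", {
  cfg <- acquisition(pixel_size_um = 1)
  sd_deg <- 20
  flow <- make_kin(function(n) (45 + stats::rnorm(n, 0, sd_deg)) %% 360,
                   n = 900, frames = 12, seed = 6)
  r <- prmi(flow, "nearest_neighbor", cfg)
  # E|d1 - d2| for two iid N(0, sd): sd * 2 / sqrt(pi)
  expected <- sd_deg * sqrt(2) * 2 / sqrt(2 * pi) / sqrt(2)
  expect_equal(r$prmi_deg, expected, tolerance = 0.05)
})

test_that("random modes are reproducible and independent of true structure", {
  cfg <- acquisition(pixel_size_um = 1)
  k <- make_kin(function(n) stats::runif(n, 0, 360), n = 400, frames = 5)
  a <- prmi(k, "random_angles", cfg, seed = 9)
  b <- prmi(k, "random_angles", cfg, seed = 9)
  expect_identical(a, b)
  aligned <- make_kin(function(n) rep(10, n), n = 400, frames = 5)
  c2 <- prmi(aligned, "random_angles", cfg, seed = 9)
  expect_equal(a$prmi_deg, c2$prmi_deg)  # null ignores the real angles
  expect_error(prmi(k, "random_pairing", cfg), "seed")
})

test_that("PRMI is rotation invariant without exclusion, nearly so with", {
  cfg <- acquisition(pixel_size_um = 1)
  base_angles <- withr::with_seed(11, (90 + stats::rnorm(900, 0, 15)) %% 360)
  for (phi in c(0, 111, 222, 333)) {
    k <- make_kin(function(n) (base_angles + phi) %% 360, n = 900, frames = 1)
    r <- prmi(k, "nearest_neighbor", cfg)
    if (phi == 0) base_val <- r$prmi_deg
    expect_lt(abs(r$prmi_deg - base_val), 2)
  }
})

test_that("PRMI increases with alignment noise and detects local coupling", {
  cfg <- acq1()
  vals <- vapply(c(5, 25, 60, 90), function(sig) {
    k <- make_kin(function(n) (stats::rnorm(n, 45, sig)) %% 360,
                  n = 400, frames = 6, seed = 20 + sig)
    prmi(k, "nearest_neighbor", acquisition(pixel_size_um = 1))$prmi_deg
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # locally aligned, globally disordered: nearest-neighbor < random pairing
  cp <- collective_params(prw_params(n_cells = 300, n_frames = 40,
                                     turn_sigma_deg = 25, config = cfg),
                          coupling_radius_um = 120, alignment_weight = 0.6)
  k <- compute_kinematics(simulate_collective(cp, seed = 21), cfg)
  nn <- prmi(k, "nearest_neighbor", cfg)
  rp <- prmi(k, "random_pairing", cfg, seed = 5)
  ra <- prmi(k, "random_angles", cfg, seed = 5)
  expect_lt(nn$prmi_deg, rp$prmi_deg)
  expect_lt(rp$prmi_deg, ra$prmi_deg)
})

test_that("leading-edge profile reports spatial structure honestly", {
  cfg <- acq1()
  # no spatial structure: all bins sit at the uniform-angle ceiling
  unif <- make_kin(function(n) stats::runif(n, 0, 360), n = 900, frames = 12)
  prof <- leading_edge_profile(unif, acquisition(pixel_size_um = 1),
                               bin_width_um = 300, min_pairs = 50)
  # raw uniform pairs within a bin, exclusion applied: expectation ~69.7 deg
  expect_true(all(abs(prof$prmi_deg - (120 - 270 / 8) / (7 / 8) / sqrt(2)) < 3))

  # alignment decaying from the x = 0 edge: PRMI strictly increases
  cp <- collective_params(prw_params(n_cells = 400, n_frames = 40,
                                     turn_sigma_deg = 2, config = cfg),
                          coupling_radius_um = 100, alignment_weight = 0.5,
                          edge_gradient = 0.05)
  k <- compute_kinematics(simulate_collective(cp, seed = 22), cfg)
  prof2 <- leading_edge_profile(k, cfg, bin_width_um = 250)
  expect_true(all(diff(prof2$prmi_deg) > 0))

  # a bin with a single cell is undefined, not zero
  lone <- make_kin(function(n) rep(10, n), n = 2, frames = 2, spacing = 4000)
  prof3 <- leading_edge_profile(lone, acquisition(pixel_size_um = 1),
                                bin_width_um = 100)
  expect_true(all(is.na(prof3$prmi_deg)))
})
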