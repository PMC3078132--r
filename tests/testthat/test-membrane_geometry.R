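leaflet_sheets <- function(h = 19, n = 5, spacing = 8, jitter = 0) {
  g <- (seq_len(n) - (n + 1) / 2) * spacing
  grid <- as.matrix(expand.grid(g, g))
  pts <- rbind(cbind(grid, h), cbind(grid, -h))
  if (jitter > 0) pts <- pts + matrix(rnorm(length(pts), sd = jitter),
                                      nrow = nrow(pts))
  pts
}

test_that("membrane frame is recovered from two leaflet sheets", {
  pts <- leaflet_sheets(h = 19)
  mf <- estimate_membrane_frame(pts, seq_len(nrow(pts)))
  expect_equal(abs(mf$normal[3]), 1, tolerance = 1e-9)
  expect_equal(mf$midplane_point[3], 0, tolerance = 1e-9)
  expect_equal(mf$leaflet_half_thickness, 19, tolerance = 1e-9)
})

test_that("membrane frame estimation is rotation-equivariant", {
  pts <- leaflet_sheets(h = 19)
  a <- 30 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
               3, 3, byrow = TRUE)
  mf <- estimate_membrane_frame(pts %*% t(Rx), seq_len(nrow(pts)))
  expected <- Rx %*% c(0, 0, 1)
  expect_equal(abs(sum(mf$normal * expected)), 1, tolerance = 1e-9)
  expect_equal(mf$leaflet_half_thickness, 19, tolerance = 1e-9)
})

test_that("fallback frame and degenerate references behave as declared", {
  mf <- estimate_membrane_frame(matrix(rnorm(30), 10, 3), NULL)
  expect_equal(mf$normal, c(0, 0, 1))
  expect_equal(mf$midplane_point, c(0, 0, 0))
  line_pts <- cbind(1:10, 0, rep(c(-5, 5), each = 5))[, c(1, 2, 3)]
  collinear <- cbind(seq(0, 9), 0, rep(c(-5, 5), each = 5))
  expect_error(estimate_membrane_frame(collinear, 1:10),
               class = "geometry_error")
  expect_error(estimate_membrane_frame(matrix(0, 4, 3), 1:4),
               class = "geometry_error")
})

test_that("cytoplasmic axis is the unit first-to-last residue vector", {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 3, 4))
  expect_equal(cp_axis(coords, 1, 2), c(1, 0, 0))
  expect_equal(cp_axis(coords, 1, 3), c(0, 0.6, 0.8))
  coords2 <- rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9))
  expect_error(cp_axis(coords2, 1, 2), class = "geometry_error")
})

test_that("tilt angle matches the analytic cases", {
  mf <- membrane_frame()
  expect_equal(theta_angle(c(1, 0, 0), mf), 0, tolerance = 1e-9)
  expect_equal(theta_angle(c(0, 0, 1), mf), 90, tolerance = 1e-9)
  expect_equal(theta_angle(c(1, 0, 1) / sqrt(2), mf), 45, tolerance = 1e-9)
  expect_error(theta_angle(c(1, 0, 1), mf), class = "contract_violation")
})

test_that("midplane distance matches direct point-to-plane computation", {
  mf <- membrane_frame()
  expect_equal(distance_d(rbind(c(0, 0, 30)), mf), 30)
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(30, sd = 10), 10, 3)
    n <- pts[1, ] / sqrt(sum(pts[1, ]^2))
    p0 <- rnorm(3)
    fr <- membrane_frame(p0, n)
    direct <- abs(sum(n * (colMeans(pts) - p0)))
    expect_equal(distance_d(pts, fr), direct, tolerance = 1e-9)
  }
  # invariance under in-plane translation
  shift <- c(4, -7, 0)  # perpendicular to +z normal
  expect_equal(distance_d(sweep(rbind(c(1, 2, 12)), 2, shift, "+"),
                          membrane_frame()),
               distance_d(rbind(c(1, 2, 12)), membrane_frame()))
})

test_that("theta and d are invariant under rigid transforms and normal flips", {
  set.seed(4)
  sim <- quick_sim(n_frames = 1, seed = 2, positional_noise_sd = 0)
  xyz <- frame_coords(sim$trajectory, 1)
  lip <- lipid_reference_indices(sim$trajectory)
  ca <- select_atoms(sim$trajectory, chain = "A", domain = c(1, 16))
  mf0 <- estimate_membrane_frame(xyz, lip)
  ax0 <- cp_axis(xyz, ca[1], ca[16])
  th0 <- theta_angle(ax0, mf0)
  d0 <- distance_d(xyz[ca, ], mf0)
  for (i in 1:50) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 30)
    xyz2 <- sweep(xyz %*% t(R), 2, tr, "+")
    mf2 <- estimate_membrane_frame(xyz2, lip)
    ax2 <- cp_axis(xyz2, ca[1], ca[16])
    expect_equal(theta_angle(ax2, mf2), th0, tolerance = 1e-6)
    expect_equal(distance_d(xyz2[ca, ], mf2), d0, tolerance = 1e-6)
  }
  flipped <- membrane_frame(mf0$midplane_point, -mf0$normal,
                            mf0$leaflet_half_thickness)
  expect_equal(theta_angle(ax0, flipped), th0, tolerance = 1e-12)
  expect_equal(distance_d(xyz[ca, ], flipped), d0, tolerance = 1e-12)
})

test_that("tilt grows strictly with the axis' out-of-plane component", {
  mf <- membrane_frame()
  zc <- seq(0.05, 0.95, by = 0.1)
  th <- sapply(zc, function(z) theta_angle(unit3(c(sqrt(1 - z^2), 0, z)), mf))
  expect_true(all(diff(th) > 0))
})

test_that("orientation series inverts the generator exactly without noise", {
  cfg <- synthetic_config(n_frames = 20, dt_ps = 10, positional_noise_sd = 0,
                          theta_sds = c(extended = 0, bent = 0),
                          d_sds = c(extended = 0, bent = 0),
                          switch_rates = c(0, 0), seed = 5)
  sim <- generate_synthetic(cfg)
  for (ch in c("A", "D")) {
    os <- orientation_series(sim$trajectory, ch,
                             lipid_ref = lipid_reference_indices(sim$trajectory))
    expect_equal(os$theta, rep(41.19, 20), tolerance = 1e-9)
    expect_equal(os$d, rep(30.00, 20), tolerance = 1e-9)
  }
})

test_that("planted stochastic tilt path is recovered within the noise envelope", {
  sim <- quick_sim(n_frames = 300, seed = 8, switch_rates = c(0, 0))
  os <- orientation_series(sim$trajectory, "B",
                           lipid_ref = lipid_reference_indices(sim$trajectory),
                           per_frame_membrane = FALSE)
  planted <- sim$truth$theta[, 2]
  # endpoint noise of 0.5 A on a ~23 A lever arm: ~2 degrees per frame
  expect_lt(max(abs(os$theta - planted)), 8)
  expect_lt(mean(abs(os$theta - planted)), 2.5)
  expect_lt(mean(abs(os$d - sim$truth$d[, 2])), 1)
})

test_that("a chain missing cytoplasmic residues raises a selection error", {
  sim <- quick_sim(n_frames = 2, seed = 13)
  tr <- sim$trajectory
  keep <- !(tr$topology$chain_id == "A" & tr$topology$residue_number == 16L)
  tr2 <- trajectory(tr$topology[keep, ], tr$coords[keep, , , drop = FALSE],
                    tr$times)
  expect_error(orientation_series(tr2, "A"), "16", class = "selection_error")
})
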