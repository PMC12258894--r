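test_that("charged-group z-displacement tracks planted translations", {
  b <- make_helix_bundle(1, residue_names = c("ALA", "ARG"),
                         n_residues = 8, start_residue = 207)
  px <- charge_group_proxies(b$atoms, c(208, 210))
  expect_named(px, c("A208", "A210"))
  # static: zeros
  tr <- static_traj(b$coords, 4)
  expect_true(all(charge_z_displacement(tr, px) == 0))
  # step translation of +3 A along z from frame 3 on
  arr <- tr$coords
  arr[3, , 3] <- arr[3, , 3] + 3
  arr[4, , 3] <- arr[4, , 3] + 3
  zd <- charge_z_displacement(trajectory(arr), px)
  expect_equal(unname(zd[, 1]), c(0, 0, 3, 3))
  expect_error(charge_group_proxies(b$atoms, 9999), "not in atom table")
  expect_error(charge_group_proxies(b$atoms, 207), "no charged-group")
})

test_that("helix tilt matches a closed-form rotation oracle", {
  b <- make_helix_bundle(1, tilt_deg = 0, n_residues = 20)
  idx <- select_atoms(b$atoms, name = "CA")
  tr <- static_traj(b$coords, 1)
  expect_equal(helix_tilt(tr, idx), 0, tolerance = 0.5)
  rot_x <- function(th) matrix(c(1, 0, 0, 0, cos(th), -sin(th),
                                 0, sin(th), cos(th)), 3, byrow = TRUE)
  tr30 <- static_traj(b$coords %*% t(rot_x(30 * pi / 180)), 1)
  expect_equal(helix_tilt(tr30, idx), 30, tolerance = 0.5)
  # random rigid rotation: tilt equals the angle of the rotated axis
  set.seed(2)
  for (k in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi / 3)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                  -ax[2], ax[1], 0), 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    xyz <- b$coords[idx, ]
    v0 <- svd(sweep(xyz, 2, colMeans(xyz)))$v[, 1]
    expected <- acos(abs((R %*% v0)[3])) * 180 / pi
    got <- helix_tilt(static_traj(b$coords %*% t(R), 1), idx)
    expect_equal(got, expected, tolerance = 0.5)
  }
  expect_error(helix_tilt(tr, idx[1:3]), ">= 4 atoms")
})

test_that("tilt is invariant and displacement equivariant under z shifts", {
  b <- make_helix_bundle(1, tilt_deg = 15, n_residues = 15)
  idx <- select_atoms(b$atoms, name = "CA")
  tr <- static_traj(b$coords, 2)
  shifted <- tr$coords
  shifted[2, , 3] <- shifted[2, , 3] + 5
  trs <- trajectory(shifted)
  expect_equal(helix_tilt(trs, idx)[2], helix_tilt(tr, idx)[2])
  expect_equal(unname(helix_com_displacement(trs, idx)[2, "dz"]), 5)
})

test_that("COM displacement reproduces planted translations", {
  b <- make_helix_bundle(1, n_residues = 10)
  idx <- select_atoms(b$atoms, name = "CA")
  arr <- static_traj(b$coords, 2)$coords
  arr[2, , ] <- sweep(arr[2, , ], 2, c(2, -1, 3), "+")
  d <- helix_com_displacement(trajectory(arr), idx)
  expect_equal(unname(d[2, ]), c(2, -1, 3))
  expect_error(helix_com_displacement(trajectory(arr), integer(0)),
               "empty selection")
})

test_that("Boltzmann inversion recovers the planted harmonic curvature", {
  set.seed(9)
  sd0 <- 0.5; n <- 1e5
  x <- rnorm(n, sd = sd0); y <- rnorm(n, sd = sd0)
  fs <- free_energy_surface(x, y, nbins = 40)
  grid <- expand.grid(x = fs$x, y = fs$y)
  r2 <- grid$x^2 + grid$y^2
  Fv <- as.vector(fs$F)
  keep <- is.finite(Fv) & r2 < (2 * sd0)^2
  fit <- stats::lm(Fv[keep] ~ r2[keep])
  k_true <- vg_constants$R_kcal * 300 / (2 * sd0^2)
  expect_equal(unname(stats::coef(fit)[2]), k_true, tolerance = 0.15)
})

test_that("superposed RMSD matches a brute-force rotation-grid oracle", {
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0.5), ncol = 3, byrow = TRUE)
  set.seed(4)
  b <- a + matrix(rnorm(9, sd = 0.3), ncol = 3)
  tr <- static_traj(b, 1)
  got <- rmsd_series(tr, a, idx = 1:3)
  expect_equal(got, bruteforce_rmsd(a, b), tolerance = 1e-3)
  # identity and rigid displacement give zero after superposition
  expect_equal(rmsd_series(static_traj(a, 1), a, 1:3), 0,
               tolerance = 1e-8)
  moved <- sweep(a, 2, c(3, -2, 7), "+")
  expect_equal(rmsd_series(static_traj(moved, 1), a, 1:3), 0,
               tolerance = 1e-6)
})

test_that("pore water counting respects slab and radial bounds", {
  set.seed(5)
  inside <- cbind(runif(12, -3, 3), runif(12, -3, 3), runif(12, -4, 4))
  outside <- rbind(cbind(runif(3, -3, 3), runif(3, -3, 3),
                         runif(3, 6, 10)),       # above slab
                   cbind(runif(2, 9, 12), 0, 0)) # outside radius
  xyz <- rbind(inside, outside)
  tr <- static_traj(xyz, 2)
  reg <- pore_region(lower = -5, upper = 5, radial_cutoff = 8)
  expect_equal(pore_water_count(tr, reg, seq_len(nrow(xyz))),
               c(12L, 12L))
  expect_equal(pore_water_count(tr, reg, integer(0)), c(0L, 0L))
  bad <- pore_region(lower = 5, upper = -5)
  expect_error(pore_water_count(tr, bad, 1:3), "frame 1")
})

test_that("anchored pore bounds follow the anchor atoms per frame", {
  # anchor atoms define upper bound via their centroid z
  anchors <- rbind(c(0, 0, 6), c(0, 0, 4))   # centroid z = 5
  waters <- rbind(c(0, 0, 4.5), c(0, 0, 5.5))
  xyz <- rbind(anchors, waters)
  tr <- static_traj(xyz, 1)
  reg <- pore_region(lower = -5, upper = 1:2, radial_cutoff = 8)
  expect_equal(pore_water_count(tr, reg, 3:4), 1L)
})

test_that("pore radius profile matches ring geometry", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(10 * cos(ang), 10 * sin(ang), 0)
  prof <- pore_radius_profile(ring, radii = rep(2, 8), z_range = c(-5, 5),
                              dz = 1)
  expect_equal(prof$radius[prof$z == 0], 8.0)
  expect_true(all(prof$flagged[abs(prof$z) > 3]))
  expect_equal(prof$radius[prof$z == 5], 15)  # empty slice -> max probe
  # two stacked rings: inner ring shrinks the profile
  ring2 <- rbind(ring, cbind(6 * cos(ang), 6 * sin(ang), 4))
  prof2 <- pore_radius_profile(ring2, radii = rep(2, 16),
                               z_range = c(0, 4), dz = 1)
  expect_equal(prof2$radius[prof2$z == 0], 8.0)
  expect_equal(prof2$radius[prof2$z == 4], 4.0)
  expect_true(all(diff(prof2$radius) <= 0))
  empty <- pore_radius_profile(ring, rep(2, 8), z_range = c(50, 52),
                               dz = 1)
  expect_true(all(empty$flagged) && all(empty$radius == 15))
})

test_that("permeation detection equals the boundary-automaton oracle", {
  expect_equal(nrow(detect_permeations(c(-10, 0, -10), -5, 5)), 0)
  ev <- detect_permeations(c(-10, 0, 10), -5, 5)
  expect_equal(ev$direction, "up")
  set.seed(6)
  for (k in 1:20) {
    zt <- cumsum(rnorm(500, sd = 3))
    ev <- detect_permeations(zt, -5, 5)
    orc <- permeation_oracle(zt, -5, 5)
    expect_equal(sum(ev$direction == "up"), unname(orc["up"]))
    expect_equal(sum(ev$direction == "down"), unname(orc["down"]))
    # reversing time flips up and down counts exactly
    rev_ev <- detect_permeations(rev(zt), -5, 5)
    expect_equal(sum(rev_ev$direction == "down"),
                 sum(ev$direction == "up"))
    expect_equal(sum(rev_ev$direction == "up"),
                 sum(ev$direction == "down"))
  }
})

test_that("conductance follows g = Ne/(VT) with correct scaling", {
  expect_equal(conductance(0, 0, voltage = 0.75, duration_s = 2e-6), 0)
  g <- conductance(7, 0, voltage = 0.75, duration_s = 2e-6)
  expect_equal(g, 7 * 1.602176634e-19 / (0.75 * 2e-6))
  expect_equal(conductance(14, 0, 0.75, 2e-6), 2 * g)
  expect_equal(conductance(7, 0, 1.5, 2e-6), g / 2)
  expect_error(conductance(1, 0, voltage = 0, duration_s = 1), "zero")
})

test_that("running average and chain averaging behave on simple series", {
  x <- c(rep(0, 10), rep(2, 10))
  ra <- running_average(x, window = 4)
  expect_equal(ra[5], 0)
  expect_equal(ra[16], 2)
  expect_equal(ra[10], mean(x[8:12]))
  m <- cbind(a1 = 1:3, a2 = 3:5, b1 = c(10, 10, 10))
  avg <- average_by_chain(m, c("A", "A", "B"))
  expect_equal(unname(avg[, "A"]), c(2, 3, 4))
  expect_equal(unname(avg[, "B"]), c(10, 10, 10))
})
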