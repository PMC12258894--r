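test_that("smeared charge density is normalized with the Gaussian peak", {
  box <- c(60, 60, 60)
  dens <- smear_charges(rbind(c(30, 30, 30)), 1, box)
  expect_equal(sum(dens$values) * 1^3, 1.0, tolerance = 1e-4)
  # peak at the charge site: (beta/sqrt(pi))^3 for beta = 0.25
  expect_equal(max(dens$values), (0.25 / sqrt(pi))^3, tolerance = 1e-6)
  expect_equal(dens$values[31, 31, 31], max(dens$values))
})

test_that("smearing is linear and wraps atoms periodically", {
  box <- c(40, 40, 40)
  d1 <- smear_charges(rbind(c(10, 20, 20)), 1, box)
  d2 <- smear_charges(rbind(c(25, 20, 20)), -0.5, box)
  d12 <- smear_charges(rbind(c(10, 20, 20), c(25, 20, 20)), c(1, -0.5),
                       box)
  expect_equal(d12$values, d1$values + d2$values, tolerance = 1e-12)
  # an atom outside the box wraps, never errors
  d3 <- smear_charges(rbind(c(10 + 40, 20, 20 - 40)), 1, box)
  expect_equal(d3$values, d1$values, tolerance = 1e-12)
})

test_that("the periodic Poisson solve matches the erf image-sum oracle", {
  box <- c(100, 100, 100)
  coords <- rbind(c(50, 50, 45), c(50, 50, 55))
  q <- c(1, -1); beta <- 0.25
  phi <- solve_poisson(smear_charges(coords, q, box, beta = beta))
  probes <- rbind(c(50, 50, 40), c(50, 50, 60), c(50, 55, 45),
                  c(45, 50, 55), c(50, 50, 50), c(55, 55, 50))
  oracle <- vapply(seq_len(nrow(probes)), function(k) {
    s <- 0
    for (nx in -4:4) for (ny in -4:4) for (nz in -4:4)
      for (i in 1:2) {
        r <- sqrt(sum((probes[k, ] - coords[i, ] -
                         c(nx, ny, nz) * box)^2))
        s <- s + q[i] * pracma::erf(beta * r) / r
      }
    s
  }, numeric(1))
  got <- potential_at(phi, probes, include_external = FALSE)
  # compare gauge-free (the oracle sum carries its own constant)
  off <- mean(got - oracle)
  expect_lt(max(abs(got - off - oracle)) / max(abs(oracle)), 0.02)
})

test_that("the solver is linear and gauge-fixed to zero mean", {
  box <- c(40, 40, 40)
  d1 <- smear_charges(rbind(c(10, 20, 20), c(30, 20, 20)), c(1, -1), box)
  d2 <- smear_charges(rbind(c(20, 10, 20), c(20, 30, 20)), c(2, -2), box)
  zero <- scalar_grid(array(0, dim = dim(d1$values)), spacing = 1)
  expect_true(all(solve_poisson(zero)$values == 0))
  p1 <- solve_poisson(d1); p2 <- solve_poisson(d2)
  d12 <- scalar_grid(3 * d1$values + d2$values, spacing = 1)
  p12 <- solve_poisson(d12)
  expect_equal(p12$values, 3 * p1$values + p2$values,
               tolerance = 1e-10)
  expect_lt(abs(mean(p1$values)), 1e-12)
})

test_that("the solve is equivariant under lattice-commensurate shifts", {
  box <- c(40, 40, 40)
  p1 <- solve_poisson(smear_charges(rbind(c(10, 20, 20), c(30, 20, 20)),
                                    c(1, -1), box))
  p2 <- solve_poisson(smear_charges(rbind(c(10, 20, 25), c(30, 20, 25)),
                                    c(1, -1), box))
  shifted <- p1$values[, , c(36:40, 1:35)]  # shift by +5 voxels in z
  expect_equal(p2$values, shifted, tolerance = 1e-10)
})

test_that("net-charge densities are neutralized and flagged", {
  box <- c(40, 40, 40)
  dens <- smear_charges(rbind(c(20, 20, 20)), 1, box)
  phi <- solve_poisson(dens)
  expect_true(attr(phi, "neutralized"))
})

test_that("the external ramp has the exact gradient and drop", {
  g <- scalar_grid(array(0, dim = c(20, 20, 110)), spacing = 1)
  phi <- solve_poisson(g)
  phi <- add_external_field(phi, 0.75)
  z <- seq(0, 100, by = 10)
  ramp <- external_ramp(phi, z)
  grad <- diff(ramp) / diff(z)
  expect_equal(grad, rep(-0.75 / 110, length(grad)), tolerance = 1e-12)
  expect_equal(abs(grad[1]) * 1000, 6.8181818, tolerance = 1e-6)
  # face-to-face drop across the full box is exactly V
  expect_equal(external_ramp(phi, 0) - external_ramp(phi, 110), 0.75)
  # V = 0 leaves the potential untouched
  phi0 <- add_external_field(phi, 0)
  expect_equal(external_ramp(phi0, z), rep(0, length(z)))
})

test_that("trajectory averaging reduces to the single-frame map", {
  box <- c(30, 30, 30)
  xyz <- rbind(c(10, 15, 15), c(20, 15, 15))
  arr <- array(NA_real_, dim = c(3, 2, 3))
  for (i in 1:3) arr[i, , ] <- xyz
  tr <- trajectory(arr, box = box)
  avg <- average_potential(tr, charges = c(1, -1))
  single <- solve_poisson(smear_charges(xyz, c(1, -1), box))
  expect_equal(avg$values, single$values, tolerance = 1e-12)
  # two frames with the charge pair mirrored in z: average is symmetric
  # under z-reflection about the box center
  arr2 <- array(NA_real_, dim = c(2, 2, 3))
  arr2[1, , ] <- rbind(c(15, 15, 10), c(15, 15, 20))
  arr2[2, , ] <- rbind(c(15, 15, 20), c(15, 15, 10))
  avg2 <- average_potential(trajectory(arr2, box = box), c(1, -1))
  v <- avg2$values
  # grid point z index k maps to 32 - k under reflection through z = 15
  refl <- v[, , c(1, 30:2)]
  expect_equal(v[, , 2:30], refl[, , 2:30], tolerance = 1e-8)
  badbox <- matrix(c(30, 30, 30, 30, 30, 35), 2, byrow = TRUE)
  trb <- trajectory(arr2, box = badbox)
  expect_error(average_potential(trb, c(1, -1)), "1%")
})

test_that("trilinear interpolation is exact at nodes and linear fields", {
  set.seed(8)
  vals <- array(rnorm(5 * 5 * 5), dim = c(5, 5, 5))
  g <- scalar_grid(vals, origin = c(1, 2, 3), spacing = 2)
  pts <- expand.grid(x = 1 + 2 * (0:4), y = 2 + 2 * (0:4),
                     z = 3 + 2 * (0:4))
  got <- potential_at(g, as.matrix(pts))
  expect_equal(got, as.vector(vals), tolerance = 1e-12)
  # linear-in-z field is reproduced exactly between nodes
  zlin <- array(0, dim = c(4, 4, 4))
  for (k in 1:4) zlin[, , k] <- 2 * k
  gl <- scalar_grid(zlin, spacing = 1)
  expect_equal(potential_at(gl, rbind(c(1, 1, 1.25))), 4.5)
  expect_error(potential_at(gl, rbind(c(10, 0, 0))), "outside")
})

test_that("plane slices reproduce constant and linear fields", {
  const <- scalar_grid(array(7, dim = c(10, 10, 10)))
  sl <- plane_slice(const, c(0, 0, 0), c(9, 0, 0), c(0, 0, 9))
  expect_true(all(sl$values == 7))
  zlin <- array(0, dim = c(10, 10, 10))
  for (k in 1:10) zlin[, , k] <- k
  gl <- scalar_grid(zlin)
  sl2 <- plane_slice(gl, c(0, 0, 0), c(9, 0, 0), c(0, 0, 9))
  expect_equal(sl2$values[1, ], sl2$v + 1, tolerance = 1e-12)
  expect_error(plane_slice(const, c(0, 0, 0), c(9, 0, 0), c(18, 0, 0)),
               "collinear")
})

test_that("potential grids export mV with the ramp folded in", {
  g <- scalar_grid(array(0, dim = c(5, 5, 10)), spacing = 1)
  phi <- add_external_field(solve_poisson(g), 0.5)
  f <- withr::local_tempfile(fileext = ".dx")
  export_potential_dx(phi, f)
  g2 <- read_dx(f)
  # grid plane z = 0 sits at +V/2 under the symmetric ramp convention
  expect_equal(g2$values[1, 1, 1], 250, tolerance = 1e-6)
  expect_equal(g2$values[1, 1, 1] - g2$values[1, 1, 10],
               0.5 * 9 / 10 * 1000, tolerance = 1e-6)
})
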