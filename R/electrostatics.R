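#' Gaussian-smeared charge density on a periodic grid
#'
#' Each atomic charge q_i at r_i contributes a spherical Gaussian density
#' \deqn{\rho_i(r) = q_i (\beta/\sqrt{\pi})^3 \exp(-\beta^2 |r - r_i|^2)}
#' accumulated on a regular grid covering the periodic box. The Gaussian
#' is separable, so each atom is deposited as an outer product of three
#' 1-D profiles, truncated where the density falls below 1e-10 of its
#' peak; periodic images are included by per-axis image sums (which the
#' separable form factorizes exactly), so small boxes are handled too.
#'
#' @param coords n_atoms x 3 coordinates (Angstrom).
#' @param charges per-atom charges (e); zero-charge atoms are skipped.
#' @param box length-3 box edges (Lx, Ly, Lz) in Angstrom.
#' @param beta inverse Gaussian width in 1/Angstrom (default 0.25).
#' @param spacing grid spacing in Angstrom (default 1.0); box edges must
#'   be integer multiples of it.
#' @param origin grid origin (default (0,0,0)).
#' @return a \code{\link{scalar_grid}} of charge density (e/Angstrom^3),
#'   with attribute \code{net_charge}.
#' @export
smear_charges <- function(coords, charges, box, beta = 0.25,
                          spacing = 1.0, origin = c(0, 0, 0)) {
  stopifnot(beta > 0, spacing > 0, length(box) == 3)
  n <- round(box / spacing)
  if (max(abs(n * spacing - box)) > 1e-6)
    stop("box edges must be integer multiples of the grid spacing")
  rcut <- sqrt(-log(1e-10)) / beta
  vals <- array(0, dim = n)
  peak <- (beta / sqrt(pi))^3
  axes <- lapply(1:3, function(k) origin[k] + (seq_len(n[k]) - 1) * spacing)
  # the 3-D Gaussian image sum factorizes into per-axis image sums
  axis_profile <- function(k, xi) {
    d <- axes[[k]] - xi
    d <- d - box[k] * round(d / box[k])     # nearest image
    m_max <- ceiling(rcut / box[k] - 0.5)   # extra image shells if needed
    g <- numeric(length(d))
    for (m in -m_max:m_max) {
      dm <- d + m * box[k]
      inside <- abs(dm) <= rcut
      g[inside] <- g[inside] + exp(-beta^2 * dm[inside]^2)
    }
    g
  }
  for (a in which(abs(charges) > 0)) {
    g <- lapply(1:3, function(k) axis_profile(k, coords[a, k]))
    keep <- lapply(g, function(x) which(x > 0))
    contrib <- charges[a] * peak *
      (g[[1]][keep[[1]]] %o% g[[2]][keep[[2]]] %o% g[[3]][keep[[3]]])
    vals[keep[[1]], keep[[2]], keep[[3]]] <-
      vals[keep[[1]], keep[[2]], keep[[3]]] + contrib
  }
  out <- scalar_grid(vals, origin = origin, spacing = spacing,
                     periodic = TRUE, units_label = "e/Angstrom^3")
  attr(out, "net_charge") <- sum(vals) * spacing^3
  out
}

#' Solve the periodic Poisson equation on a grid
#'
#' Spectral (FFT) solution of \eqn{\nabla^2 \phi = -4 \pi \rho} in
#' Gaussian units: density in e/Angstrom^3 gives potential in e/Angstrom
#' (multiply by 14.39964 for volts). The k = 0 mode is set to zero, which
#' fixes the mean of the potential to zero (gauge) and, for a net-charged
#' density, is equivalent to adding a uniform neutralizing background
#' (flagged in the result).
#'
#' @param density a periodic \code{\link{scalar_grid}} of charge density.
#' @return a \code{"potential_grid"} (a \code{scalar_grid} subclass) in
#'   e/Angstrom with fields \code{applied_voltage} (0) and attribute
#'   \code{neutralized} if a background was implied.
#' @export
solve_poisson <- function(density) {
  stopifnot(inherits(density, "scalar_grid"))
  if (!density$periodic) stop("spectral solve requires a periodic grid")
  d <- dim(density$values)
  L <- d * density$spacing
  rho_k <- stats::fft(density$values)
  kcomp <- function(nk, Lk) {
    m <- c(0:(nk %/% 2), -((nk - nk %/% 2 - 1):1))[seq_len(nk)]
    2 * pi * m / Lk
  }
  kx <- kcomp(d[1], L[1]); ky <- kcomp(d[2], L[2]); kz <- kcomp(d[3], L[3])
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  k2[1, 1, 1] <- Inf                      # drop k = 0 (mean-zero gauge)
  phi_k <- 4 * pi * rho_k / k2
  phi <- Re(stats::fft(phi_k, inverse = TRUE)) / prod(d)
  out <- scalar_grid(phi, origin = density$origin,
                     spacing = density$spacing, periodic = TRUE,
                     units_label = "e/Angstrom")
  class(out) <- c("potential_grid", class(out))
  out$applied_voltage <- 0
  net <- attr(density, "net_charge")
  attr(out, "neutralized") <- !is.null(net) && abs(net) > 1e-6
  out
}

#' Attach an external membrane voltage to a potential grid
#'
#' Records a linear potential ramp with a total drop of magnitude V
#' across the box along z. The ramp is stored separately from the
#' protein field (which stays inspectable) and added when values are
#' queried with \code{include_external = TRUE} or exported. Sign
#' convention: for positive (depolarizing) V the potential is higher on
#' the intracellular (low z) side, i.e. the ramp decreases with z at
#' gradient V / Lz.
#'
#' @param grid a \code{"potential_grid"}.
#' @param voltage applied voltage in volts.
#' @param intracellular_low_z flip to \code{FALSE} to reverse the sign
#'   convention.
#' @return the grid with \code{applied_voltage} set.
#' @export
add_external_field <- function(grid, voltage, intracellular_low_z = TRUE) {
  stopifnot(inherits(grid, "potential_grid"))
  grid$applied_voltage <- voltage
  grid$intracellular_low_z <- intracellular_low_z
  grid
}

#' Evaluate the external ramp at given z
#'
#' @param grid a \code{"potential_grid"} with an applied voltage.
#' @param z numeric z coordinates (Angstrom).
#' @return ramp potential in volts (0 everywhere if no voltage applied).
#' @export
external_ramp <- function(grid, z) {
  V <- grid$applied_voltage
  if (is.null(V) || V == 0) return(rep(0, length(z)))
  Lz <- dim(grid$values)[3] * grid$spacing
  sgn <- if (isTRUE(grid$intracellular_low_z) ||
             is.null(grid$intracellular_low_z)) -1 else 1
  V / 2 + sgn * V * (z - grid$origin[3]) / Lz
}

#' Trajectory-averaged electrostatic potential map
#'
#' Smears and solves each requested frame and returns the arithmetic mean
#' of the per-frame potential grids on the common grid. Requires a
#' constant box across frames (within 1 percent), as for constant-volume
#' simulations.
#'
#' @param traj a \code{\link{trajectory}} with per-frame boxes (or
#'   \code{box} given).
#' @param charges per-atom charges (e).
#' @param frames frame indices to average (default all).
#' @param box length-3 box override if the trajectory has none.
#' @param beta,spacing,origin passed to \code{\link{smear_charges}}.
#' @return a \code{"potential_grid"} in e/Angstrom.
#' @export
average_potential <- function(traj, charges, frames = NULL, box = NULL,
                              beta = 0.25, spacing = 1.0,
                              origin = c(0, 0, 0)) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("need at least one frame")
  boxes <- if (!is.null(box)) matrix(box, length(frames), 3, byrow = TRUE)
    else traj$box[frames, , drop = FALSE]
  if (is.null(boxes)) stop("no box information available")
  ref <- boxes[1, ]
  if (any(abs(sweep(boxes, 2, ref) / rep(ref, each = nrow(boxes))) > 0.01))
    stop("box varies by more than 1% across frames")
  acc <- NULL
  for (i in frames) {
    dens <- smear_charges(frame_coords(traj, i), charges, box = ref,
                          beta = beta, spacing = spacing, origin = origin)
    phi <- solve_poisson(dens)
    acc <- if (is.null(acc)) phi$values else acc + phi$values
  }
  out <- scalar_grid(acc / length(frames), origin = origin,
                     spacing = spacing, periodic = TRUE,
                     units_label = "e/Angstrom")
  class(out) <- c("potential_grid", class(out))
  out$applied_voltage <- 0
  out
}

#' Interpolate grid values at arbitrary points
#'
#' Trilinear interpolation; exact at voxel centers and for fields linear
#' in the coordinates. Points outside the grid's sampled domain raise an
#' error (no extrapolation).
#'
#' @param grid a \code{\link{scalar_grid}} or \code{"potential_grid"}.
#' @param points m x 3 matrix of coordinates (Angstrom).
#' @param include_external add the external ramp (potential grids only;
#'   default \code{TRUE}).
#' @param units \code{"native"} (grid units) or \code{"mV"} (potential
#'   grids in e/Angstrom only).
#' @return numeric vector of interpolated values.
#' @export
potential_at <- function(grid, points, include_external = TRUE,
                         units = c("native", "mV")) {
  units <- match.arg(units)
  points <- matrix(points, ncol = 3)
  d <- dim(grid$values)
  u <- sweep(points, 2, grid$origin) / grid$spacing   # voxel coordinates
  if (any(u < -1e-9) || any(sweep(u, 2, d - 1) > 1e-9))
    stop("point outside grid; no extrapolation")
  u <- pmin(pmax(u, 0), rep(d - 1, each = nrow(u)))
  i0 <- pmin(floor(u), rep(d - 2, each = nrow(u))); fr <- u - i0
  v <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
      (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
      (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    v <- v + wgt * grid$values[cbind(i0[, 1] + cx + 1, i0[, 2] + cy + 1,
                                     i0[, 3] + cz + 1)]
  }
  if (inherits(grid, "potential_grid")) {
    v_volt <- v * vg_constants$e_per_ang_to_volt
    if (include_external)
      v_volt <- v_volt + external_ramp(grid, points[, 3])
    return(if (units == "mV") v_volt * 1000 else
             v_volt / vg_constants$e_per_ang_to_volt)
  }
  v
}

#' Slice a grid on a plane through three anchor points
#'
#' Builds an orthonormal raster in the plane defined by three
#' non-collinear anchors and trilinearly interpolates the grid onto it.
#'
#' @param grid a \code{\link{scalar_grid}} or \code{"potential_grid"}.
#' @param p1,p2,p3 length-3 anchor points; p1 is the raster origin, the
#'   u axis points along p2 - p1.
#' @param extent_u,extent_v raster extents in Angstrom (defaults: |p2-p1|
#'   and |component of p3-p1 orthogonal to u|).
#' @param du raster step (default the grid spacing).
#' @param include_external,units as in \code{\link{potential_at}}.
#' @return list with vectors \code{u}, \code{v}, matrix \code{values},
#'   and the raster \code{points}.
#' @export
plane_slice <- function(grid, p1, p2, p3, extent_u = NULL, extent_v = NULL,
                        du = NULL, include_external = TRUE,
                        units = c("native", "mV")) {
  units <- match.arg(units)
  e1 <- p2 - p1
  if (sqrt(sum(e1^2)) < 1e-9) stop("anchors p1 and p2 coincide")
  eu <- e1 / sqrt(sum(e1^2))
  w <- (p3 - p1) - sum((p3 - p1) * eu) * eu
  if (sqrt(sum(w^2)) < 1e-9) stop("anchor points are collinear")
  ev <- w / sqrt(sum(w^2))
  if (is.null(extent_u)) extent_u <- sqrt(sum(e1^2))
  if (is.null(extent_v)) extent_v <- sqrt(sum(w^2))
  if (is.null(du)) du <- grid$spacing
  us <- seq(0, extent_u, by = du)
  vs <- seq(0, extent_v, by = du)
  pts <- cbind(rep(us, times = length(vs))) %*% rbind(eu) +
    cbind(rep(vs, each = length(us))) %*% rbind(ev)
  pts <- sweep(pts, 2, p1, "+")
  vals <- potential_at(grid, pts, include_external = include_external,
                       units = units)
  list(u = us, v = vs,
       values = matrix(vals, nrow = length(us)), points = pts)
}

#' Export a potential grid as OpenDX in millivolts
#'
#' Writes the total potential (protein field plus any attached external
#' ramp, evaluated at the grid points) in millivolts.
#'
#' @param grid a \code{"potential_grid"} in e/Angstrom.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_potential_dx <- function(grid, path) {
  mv <- grid$values * vg_constants$e_per_ang_to_volt * 1000
  if (!is.null(grid$applied_voltage) && grid$applied_voltage != 0) {
    z <- grid$origin[3] + (seq_len(dim(grid$values)[3]) - 1) * grid$spacing
    ramp <- external_ramp(grid, z) * 1000
    mv <- sweep(mv, 3, ramp, "+")
  }
  out <- scalar_grid(mv, origin = grid$origin, spacing = grid$spacing,
                     periodic = grid$periodic, units_label = "mV")
  write_dx(out, path)
}
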