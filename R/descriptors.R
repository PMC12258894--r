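#' Resolve charged-group proxy atoms
#'
#' Maps charged residues to the single atom used as the location of the
#' charged group: the guanidinium CZ for Arg and the sidechain carboxyl
#' carbon for Asp (CG) and Glu (CD).
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param residue_id integer residue ids to resolve.
#' @param chain optional chain filter.
#' @return named integer vector of atom-table row indices (names are
#'   residue labels).
#' @export
charge_group_proxies <- function(atoms, residue_id, chain = NULL) {
  proxy_map <- c(ARG = "CZ", ASP = "CG", GLU = "CD", LYS = "NZ")
  idx <- vapply(residue_id, function(r) {
    rows <- which(atoms$residue_id == r &
                    (is.null(chain) | atoms$chain_id %in% chain))
    if (!length(rows)) stop("residue ", r, " not in atom table")
    rn <- atoms$residue_name[rows[1]]
    pa <- proxy_map[rn]
    if (is.na(pa))
      stop("no charged-group proxy defined for residue ", r, " (", rn, ")")
    hit <- rows[atoms$atom_name[rows] == pa]
    if (!length(hit))
      stop("proxy atom ", pa, " missing for residue ", r)
    hit[1]
  }, integer(1))
  names(idx) <- paste0(substr(atoms$residue_name[idx], 1, 1), residue_id)
  idx
}

#' z-displacement time series of charged groups
#'
#' For each proxy atom, the displacement along the membrane normal from
#' its position in a reference frame:
#' z(proxy, frame) - z(proxy, reference).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param proxy_idx atom indices (e.g. from
#'   \code{\link{charge_group_proxies}}).
#' @param reference_frame frame index the displacement is measured from.
#' @return n_frames x n_proxies numeric matrix (Angstrom).
#' @export
charge_z_displacement <- function(traj, proxy_idx, reference_frame = 1) {
  z <- traj$coords[, proxy_idx, 3, drop = FALSE]
  z <- matrix(z, nrow = n_frames(traj))
  out <- sweep(z, 2, z[reference_frame, ], "-")
  colnames(out) <- names(proxy_idx)
  out
}

#' Centered running average of a time series
#'
#' Thick-line smoothing for descriptor series: centered window, shrunk
#' symmetrically near the edges.
#'
#' @param x numeric vector.
#' @param window window width in frames (default 100).
#' @return numeric vector, same length.
#' @export
running_average <- function(x, window = 100) {
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1); hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Average a per-chain descriptor over subunits
#'
#' @param series n_frames x n_units matrix.
#' @param chains character vector assigning each column to a chain.
#' @return n_frames x n_chains matrix of per-chain means.
#' @export
average_by_chain <- function(series, chains) {
  u <- unique(chains)
  out <- vapply(u, function(ch)
    rowMeans(series[, chains == ch, drop = FALSE]), numeric(nrow(series)))
  colnames(out) <- u
  out
}

# principal axis of a coordinate set, oriented first -> last point
.principal_axis <- function(xyz) {
  if (nrow(xyz) < 4) stop("need >= 4 atoms to define a helix axis")
  cen <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(cen)
  if (sv$d[1] < 1e-9 || sv$d[1] - sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate coordinates: no dominant axis")
  v <- sv$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  v
}

#' Helix tilt angle time series
#'
#' Per frame, the angle between the helix principal axis (dominant
#' singular vector of the centered axis-atom coordinates, oriented from
#' the N- to the C-terminal atom) and the membrane normal (+z), folded
#' into [0, 90] degrees.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param axis_idx atom indices of the axis atoms (typically Ca), in
#'   N-to-C order.
#' @return numeric vector of angles (degrees), one per frame.
#' @export
helix_tilt <- function(traj, axis_idx) {
  vapply(seq_len(n_frames(traj)), function(i) {
    v <- .principal_axis(frame_coords(traj, i)[axis_idx, , drop = FALSE])
    ang <- acos(max(-1, min(1, v[3]))) * 180 / pi
    if (ang > 90) 180 - ang else ang
  }, numeric(1))
}

#' Helix center-of-mass displacement time series
#'
#' Displacement of the (optionally weighted) centroid of a selection from
#' its position in a reference frame, per axis.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param idx atom indices of the helix selection.
#' @param reference_frame reference frame index.
#' @param weights optional per-atom weights (e.g. masses).
#' @return n_frames x 3 matrix of (dx, dy, dz) in Angstrom.
#' @export
helix_com_displacement <- function(traj, idx, reference_frame = 1,
                                   weights = NULL) {
  if (!length(idx)) stop("empty selection")
  if (is.null(weights)) weights <- rep(1, length(idx))
  w <- weights / sum(weights)
  com <- t(vapply(seq_len(n_frames(traj)), function(i)
    colSums(frame_coords(traj, i)[idx, , drop = FALSE] * w), numeric(3)))
  out <- sweep(com, 2, com[reference_frame, ])
  colnames(out) <- c("dx", "dy", "dz")
  out
}

#' Boltzmann-inverted 2D free-energy surface
#'
#' Converts a 2D sample density (e.g. lateral center-of-mass positions)
#' into a free-energy scale, F = -RT ln P(x, y), with the minimum shifted
#' to zero.
#'
#' @param x,y sample coordinates.
#' @param nbins number of histogram bins per axis.
#' @param temperature temperature in kelvin (default 300).
#' @return list with bin centers \code{x}, \code{y} and matrix \code{F}
#'   (kcal/mol; \code{Inf} in empty bins).
#' @export
free_energy_surface <- function(x, y, nbins = 50, temperature = 300) {
  bx <- seq(min(x), max(x), length.out = nbins + 1)
  by <- seq(min(y), max(y), length.out = nbins + 1)
  h <- table(cut(x, bx, include.lowest = TRUE),
             cut(y, by, include.lowest = TRUE))
  p <- h / sum(h)
  f <- -vg_constants$R_kcal * temperature * log(as.matrix(p))
  f <- f - min(f[is.finite(f)])
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2, F = f)
}

#' RMSD time series after least-squares superposition
#'
#' Superposes each frame onto the reference using the fit selection
#' (default: the same atoms as the RMSD selection), then reports the RMSD
#' over the RMSD selection. Superposition uses the standard least-squares
#' rotation (via \pkg{bio3d}).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param ref_coords n_atoms x 3 reference coordinate matrix (full atom
#'   set, same indexing as the trajectory).
#' @param idx atom indices RMSD is computed over.
#' @param fit_idx atom indices used for superposition (default
#'   \code{idx}).
#' @param fit if \code{FALSE}, skip superposition.
#' @return numeric vector of RMSD (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, ref_coords, idx, fit_idx = idx, fit = TRUE) {
  if (!length(idx) || !length(fit_idx)) stop("empty selection")
  vapply(seq_len(n_frames(traj)), function(i) {
    mob <- frame_coords(traj, i)
    if (fit) {
      xyz_ind <- function(k) as.vector(rbind(3 * k - 2, 3 * k - 1, 3 * k))
      fitted <- bio3d::fit.xyz(
        fixed = as.numeric(t(ref_coords)),
        mobile = matrix(as.numeric(t(mob)), nrow = 1),
        fixed.inds = xyz_ind(fit_idx), mobile.inds = xyz_ind(fit_idx))
      mob <- matrix(fitted[1, ], ncol = 3, byrow = TRUE)
    }
    d <- mob[idx, , drop = FALSE] - ref_coords[idx, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

#' Define a pore region
#'
#' Axial slab plus radial cutoff defining "inside the pore". Each bound is
#' either a fixed z value or an atom selection whose per-frame centroid z
#' sets the bound (e.g. the center of mass of a residue ring).
#'
#' @param lower,upper fixed numeric z (Angstrom) or an integer vector of
#'   atom indices.
#' @param radial_cutoff maximal distance from the pore axis (default 8).
#' @param axis_idx atom indices whose per-frame (x, y) centroid defines
#'   the pore axis; \code{NULL} fixes the axis at (0, 0).
#' @return list of class \code{"pore_region"}.
#' @export
pore_region <- function(lower, upper, radial_cutoff = 8, axis_idx = NULL) {
  structure(list(lower = lower, upper = upper,
                 radial_cutoff = radial_cutoff, axis_idx = axis_idx),
            class = "pore_region")
}

.resolve_bound <- function(bound, xyz) {
  if (is.numeric(bound) && length(bound) == 1 && !is.integer(bound))
    return(bound)
  mean(xyz[as.integer(bound), 3])
}

#' Count waters inside the pore per frame
#'
#' A water (oxygen) is inside when its z lies in [lower, upper) and its
#' distance from the pore axis is at most the radial cutoff.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param region a \code{\link{pore_region}}.
#' @param water_idx atom indices of the water oxygens.
#' @return integer vector of counts, one per frame.
#' @export
pore_water_count <- function(traj, region, water_idx) {
  vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    lo <- .resolve_bound(region$lower, xyz)
    hi <- .resolve_bound(region$upper, xyz)
    if (lo >= hi)
      stop("inverted pore bounds in frame ", i,
           sprintf(" (lower %.2f >= upper %.2f)", lo, hi))
    ax <- if (is.null(region$axis_idx)) c(0, 0) else
      colMeans(xyz[region$axis_idx, 1:2, drop = FALSE])
    w <- xyz[water_idx, , drop = FALSE]
    inz <- w[, 3] >= lo & w[, 3] < hi
    r2 <- (w[, 1] - ax[1])^2 + (w[, 2] - ax[2])^2
    sum(inz & r2 <= region$radial_cutoff^2)
  }, integer(1))
}

#' Axial pore radius profile
#'
#' Simplified axial profiler: for each z slice, the pore radius is the
#' minimum over nearby atoms of (distance of the atom center from the
#' pore axis minus its vdW radius), clamped at zero. Slices with no atom
#' whose sphere reaches them report the configured maximum probe radius
#' and are flagged.
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param radii per-atom vdW radii (Angstrom).
#' @param axis_xy length-2 (x, y) of the pore axis.
#' @param z_range length-2 range of z to profile.
#' @param dz slice thickness (default 1).
#' @param max_probe radius reported for empty slices (default 15).
#' @return data.frame with columns \code{z}, \code{radius},
#'   \code{flagged}.
#' @export
pore_radius_profile <- function(coords, radii, axis_xy = c(0, 0),
                                z_range, dz = 1, max_probe = 15) {
  zs <- seq(z_range[1], z_range[2], by = dz)
  rad_xy <- sqrt((coords[, 1] - axis_xy[1])^2 +
                   (coords[, 2] - axis_xy[2])^2)
  out <- t(vapply(zs, function(z) {
    near <- abs(coords[, 3] - z) <= radii + dz / 2
    if (!any(near)) return(c(max_probe, 1))
    c(max(0, min(rad_xy[near] - radii[near])), 0)
  }, numeric(2)))
  data.frame(z = zs, radius = out[, 1], flagged = out[, 2] == 1)
}

#' Detect full ion permeation events
#'
#' State-machine over each ion's z(t): an event is recorded when an ion
#' that entered the slab through one boundary exits through the other
#' without first leaving back through the entry boundary. Direction
#' \code{"up"} means entry from below and exit above. Frames jumping
#' straight across the slab count as a crossing.
#'
#' @param z n_frames x n_ions matrix (or vector) of ion z coordinates.
#' @param slab_lower,slab_upper slab bounds (Angstrom).
#' @return data.frame with columns \code{ion}, \code{frame_entry},
#'   \code{frame_exit}, \code{direction}.
#' @export
detect_permeations <- function(z, slab_lower, slab_upper) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  stopifnot(slab_lower < slab_upper)
  recs <- list()
  for (ion in seq_len(ncol(z))) {
    zt <- z[, ion]
    region <- ifelse(zt < slab_lower, -1L, ifelse(zt >= slab_upper, 1L, 0L))
    entry_side <- 0L; entry_frame <- NA_integer_
    prev <- region[1]
    for (t in seq_along(region)[-1]) {
      cur <- region[t]
      if (cur == prev) next
      if (prev != 0L && cur == 0L) {          # entered the slab
        entry_side <- prev; entry_frame <- t
      } else if (prev == 0L && cur != 0L) {   # left the slab
        if (entry_side != 0L && cur == -entry_side) {
          recs[[length(recs) + 1L]] <- data.frame(
            ion = ion, frame_entry = entry_frame, frame_exit = t,
            direction = if (cur == 1L) "up" else "down",
            stringsAsFactors = FALSE)
        }
        entry_side <- 0L
      } else if (prev != 0L && cur == -prev) { # jumped straight across
        recs[[length(recs) + 1L]] <- data.frame(
          ion = ion, frame_entry = t, frame_exit = t,
          direction = if (cur == 1L) "up" else "down",
          stringsAsFactors = FALSE)
        entry_side <- 0L
      }
      prev <- cur
    }
  }
  if (!length(recs))
    return(data.frame(ion = integer(0), frame_entry = integer(0),
                      frame_exit = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Single-channel conductance from permeation counts
#'
#' g = N_net e / (V T) with N_net the net number of permeation events in
#' the field direction, e the elementary charge, V the membrane voltage
#' and T the observation time.
#'
#' @param n_up,n_down event counts (or pass a data.frame from
#'   \code{\link{detect_permeations}} as \code{n_up}).
#' @param voltage membrane voltage in volts (nonzero).
#' @param duration_s observation time in seconds.
#' @return conductance in siemens.
#' @export
conductance <- function(n_up, n_down = 0, voltage, duration_s) {
  if (is.data.frame(n_up)) {
    n_down <- sum(n_up$direction == "down")
    n_up <- sum(n_up$direction == "up")
  }
  if (voltage == 0) stop("conductance undefined at zero voltage")
  if (duration_s <= 0) stop("duration must be > 0")
  (n_up - n_down) * vg_constants$elementary_charge_C /
    (voltage * duration_s)
}

#' Block-averaged mean and standard error
#'
#' Splits the series into contiguous equal blocks (discarding the
#' remainder), and reports the mean of block means and their standard
#' error, sd(block means) / sqrt(n_blocks). The standard way to estimate
#' errors on correlated simulation time series.
#'
#' @param series numeric vector.
#' @param n_blocks number of blocks (>= 2).
#' @return list with \code{mean} and \code{se}.
#' @export
block_average <- function(series, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 blocks")
  n <- length(series)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  per <- n %/% n_blocks
  use <- series[seq_len(per * n_blocks)]
  bm <- colMeans(matrix(use, nrow = per))
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks))
}
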