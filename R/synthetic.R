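#' Build an ideal alpha-helix bundle
#'
#' Generates Ca/CB (and charged-group proxy) atoms for one or more ideal
#' alpha-helices (rise 1.5 A per residue, 100 degrees twist per residue,
#' backbone radius 2.3 A), each tilted away from the z axis by a prescribed
#' angle. Used as a fixture with known ground truth for tilt, displacement
#' and selection machinery.
#'
#' Arg residues get an additional CZ proxy atom, Asp a CG and Glu a CD,
#' displaced radially so charged-group descriptors can be exercised.
#'
#' @param n_helices number of helices.
#' @param tilt_deg numeric vector (recycled) of tilt angles in degrees,
#'   each in [0, 90); tilt is applied as a rotation about the x axis.
#' @param n_residues residues per helix (>= 4; recycled).
#' @param residue_names residue names per helix position (recycled;
#'   default \code{"ALA"}).
#' @param start_residue first residue id of each helix (recycled;
#'   default spaces helices 100 ids apart).
#' @param spacing_xy lateral spacing between helix centers in Angstrom.
#' @param seed integer seed (only used for reproducible atom ids; geometry
#'   is deterministic).
#' @return a \code{structure_frame} (see \code{\link{load_structure}}).
#' @export
make_helix_bundle <- function(n_helices = 1, tilt_deg = 0, n_residues = 27,
                              residue_names = "ALA", start_residue = NULL,
                              spacing_xy = 14, seed = 1) {
  tilt_deg <- rep_len(tilt_deg, n_helices)
  n_residues <- rep_len(n_residues, n_helices)
  if (any(tilt_deg < 0 | tilt_deg >= 90))
    stop("tilt must be in [0, 90)")
  if (is.null(start_residue))
    start_residue <- 1 + (seq_len(n_helices) - 1) * 100L
  start_residue <- rep_len(start_residue, n_helices)
  rows <- list(); coords <- list(); aid <- 0L
  ncol_grid <- ceiling(sqrt(n_helices))
  for (h in seq_len(n_helices)) {
    nres <- n_residues[h]
    if (nres < 4) stop("need >= 4 residues per helix")
    resn <- rep_len(residue_names, nres)
    i <- seq_len(nres) - 1
    phi <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * i)
    ca <- sweep(ca, 2, c(0, 0, mean(ca[, 3])))  # center along axis
    th <- tilt_deg[h] * pi / 180
    rot <- matrix(c(1, 0, 0,
                    0, cos(th), -sin(th),
                    0, sin(th), cos(th)), 3, 3, byrow = TRUE)
    place <- function(xyz) {
      xyz <- xyz %*% t(rot)
      off <- c(((h - 1) %% ncol_grid) * spacing_xy,
               ((h - 1) %/% ncol_grid) * spacing_xy, 0)
      sweep(xyz, 2, off, "+")
    }
    cb <- cbind(3.8 * cos(phi), 3.8 * sin(phi), 1.5 * i - mean(1.5 * i))
    proxy_name <- c(ARG = "CZ", ASP = "CG", GLU = "CD")[resn]
    proxy <- cbind(5.5 * cos(phi), 5.5 * sin(phi),
                   1.5 * i - mean(1.5 * i))
    for (r in seq_len(nres)) {
      nm <- c("CA", "CB"); xyz <- rbind(ca[r, ], cb[r, ])
      if (!is.na(proxy_name[r])) {
        nm <- c(nm, proxy_name[r]); xyz <- rbind(xyz, proxy[r, ])
      }
      for (k in seq_along(nm)) {
        aid <- aid + 1L
        rows[[aid]] <- data.frame(
          atom_id = aid, atom_name = nm[k],
          residue_id = start_residue[h] + r - 1L,
          residue_name = resn[r], chain_id = LETTERS[h],
          element = "C", stringsAsFactors = FALSE)
      }
      coords[[length(coords) + 1L]] <- place(xyz)
    }
  }
  tab <- do.call(rbind, rows)
  atoms <- atom_table(tab$atom_id, tab$atom_name, tab$residue_id,
                      tab$residue_name, tab$chain_id, tab$element)
  atoms <- assign_charges(atoms)
  structure(list(atoms = atoms, coords = do.call(rbind, coords)),
            class = "structure_frame")
}

#' Sample a harmonic (multivariate normal) ensemble
#'
#' Draws i.i.d. frames of node positions from a multivariate normal around
#' planted mean positions. The same node-by-node covariance (Angstrom^2) is
#' applied independently to each Cartesian axis unless per-axis covariances
#' are given, so the 3-D displacement-dot-product correlation between two
#' nodes equals the planted entry. Frames are i.i.d. by design: all the
#' stationary statistics downstream analyses use (correlations, contact
#' occupancies, fluctuation densities) are functions of the single-frame
#' distribution only.
#'
#' @param mean_positions n x 3 matrix of node mean positions (Angstrom).
#' @param covariance n x n symmetric positive-semidefinite matrix of
#'   per-axis displacement covariances (Angstrom^2), or a list of three
#'   such matrices (one per axis).
#' @param n_frames number of frames to draw.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param timestep_ns nominal frame spacing.
#' @return a \code{\link{trajectory}}.
#' @export
sample_harmonic_ensemble <- function(mean_positions, covariance, n_frames,
                                     seed = 1, timestep_ns = 1) {
  mp <- as.matrix(mean_positions)
  n <- nrow(mp)
  covs <- if (is.list(covariance)) covariance else
    list(covariance, covariance, covariance)
  roots <- lapply(covs, function(S) {
    S <- as.matrix(S)
    if (nrow(S) != n || any(abs(S - t(S)) > 1e-8))
      stop("covariance must be symmetric n x n")
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop("covariance is not positive semidefinite")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  set.seed(seed)
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
    coords[, , ax] <- sweep(z %*% roots[[ax]], 2, mp[, ax], "+")
  }
  trajectory(coords, timestep_ns = timestep_ns)
}

#' Build a synthetic thermodynamic-integration dataset
#'
#' Evaluates a polynomial mean-force profile on a lambda grid, optionally
#' adds Gaussian noise, and attaches the closed-form integral as ground
#' truth. Profile kinds: \code{constant} (c0), \code{linear} (c0 + c1
#' lambda), \code{quadratic} (c0 + c1 lambda + c2 lambda^2), or
#' \code{tabulated} (coefficients are the window values themselves).
#'
#' @param profile_kind one of \code{"constant"}, \code{"linear"},
#'   \code{"quadratic"}, \code{"tabulated"}.
#' @param coefficients polynomial coefficients in increasing order (or the
#'   tabulated window values).
#' @param lambdas increasing grid in [0, 1] including both endpoints.
#' @param noise_sd per-window Gaussian noise, kcal/mol (default 0 so
#'   integrals are exact in tests).
#' @param seed integer seed for the noise.
#' @param residue_id,state,voltage,q metadata carried into the dataset.
#' @param n_blocks if > 0, per-window block series of \code{n_blocks}
#'   values with the same noise level are attached for error propagation.
#' @return a \code{\link{ti_dataset}} with attribute \code{ground_truth}
#'   (the closed-form integral of the noise-free profile).
#' @export
make_ti_dataset <- function(profile_kind = c("constant", "linear",
                                             "quadratic", "tabulated"),
                            coefficients, lambdas = seq(0, 1, by = 0.1),
                            noise_sd = 0, seed = 1, residue_id = 0L,
                            state = "closed", voltage = 0, q = 1,
                            n_blocks = 0) {
  profile_kind <- match.arg(profile_kind)
  maxdeg <- c(constant = 1, linear = 2, quadratic = 3)[profile_kind]
  if (profile_kind == "tabulated") {
    if (length(coefficients) != length(lambdas))
      stop("tabulated profile needs one value per lambda")
    mf0 <- coefficients
    truth <- pracma::trapz(lambdas, coefficients)
  } else {
    if (length(coefficients) > maxdeg)
      stop("too many coefficients for kind '", profile_kind, "'")
    co <- c(coefficients, rep(0, maxdeg - length(coefficients)))
    mf0 <- drop(outer(lambdas, seq_along(co) - 1, "^") %*% co)
    truth <- sum(co / seq_along(co))
  }
  set.seed(seed)
  mf <- mf0 + stats::rnorm(length(mf0), sd = noise_sd)
  blocks <- NULL
  if (n_blocks > 0) {
    blocks <- lapply(mf0, function(m)
      m + stats::rnorm(n_blocks, sd = noise_sd * sqrt(n_blocks)))
    mf <- vapply(blocks, mean, numeric(1))
  }
  out <- ti_dataset(lambdas, mf, residue_id = residue_id, state = state,
                    voltage = voltage, q = q, units = "kcal/mol",
                    blocks = blocks)
  attr(out, "ground_truth") <- truth
  out
}

#' Build a linear-slab charge-coupling system
#'
#' Idealized validation system for the gating-charge bookkeeping: each
#' residue charge sits at a fractional membrane depth d in [0, 1] inside a
#' linear transmembrane field, so the charging free energy is exactly
#' \eqn{\Delta G_s(V, q) = q V d} (eV) and the true coupling fraction
#' equals the depth. For each residue, state and voltage a TI dataset with
#' a constant mean-force profile is generated (optionally noisy), so the
#' full pipeline (integration, coupling fractions, gating-charge sum) can
#' be checked against planted values.
#'
#' @param depths_closed,depths_open fractional depths in [0, 1], one per
#'   residue.
#' @param charges residue charges in e.
#' @param V1,V2 the two probe voltages (volts); defaults 0 and +0.75.
#' @param residue_ids integer ids (default 1..n).
#' @param lambdas TI lambda grid.
#' @param noise_sd per-window mean-force noise, kcal/mol.
#' @param n_blocks per-window block count when noisy (for error bars).
#' @param seed integer seed.
#' @return a list of class \code{"slab_system"}: \code{datasets} (list of
#'   \code{ti_dataset}), and \code{truth} with planted depths, per-residue
#'   \code{dq} and total \code{dQ}.
#' @export
make_slab_coupling_system <- function(depths_closed, depths_open, charges,
                                      V1 = 0, V2 = 0.75,
                                      residue_ids = NULL,
                                      lambdas = seq(0, 1, by = 0.1),
                                      noise_sd = 0, n_blocks = 0,
                                      seed = 1) {
  nres <- length(charges)
  stopifnot(length(depths_closed) == nres, length(depths_open) == nres,
            all(depths_closed >= 0 & depths_closed <= 1),
            all(depths_open >= 0 & depths_open <= 1))
  if (is.null(residue_ids)) residue_ids <- seq_len(nres)
  datasets <- list(); s <- 0L
  for (r in seq_len(nres)) {
    for (st in c("closed", "open")) {
      d <- if (st == "closed") depths_closed[r] else depths_open[r]
      for (V in c(V1, V2)) {
        s <- s + 1L
        # constant mean force in kcal/mol whose integral is q*V*d eV
        mf_kcal <- charges[r] * V * d / vg_constants$kcalmol_to_ev
        datasets[[s]] <- make_ti_dataset(
          "constant", mf_kcal, lambdas = lambdas, noise_sd = noise_sd,
          n_blocks = n_blocks, seed = seed * 10000L + s,
          residue_id = residue_ids[r], state = st, voltage = V,
          q = charges[r])
      }
    }
  }
  dq <- charges * (depths_closed - depths_open)
  structure(list(datasets = datasets,
                 truth = list(residue_ids = residue_ids, charges = charges,
                              depths_closed = depths_closed,
                              depths_open = depths_open,
                              V1 = V1, V2 = V2, dq = dq, dQ = sum(dq))),
            class = "slab_system")
}

#' Generate ion z(t) tracks with a planted permeation count
#'
#' Builds one track per planted permeation event (smooth full crossing of
#' the slab with wide margins) plus decoy tracks that enter the slab from
#' one side and retreat without crossing. Gaussian jitter (truncated at 3
#' sigma so it can never bridge the margins) is superimposed, so partial
#' re-entries occur but the full-crossing count is exactly as planted.
#'
#' @param n_events_up,n_events_down planted full crossings in each
#'   direction.
#' @param duration_ns track duration.
#' @param slab length-2 numeric, lower and upper slab bounds (Angstrom).
#' @param n_decoys tracks that enter but never cross.
#' @param n_frames frames per track.
#' @param jitter_sd jitter amplitude in Angstrom.
#' @param seed integer seed.
#' @return list of class \code{"ion_tracks"}: \code{z} (n_frames x n_ions
#'   matrix), \code{time_ns}, \code{slab}, and \code{truth} counts.
#' @export
make_ion_tracks <- function(n_events_up = 1, n_events_down = 0,
                            duration_ns = 100, slab = c(-5, 5),
                            n_decoys = 2, n_frames = 400,
                            jitter_sd = 0.5, seed = 1) {
  stopifnot(duration_ns > 0, slab[1] < slab[2])
  set.seed(seed)
  margin <- 8
  lo <- slab[1] - margin; hi <- slab[2] + margin
  tt <- seq(0, 1, length.out = n_frames)
  mk_cross <- function(up) {
    c0 <- stats::runif(1, 0.3, 0.7)  # crossing midpoint in scaled time
    base <- lo + (hi - lo) / (1 + exp(-20 * (tt - c0)))
    if (!up) base <- rev(base)
    base
  }
  mk_decoy <- function() {
    from_below <- stats::runif(1) < 0.5
    peak <- mean(slab)  # reaches mid-slab, never the far boundary
    base0 <- if (from_below) lo else hi
    c0 <- stats::runif(1, 0.3, 0.7)
    base0 + (peak - base0) * exp(-((tt - c0) / 0.1)^2)
  }
  tracks <- c(replicate(n_events_up, mk_cross(TRUE), simplify = FALSE),
              replicate(n_events_down, mk_cross(FALSE), simplify = FALSE),
              replicate(n_decoys, mk_decoy(), simplify = FALSE))
  z <- vapply(tracks, function(b) {
    j <- stats::rnorm(n_frames, sd = jitter_sd)
    b + pmax(pmin(j, 3 * jitter_sd), -3 * jitter_sd)
  }, numeric(n_frames))
  structure(list(z = z, time_ns = tt * duration_ns, slab = slab,
                 truth = list(n_up = n_events_up, n_down = n_events_down)),
            class = "ion_tracks")
}
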