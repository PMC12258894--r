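#' Construct a trajectory
#'
#' A trajectory holds per-frame Cartesian coordinates (Angstrom) for a fixed
#' set of atoms plus the per-frame periodic box edge lengths. Frames keep
#' file order. Boxes are orthorhombic; the z edge is the membrane normal
#' and enters the external-field overlay as E = V / Lz.
#'
#' @param coords numeric array of dimension (n_frames, n_atoms, 3), or a
#'   single n_atoms x 3 matrix for a one-frame trajectory.
#' @param box numeric length-3 vector (Lx, Ly, Lz) in Angstrom, or an
#'   n_frames x 3 matrix for per-frame boxes. May be \code{NULL} for
#'   non-periodic fixtures.
#' @param timestep_ns time between stored frames in nanoseconds.
#' @return an object of class \code{"trajectory"}.
#' @export
trajectory <- function(coords, box = NULL, timestep_ns = 1) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, nrow(coords), ncol(coords)))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3,
                                         byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
    if (any(box <= 0)) stop("box edges must be > 0")
  }
  structure(list(coords = coords, box = box, timestep_ns = timestep_ns),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ns\n",
              n_frames(x), dim(x$coords)[2], x$timestep_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{\link{trajectory}}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a \code{\link{trajectory}}.
#' @param i frame index (1-based).
#' @return an n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

# ---- DCD binary I/O ---------------------------------------------------------
# CHARMM-dialect DCD. bio3d provides the reader; the writer below emits the
# minimal compatible layout (CORD header, title, natom, optional unit-cell
# record per frame, X/Y/Z float records with Fortran record markers).

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer compatible with common readers.
#' When the trajectory carries a box, a unit-cell record (orthorhombic)
#' is written per frame.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  has_cell <- !is.null(traj$box)
  rec <- function(writer) {
    # capture payload to compute the Fortran record marker
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl[1:9], c2, size = 4)
    writeBin(as.numeric(traj$timestep_ns), c2, size = 4)  # DELTA as float32
    writeBin(icntrl[11:20], c2, size = 4)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(formatC("written by voltgate", width = 80, flag = "-"),
              c2, nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(na), c2, size = 4))
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    if (has_cell) {
      b <- traj$box[i, ]
      # XTL convention: a, cos(gamma), b, cos(beta), cos(alpha), c
      rec(function(c2) writeBin(c(b[1], 0, b[2], 0, 0, b[3]), c2, size = 8))
    }
    for (k in 1:3)
      rec(function(c2) writeBin(as.numeric(xyz[, k]), c2, size = 4))
  }
  invisible(path)
}

# read NSET and the cell flag from a DCD header (for truncation checks)
.dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  m1 <- readBin(con, "integer", 1, size = 4)
  if (!identical(m1, 84L)) stop("not a DCD file: ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a DCD file: ", path)
  icntrl_a <- readBin(con, "integer", 9, size = 4)
  readBin(con, "numeric", 1, size = 4)
  icntrl_b <- readBin(con, "integer", 10, size = 4)
  list(nset = icntrl_a[1], cell = icntrl_b[1] != 0)
}

#' Load a trajectory from a DCD file
#'
#' Reads frames with \code{bio3d::read.dcd}, validates the atom count
#' against the supplied atom table, and refuses silently short reads: if
#' the file holds fewer complete frames than its header declares (a
#' truncated download or interrupted write), an error is raised.
#'
#' @param path path to a DCD file.
#' @param atoms an \code{\link{atom_table}} the frames must match.
#' @param timestep_ns time between frames in nanoseconds.
#' @return a \code{\link{trajectory}}.
#' @export
load_trajectory <- function(path, atoms, timestep_ns = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- .dcd_header(path)
  xyz <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, verbose = FALSE)),
    error = function(e) {
      # the reader leaks its connection when a frame record is cut short
      for (ci in getAllConnections()) {
        if (ci > 2 &&
            summary(getConnection(ci))$description == path)
          close(getConnection(ci))
      }
      stop("unreadable DCD '", path, "': ", conditionMessage(e))
    })
  na <- ncol(xyz) / 3
  if (na != nrow(atoms))
    stop(sprintf("atom-count mismatch: DCD has %d atoms, atom table has %d",
                 na, nrow(atoms)))
  if (nrow(xyz) < hdr$nset)
    stop(sprintf(
      "truncated DCD '%s': header declares %d frames, %d complete frames read",
      path, hdr$nset, nrow(xyz)))
  box <- NULL
  if (hdr$cell) {
    cell <- suppressWarnings(bio3d::read.dcd(path, cell = TRUE,
                                             verbose = FALSE))
    box <- cell[, 1:3, drop = FALSE]
  }
  coords <- array(NA_real_, dim = c(nrow(xyz), na, 3))
  coords[, , 1] <- xyz[, seq(1, ncol(xyz), by = 3)]
  coords[, , 2] <- xyz[, seq(2, ncol(xyz), by = 3)]
  coords[, , 3] <- xyz[, seq(3, ncol(xyz), by = 3)]
  trajectory(coords, box = box, timestep_ns = timestep_ns)
}
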