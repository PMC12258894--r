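#' Construct a 3D scalar grid
#'
#' Regular orthorhombic grid of scalar values (charge density, potential).
#' Grid points are at \code{origin + (i-1, j-1, k-1) * spacing}. Values are
#' stored as a 3D array indexed \code{[ix, iy, iz]}.
#'
#' @param values 3D numeric array.
#' @param origin length-3 numeric, Angstrom.
#' @param spacing scalar grid spacing in Angstrom (uniform; default 1.0).
#' @param periodic logical, whether the grid tiles space periodically.
#' @param units_label free-text unit tag carried through I/O.
#' @return an object of class \code{"scalar_grid"}.
#' @export
scalar_grid <- function(values, origin = c(0, 0, 0), spacing = 1.0,
                        periodic = TRUE, units_label = "") {
  stopifnot(length(dim(values)) == 3, length(origin) == 3)
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), periodic = periodic,
                 units_label = units_label),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<scalar_grid> %d x %d x %d, spacing %g A, origin (%g, %g, %g) %s\n",
    d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3],
    if (nzchar(x$units_label)) paste0("[", x$units_label, "]") else ""))
  invisible(x)
}

#' Box edge lengths spanned by a periodic grid
#' @param grid a \code{\link{scalar_grid}}.
#' @return length-3 numeric (Lx, Ly, Lz) in Angstrom.
#' @export
grid_box <- function(grid) dim(grid$values) * grid$spacing

#' Write a scalar grid in OpenDX format
#'
#' Emits the OpenDX dialect used by common molecular visualization grid
#' tools: \code{gridpositions} / \code{gridconnections} / rank-0 data
#' array, values three per line with the z index varying fastest.
#'
#' @param grid a \code{\link{scalar_grid}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$values)
  sp <- grid$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar grid%s",
            if (nzchar(grid$units_label))
              paste0(" (", grid$units_label, ")") else ""),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", sp),
    sprintf("delta 0.000000 %.6f 0.000000", sp),
    sprintf("delta 0.000000 0.000000 %.6f", sp),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(d))), con)
  # z-fastest ordering: loop x outer, y middle, z inner
  v <- aperm(grid$values, c(3, 2, 1))  # now [z, y, x]; flattening x slowest
  v <- as.vector(v)
  n <- length(v)
  full <- n %/% 3L * 3L
  if (full > 0) {
    m <- matrix(v[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10e %.10e %.10e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n > full)
    writeLines(paste(sprintf("%.10e", v[(full + 1L):n]), collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Counterpart of \code{\link{write_dx}}; accepts the same dialect
#' (uniform axis-aligned deltas, rank-0 double data, z-fastest ordering).
#'
#' @param path path to an OpenDX file.
#' @param periodic logical flag to set on the returned grid.
#' @return a \code{\link{scalar_grid}}.
#' @export
read_dx <- function(path, periodic = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) != 1) stop("not an OpenDX grid file: ", path)
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])),
                                "\\s+")[[1]])
  oline <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", oline[1])),
                                "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl, function(s)
    as.numeric(strsplit(trimws(sub("^delta", "", s)), "\\s+")[[1]]),
    numeric(3)))
  diag3 <- deltas[cbind(1:3, 1:3)]
  if (any(abs(deltas - diag(diag3)) > 1e-9) ||
      abs(diag3[1] - diag3[2]) > 1e-9 || abs(diag3[1] - diag3[3]) > 1e-9)
    stop("only uniform axis-aligned grid spacing is supported")
  istart <- grep("data follows", lines)
  if (length(istart) != 1) stop("not an OpenDX grid file: ", path)
  iend <- grep("^attribute|^object .* class field", lines)
  iend <- iend[iend > istart]
  iend <- if (length(iend)) min(iend) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1L):iend]),
                                     "\\s+")))
  if (length(vals) != prod(counts))
    stop(sprintf("OpenDX data length %d does not match counts %s",
                 length(vals), paste(counts, collapse = "x")))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  scalar_grid(arr, origin = origin, spacing = diag3[1], periodic = periodic)
}
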