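#' Construct an atom table
#'
#' The atom table is the package's central atom-metadata container: one row
#' per atom with identity, residue membership, partial charge (e) and van der
#' Waals radius (Angstrom). It is a plain \code{data.frame} subclass so all
#' the usual indexing applies.
#'
#' @param atom_id integer vector, unique atom serial numbers.
#' @param atom_name character, PDB-style atom names (e.g. \code{"CA"}).
#' @param residue_id integer residue numbers (1-based, as in the source PDB;
#'   never renumbered).
#' @param residue_name character three-letter residue names.
#' @param chain_id character chain identifiers.
#' @param element character element symbols.
#' @param charge numeric partial charges in units of e (default 0).
#' @param radius numeric van der Waals radii in Angstrom (default 1.7).
#' @return an object of class \code{c("atom_table","data.frame")}.
#' @export
atom_table <- function(atom_id, atom_name, residue_id, residue_name,
                       chain_id = "A", element = NA_character_,
                       charge = 0, radius = 1.7) {
  n <- length(atom_id)
  if (anyDuplicated(atom_id))
    stop("atom_id values must be unique")
  tab <- data.frame(
    atom_id = as.integer(atom_id),
    atom_name = as.character(atom_name),
    residue_id = as.integer(residue_id),
    residue_name = as.character(rep_len(residue_name, n)),
    chain_id = as.character(rep_len(chain_id, n)),
    element = as.character(rep_len(element, n)),
    charge = as.numeric(rep_len(charge, n)),
    radius = as.numeric(rep_len(radius, n)),
    stringsAsFactors = FALSE
  )
  if (any(tab$radius < 0)) stop("vdw radius must be >= 0")
  class(tab) <- c("atom_table", "data.frame")
  tab
}

#' @export
print.atom_table <- function(x, ...) {
  cat(sprintf("<atom_table> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain_id, x$residue_id))),
              paste(unique(x$chain_id), collapse = ",")))
  NextMethod()
}

#' Default charge/radius assignment table
#'
#' Loads the sidecar CSV mapping (residue_name, atom_name) to a partial
#' charge and vdW radius. The shipped defaults are a deliberately simple
#' formal-charge scheme for standard amino acids (Arg guanidinium carbon
#' +1 e, Asp/Glu carboxyl carbon -1 e, Lys amine nitrogen +1 e, backbone
#' and apolar atoms 0) with element-typical radii; they are not force-field
#' parameters and are intended for descriptor and map calculations where
#' a user-supplied table is not given.
#'
#' @param path optional path to a CSV with columns
#'   \code{residue_name, atom_name, charge, radius}.
#' @return a data.frame with those four columns.
#' @export
default_charge_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "amino_charge_radius.csv",
                        package = "voltgate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge", "radius")
  if (!all(need %in% names(tab)))
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  tab
}

# element-based fallback radii (Angstrom)
.element_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                    P = 1.80, K = 2.75, CL = 1.75, NA. = 2.27)

#' Assign charges and radii to an atom table
#'
#' Populates the \code{charge} and \code{radius} columns by
#' (residue_name, atom_name) lookup in an assignment table; atoms without a
#' match fall back to charge 0 and an element-typical radius.
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param table assignment data.frame as from
#'   \code{\link{default_charge_table}}.
#' @return the atom table with charges/radii filled in.
#' @export
assign_charges <- function(atoms, table = default_charge_table()) {
  key <- paste(atoms$residue_name, atoms$atom_name, sep = "|")
  tkey <- paste(table$residue_name, table$atom_name, sep = "|")
  idx <- match(key, tkey)
  hit <- !is.na(idx)
  atoms$charge[hit] <- table$charge[idx[hit]]
  atoms$radius[hit] <- table$radius[idx[hit]]
  if (any(!hit)) {
    el <- toupper(atoms$element[!hit])
    r <- .element_radii[el]
    r[is.na(r)] <- 1.7
    atoms$charge[!hit] <- 0
    atoms$radius[!hit] <- unname(r)
  }
  atoms
}

#' Read a PDB structure
#'
#' Parses a PDB file (via \pkg{bio3d}) into an atom table plus a single
#' coordinate frame. Charges and radii are populated from the supplied
#' assignment table (see \code{\link{assign_charges}}).
#'
#' @param path path to a PDB file.
#' @param charge_table optional assignment table; \code{NULL} uses the
#'   shipped defaults.
#' @return a list of class \code{"structure_frame"} with elements
#'   \code{atoms} (atom_table) and \code{coords} (n x 3 matrix, Angstrom).
#' @export
load_structure <- function(path, charge_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  a <- pdb$atom
  atoms <- atom_table(
    atom_id = a$eleno, atom_name = a$elety, residue_id = a$resno,
    residue_name = a$resid, chain_id = ifelse(is.na(a$chain), "A", a$chain),
    element = a$elesy
  )
  if (is.null(charge_table)) charge_table <- default_charge_table()
  atoms <- assign_charges(atoms, charge_table)
  coords <- cbind(a$x, a$y, a$z)
  colnames(coords) <- c("x", "y", "z")
  structure(list(atoms = atoms, coords = coords), class = "structure_frame")
}

#' Write a structure frame as PDB
#'
#' @param struct a \code{structure_frame} (or list with \code{atoms},
#'   \code{coords}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(struct, path) {
  at <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(struct$coords)),
                   resno = at$residue_id, resid = at$residue_name,
                   eleno = at$atom_id, elety = at$atom_name,
                   chain = at$chain_id, elesy = at$element)
  invisible(path)
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms\n", nrow(x$atoms)))
  invisible(x)
}
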