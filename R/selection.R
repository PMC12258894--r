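#' Select atoms from an atom table
#'
#' Resolves a selection against an atom table and returns sorted unique row
#' indices. Selections are either a compact expression string of
#' space-separated clauses joined by \code{"and"}, e.g.
#' \code{"resid 109:135 and name CA"}, \code{"chain A and resname ARG"},
#' or the equivalent named arguments. Supported keys: \code{resid}
#' (values and \code{a:b} ranges), \code{name}, \code{resname},
#' \code{chain}, \code{element}. Resolution is a pure function of the
#' table and the spec: the same inputs always give the same indices.
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param expr selection expression string, or \code{NULL} to use the
#'   named arguments.
#' @param resid integer vector of residue ids.
#' @param name character vector of atom names.
#' @param resname character vector of residue names.
#' @param chain character vector of chain ids.
#' @param element character vector of element symbols.
#' @param strict if \code{TRUE}, an atom/residue name that matches nothing
#'   in the table raises an error rather than silently selecting nothing.
#' @return sorted unique integer row indices (possibly empty).
#' @export
select_atoms <- function(atoms, expr = NULL, resid = NULL, name = NULL,
                         resname = NULL, chain = NULL, element = NULL,
                         strict = FALSE) {
  if (!is.null(expr)) {
    parsed <- parse_selection(expr)
    resid <- parsed$resid; name <- parsed$name; resname <- parsed$resname
    chain <- parsed$chain; element <- parsed$element
  }
  keep <- rep(TRUE, nrow(atoms))
  check <- function(vals, col, what) {
    if (strict && length(vals) && !any(vals %in% col))
      stop("selection ", what, " '", paste(vals, collapse = ","),
           "' matches no atom")
    col %in% vals
  }
  if (!is.null(resid))   keep <- keep & (atoms$residue_id %in% resid)
  if (!is.null(name))    keep <- keep & check(name, atoms$atom_name, "name")
  if (!is.null(resname)) keep <- keep & check(resname, atoms$residue_name,
                                              "resname")
  if (!is.null(chain))   keep <- keep & (atoms$chain_id %in% chain)
  if (!is.null(element)) keep <- keep & (toupper(atoms$element) %in%
                                           toupper(element))
  sort(unique(which(keep)))
}

# parse "resid 1:10 22 and name CA CB and chain A" into component vectors
parse_selection <- function(expr) {
  out <- list(resid = NULL, name = NULL, resname = NULL, chain = NULL,
              element = NULL)
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(toks) < 2)
      stop("malformed selection clause: '", cl, "'")
    key <- tolower(toks[1])
    vals <- toks[-1]
    if (key == "resid") {
      ids <- integer(0)
      for (v in vals) {
        if (grepl(":", v, fixed = TRUE)) {
          ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else ids <- c(ids, as.integer(v))
      }
      out$resid <- ids
    } else if (key %in% c("name", "resname", "chain", "element")) {
      out[[key]] <- vals
    } else stop("unknown selection key: '", key, "'")
  }
  out
}
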