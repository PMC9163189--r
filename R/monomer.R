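#' Rigid monomer
#'
#' A rigid molecule in its body frame: element symbols, per-atom types
#' (defaulting to the element symbol), Cartesian coordinates in Angstrom,
#' partial charges in elementary-charge units and atomic masses in amu.
#' Coordinates are recentred so the centre of mass sits at the origin.
#'
#' @param elements character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param charges per-atom partial charges (e); default zero.
#' @param types per-atom type labels; default the element symbols.  Distinct
#'   labels let symmetry-distinct atoms of one element carry their own pair
#'   parameters.
#' @param masses per-atom masses (amu); default standard atomic masses.
#' @param name optional identifier used in I/O and reports.
#' @return object of class `cspff_monomer`.
#' @export
monomer <- function(elements, xyz, charges = NULL, types = NULL,
                    masses = NULL, name = "monomer") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(elements)
  stopifnot(n >= 1, nrow(xyz) == n, ncol(xyz) == 3)
  if (is.null(types)) types <- elements
  if (is.null(charges)) charges <- rep(0, n)
  if (is.null(masses)) masses <- element_mass(elements)
  stopifnot(length(types) == n, length(charges) == n, length(masses) == n,
            all(masses > 0))
  if (n > 1) {
    d <- cross_distances(xyz, xyz)
    if (min(d[upper.tri(d)]) <= 0.5)
      stop("intramolecular distance <= 0.5 Angstrom; not a valid rigid monomer")
  }
  com <- colSums(xyz * masses) / sum(masses)
  xyz <- sweep(xyz, 2, com)
  dimnames(xyz) <- NULL
  structure(
    list(name = name, elements = as.character(elements),
         types = as.character(types), xyz = xyz,
         charges = as.numeric(charges), masses = as.numeric(masses)),
    class = "cspff_monomer"
  )
}

#' @export
print.cspff_monomer <- function(x, ...) {
  cat(sprintf("<rigid monomer '%s': %d atoms (%s), mass %.3f amu, net charge %+.3f e>\n",
              x$name, length(x$elements),
              paste(x$elements, collapse = ""), sum(x$masses), sum(x$charges)))
  invisible(x)
}

n_atoms <- function(m) length(m$elements)
molecular_mass <- function(m) sum(m$masses)

#' Read a monomer from an extended XYZ file
#'
#' Standard XYZ layout (count line, comment line, then `element x y z`
#' rows) with two optional trailing per-atom columns: partial charge (e)
#' and atom-type label.  The comment line may carry `name=<id>`.
#'
#' @param path file path.
#' @return a [monomer()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("bad XYZ atom count in ", path)
  comment <- lines[2]
  name <- sub("^.*name=([^ ]+).*$", "\\1", comment)
  if (identical(name, comment)) name <- sub("\\.xyz$", "", basename(path))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  ncol_extra <- lengths(rows) - 4
  charges <- if (all(ncol_extra >= 1))
    vapply(rows, function(r) as.numeric(r[5]), 0) else NULL
  types <- if (all(ncol_extra >= 2)) vapply(rows, `[`, "", 6) else NULL
  monomer(el, xyz, charges = charges, types = types, name = name)
}

#' Write a monomer to an extended XYZ file
#' @param m a [monomer()].
#' @param path output path.
#' @export
write_xyz <- function(m, path) {
  rows <- sprintf("%-2s %16.10f %16.10f %16.10f %12.8f %s",
                  m$elements, m$xyz[, 1], m$xyz[, 2], m$xyz[, 3],
                  m$charges, m$types)
  writeLines(c(as.character(n_atoms(m)), paste0("name=", m$name), rows), path)
  invisible(path)
}
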