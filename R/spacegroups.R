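## Built-in space groups: the 26 orientation-grid search groups plus the
## 13 random-search defaults (a subset).  General-position operators are
## stored as x,y,z triplet strings in standard settings (monoclinic unique
## axis b) and parsed on demand; arbitrary groups can be supplied as
## explicit operator lists.

.SG_TABLE <- list(
  "P1"       = list(system = "triclinic",    ops = "x,y,z"),
  "P-1"      = list(system = "triclinic",    ops = "x,y,z;-x,-y,-z"),
  "P2"       = list(system = "monoclinic",   ops = "x,y,z;-x,y,-z"),
  "Pm"       = list(system = "monoclinic",   ops = "x,y,z;x,-y,z"),
  "Pc"       = list(system = "monoclinic",   ops = "x,y,z;x,-y,z+1/2"),
  "P21"      = list(system = "monoclinic",   ops = "x,y,z;-x,y+1/2,-z"),
  "P2/c"     = list(system = "monoclinic",   ops = "x,y,z;-x,y,-z+1/2;-x,-y,-z;x,-y,z+1/2"),
  "P21/m"    = list(system = "monoclinic",   ops = "x,y,z;-x,y+1/2,-z;-x,-y,-z;x,-y+1/2,z"),
  "P2/m"     = list(system = "monoclinic",   ops = "x,y,z;-x,y,-z;-x,-y,-z;x,-y,z"),
  "P21/c"    = list(system = "monoclinic",   ops = "x,y,z;-x,y+1/2,-z+1/2;-x,-y,-z;x,-y+1/2,z+1/2"),
  "Cc"       = list(system = "monoclinic",   ops = "x,y,z;x,-y,z+1/2;x+1/2,y+1/2,z;x+1/2,-y+1/2,z+1/2"),
  "C2"       = list(system = "monoclinic",   ops = "x,y,z;-x,y,-z;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z"),
  "C2/c"     = list(system = "monoclinic",   ops = "x,y,z;-x,y,-z+1/2;-x,-y,-z;x,-y,z+1/2;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z+1/2;-x+1/2,-y+1/2,-z;x+1/2,-y+1/2,z+1/2"),
  "Pnn2"     = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;-x+1/2,y+1/2,z+1/2;x+1/2,-y+1/2,z+1/2"),
  "Pba2"     = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;-x+1/2,y+1/2,z;x+1/2,-y+1/2,z"),
  "Pnc2"     = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;-x,y+1/2,z+1/2;x,-y+1/2,z+1/2"),
  "P2221"    = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z+1/2;x,-y,-z;-x,y,-z+1/2"),
  "Pmn21"    = list(system = "orthorhombic", ops = "x,y,z;-x+1/2,-y,z+1/2;-x,y,z;x+1/2,-y,z+1/2"),
  "Pma2"     = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;-x+1/2,y,z;x+1/2,-y,z"),
  "P21212"   = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;x+1/2,-y+1/2,-z;-x+1/2,y+1/2,-z"),
  "P212121"  = list(system = "orthorhombic", ops = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2"),
  "Pca21"    = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z+1/2;-x+1/2,y,z+1/2;x+1/2,-y,z"),
  "Pna21"    = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z+1/2;-x+1/2,y+1/2,z+1/2;x+1/2,-y+1/2,z"),
  "Pnma"     = list(system = "orthorhombic", ops = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z+1/2;-x,y+1/2,-z;-x,-y,-z;x+1/2,y,-z+1/2;-x+1/2,y+1/2,z+1/2;x,-y+1/2,z"),
  "Fdd2"     = list(system = "orthorhombic", ops = "x,y,z;-x,-y,z;-x+1/4,y+1/4,z+1/4;x+1/4,-y+1/4,z+1/4;x,y+1/2,z+1/2;-x,-y+1/2,z+1/2;-x+1/4,y+3/4,z+3/4;x+1/4,-y+3/4,z+3/4;x+1/2,y,z+1/2;-x+1/2,-y,z+1/2;-x+3/4,y+1/4,z+3/4;x+3/4,-y+1/4,z+3/4;x+1/2,y+1/2,z;-x+1/2,-y+1/2,z;-x+3/4,y+3/4,z+1/4;x+3/4,-y+3/4,z+1/4"),
  "Pbcn"     = list(system = "orthorhombic", ops = "x,y,z;-x+1/2,-y+1/2,z+1/2;x+1/2,-y+1/2,-z;-x,y,-z+1/2;-x,-y,-z;x+1/2,y+1/2,-z+1/2;-x+1/2,y+1/2,z;x,-y,z+1/2"),
  "Pbca"     = list(system = "orthorhombic", ops = "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2;-x,-y,-z;x+1/2,y,-z+1/2;-x+1/2,y+1/2,z;x,-y+1/2,z+1/2")
)

#' Names of the built-in space groups
#'
#' @param set `"grid"` for the 26 deterministic-search groups, `"random"`
#'   for the 13 random-search defaults, `"all"` for every built-in symbol.
#' @return character vector of Hermann-Mauguin symbols.
#' @export
spacegroup_names <- function(set = c("all", "grid", "random")) {
  set <- match.arg(set)
  random13 <- c("C2", "C2/c", "Cc", "P1", "P-1", "P21", "P21/c",
                "P212121", "Pbca", "Pc", "Pbcn", "Pca21", "Pna21")
  grid26 <- setdiff(names(.SG_TABLE), "P2221")
  switch(set, all = names(.SG_TABLE), grid = grid26, random = random13)
}

#' Parse an x,y,z symmetry triplet
#'
#' Turns e.g. `"-x+1/2, y, -z+1/2"` into a rotation matrix and fractional
#' translation.  Shared by the space-group tables and the CIF reader.
#'
#' @param s triplet string.
#' @return list with integer-like 3x3 `M` and length-3 `t` in `[0, 1)`.
#' @export
parse_triplet <- function(s) {
  parts <- strsplit(gsub(" ", "", s), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("bad symmetry triplet: ", s)
  M <- matrix(0, 3, 3)
  tvec <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    ## tokenize into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sgn <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        M[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        fr <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        tvec[i] <- tvec[i] + sgn * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tvec[i] <- tvec[i] + sgn * as.numeric(body)
      } else stop("cannot parse symmetry term '", tm, "' in ", s)
    }
  }
  list(M = M, t = tvec %% 1)
}

format_triplet <- function(op) {
  ax <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      if (op$M[i, j] == 1) s <- paste0(s, if (nzchar(s)) "+" else "", ax[j])
      if (op$M[i, j] == -1) s <- paste0(s, "-", ax[j])
    }
    tv <- op$t[i] %% 1
    if (abs(tv) > 1e-9) {
      fr <- c("1/2" = 0.5, "1/4" = 0.25, "3/4" = 0.75, "1/3" = 1 / 3,
              "2/3" = 2 / 3, "1/6" = 1 / 6, "5/6" = 5 / 6)
      k <- which(abs(fr - tv) < 1e-9)
      s <- paste0(s, "+", if (length(k)) names(fr)[k[1]] else format(tv))
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

#' Space group object
#'
#' @param symbol Hermann-Mauguin symbol of a built-in group (see
#'   [spacegroup_names()]), or any label when `ops` is supplied.
#' @param ops optional character vector / semicolon-joined string of x,y,z
#'   triplets defining the general position; overrides the built-in table.
#' @param system crystal system (needed only with explicit `ops`;
#'   `"triclinic"`, `"monoclinic"` or `"orthorhombic"`).
#' @return object of class `cspff_spacegroup` with fields `symbol`,
#'   `system`, `ops` (list of `M`, `t`) and `order`.
#' @export
spacegroup <- function(symbol, ops = NULL, system = NULL) {
  if (is.null(ops)) {
    entry <- .SG_TABLE[[symbol]]
    if (is.null(entry)) stop("unknown space group '", symbol,
                             "'; supply explicit operator triplets")
    ops <- entry$ops
    system <- entry$system
  }
  if (length(ops) == 1 && grepl(";", ops)) ops <- strsplit(ops, ";")[[1]]
  oplist <- lapply(ops, parse_triplet)
  if (is.null(system)) system <- "triclinic"
  ## identity must be present
  has_id <- any(vapply(oplist, function(o)
    all(o$M == diag(3)) && all(abs(o$t) < 1e-9), TRUE))
  if (!has_id) stop("space group operator list lacks the identity")
  structure(list(symbol = symbol, system = system, ops = oplist,
                 order = length(oplist)),
            class = "cspff_spacegroup")
}

#' @export
print.cspff_spacegroup <- function(x, ...) {
  cat(sprintf("<space group %s (%s), order %d>\n", x$symbol, x$system, x$order))
  invisible(x)
}

## Free lattice parameters by crystal system (angles in degrees fixed at
## 90 unless the system frees them).
free_cell_params <- function(system) {
  switch(system,
    triclinic = c("a", "b", "c", "alpha", "beta", "gamma"),
    monoclinic = c("a", "b", "c", "beta"),
    orthorhombic = c("a", "b", "c"),
    stop("unsupported crystal system: ", system)
  )
}
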