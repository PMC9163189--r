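## Minimal core-CIF 1.1 reader/writer for molecular crystals.
## Symmetry is taken from _symmetry_equiv_pos_as_xyz when present (so
## non-standard settings round-trip through their explicit operator
## lists), else from the Hermann-Mauguin symbol against the built-in
## table.  Molecules are re-assembled from atom sites by covalent-radius
## bonding with nearest-image stitching.

#' Write a crystal structure to a CIF file
#'
#' Writes the cell, the symmetry operator list, and the asymmetric-unit
#' atom sites (whole molecules, fractional coordinates, possibly outside
#' `[0,1)` so molecules stay connected).
#'
#' @param s a [crystal()].
#' @param path output path.
#' @param data_name data block name.
#' @export
write_cif <- function(s, path, data_name = "cspff") {
  l <- s$lattice
  A <- lattice_matrix(l)
  Ainv <- solve(A)
  lines <- c(
    sprintf("data_%s", data_name),
    sprintf("_cell_length_a %.6f", l$a),
    sprintf("_cell_length_b %.6f", l$b),
    sprintf("_cell_length_c %.6f", l$c),
    sprintf("_cell_angle_alpha %.6f", l$alpha),
    sprintf("_cell_angle_beta %.6f", l$beta),
    sprintf("_cell_angle_gamma %.6f", l$gamma),
    sprintf("_symmetry_space_group_name_H-M '%s'", s$sg$symbol),
    sprintf("_cell_formula_units_Z %d", s$Z),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(s$sg$ops, function(op) sprintf("'%s'", format_triplet(op)), ""),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  )
  cnt <- 0
  for (e in s$asu) {
    X <- asu_atoms(e, A)
    Xf <- X %*% Ainv
    for (i in seq_len(nrow(Xf))) {
      cnt <- cnt + 1
      lines <- c(lines, sprintf("%s%d %s %.6f %.6f %.6f",
                                e$monomer$elements[i], cnt,
                                e$monomer$elements[i],
                                Xf[i, 1], Xf[i, 2], Xf[i, 3]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## Tokenize a CIF line respecting single/double quotes.
.cif_tokens <- function(line) {
  out <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (startsWith(rest, "'") || startsWith(rest, "\"")) {
      qch <- substr(rest, 1, 1)
      close <- regexpr(paste0(qch, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (close < 0) stop("unterminated quote in CIF line: ", line)
      out <- c(out, substr(rest, 2, close))
      rest <- trimws(substr(rest, close + 2, nchar(rest)))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) { out <- c(out, rest); rest <- "" }
      else { out <- c(out, substr(rest, 1, sp - 1)); rest <- trimws(substr(rest, sp, nchar(rest))) }
    }
  }
  out
}

#' Read a crystal structure from a CIF file
#'
#' Requires cell parameters and fractional atom sites; symmetry comes
#' from the `_symmetry_equiv_pos_as_xyz` loop when present, otherwise the
#' Hermann-Mauguin symbol is looked up in the built-in table.  Atom sites
#' are stitched into molecules by covalent-radius bonding (nearest
#' periodic image), each connected component becoming one rigid monomer
#' of the asymmetric unit.
#'
#' @param path CIF file path.
#' @param bond_scale bonding threshold as a multiple of the summed
#'   covalent radii.
#' @return a [crystal()].
#' @export
read_cif <- function(path, bond_scale = 1.25) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  tags <- list()
  sym_ops <- character(0)
  sites <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "data_")) { i <- i + 1; next }
    if (identical(tolower(ln), "loop_")) {
      hdr <- character(0)
      i <- i + 1
      while (i <= n && grepl("^\\s*_", lines[i])) {
        hdr <- c(hdr, trimws(lines[i])); i <- i + 1
      }
      if (!length(hdr))
        stop("malformed loop_ at line ", i - 1, ": no tag lines follow 'loop_'")
      rows <- list()
      while (i <= n) {
        ln2 <- trimws(lines[i])
        if (!nzchar(ln2) || grepl("^(_|loop_|data_)", ln2, ignore.case = TRUE)) break
        toks <- .cif_tokens(ln2)
        if (length(toks) != length(hdr))
          stop("malformed loop_ row at line ", i, ": expected ", length(hdr),
               " values, got ", length(toks), " ('", ln2, "')")
        rows[[length(rows) + 1]] <- toks
        i <- i + 1
      }
      hl <- tolower(hdr)
      if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", hl))) {
        col <- which(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", hl))[1]
        sym_ops <- vapply(rows, `[`, "", col)
      } else if (any(grepl("^_atom_site_fract_x$", hl))) {
        get <- function(tag) {
          cc <- which(hl == tag)
          if (!length(cc)) return(NULL)
          vapply(rows, `[`, "", cc[1])
        }
        sites <- list(
          label = get("_atom_site_label"),
          symbol = get("_atom_site_type_symbol"),
          x = as.numeric(get("_atom_site_fract_x")),
          y = as.numeric(get("_atom_site_fract_y")),
          z = as.numeric(get("_atom_site_fract_z"))
        )
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- .cif_tokens(ln)
      if (length(toks) >= 2) tags[[tolower(toks[1])]] <- toks[2]
      i <- i + 1
      next
    }
    i <- i + 1
  }
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(tags)))
    stop("CIF ", path, " lacks cell parameters (", paste(need, collapse = ", "), ")")
  if (!length(sites$x))
    stop("CIF ", path, " lacks an _atom_site_ loop with fractional coordinates")
  num <- function(tag, default = NULL) {
    v <- tags[[tag]]
    if (is.null(v)) {
      if (is.null(default)) stop("CIF missing tag ", tag)
      return(default)
    }
    as.numeric(sub("\\(.*\\)$", "", v))   # strip esd parentheses
  }
  l <- lattice(num("_cell_length_a"), num("_cell_length_b"), num("_cell_length_c"),
               num("_cell_angle_alpha", 90), num("_cell_angle_beta", 90),
               num("_cell_angle_gamma", 90))
  symbol <- tags[["_symmetry_space_group_name_h-m"]]
  if (is.null(symbol)) symbol <- tags[["_space_group_name_h-m_alt"]]
  sg <- if (length(sym_ops)) {
    spacegroup(if (is.null(symbol)) "custom" else gsub(" ", "", symbol),
               ops = sym_ops,
               system = tryCatch(spacegroup(gsub(" ", "", symbol))$system,
                                 error = function(e) "triclinic"))
  } else if (!is.null(symbol)) {
    spacegroup(gsub(" ", "", symbol))
  } else stop("CIF ", path, " has neither symmetry operators nor an H-M symbol")

  ## assemble molecules from sites
  el <- if (!is.null(sites$symbol)) sites$symbol else gsub("[0-9]+$", "", sites$label)
  frac <- cbind(sites$x, sites$y, sites$z)
  A <- lattice_matrix(l)
  nat <- nrow(frac)
  rads <- covalent_radius(el)
  ## bonding via nearest image
  adj <- vector("list", nat)
  if (nat > 1) {
    for (ii in 1:(nat - 1)) for (jj in (ii + 1):nat) {
      df <- frac[jj, ] - frac[ii, ]
      df <- df - round(df)
      d <- sqrt(sum((df %*% A)^2))
      if (d < bond_scale * (rads[ii] + rads[jj])) {
        adj[[ii]] <- c(adj[[ii]], jj); adj[[jj]] <- c(adj[[jj]], ii)
      }
    }
  }
  seen <- logical(nat)
  asu <- list()
  for (start in seq_len(nat)) {
    if (seen[start]) next
    ## BFS with unwrapping
    comp <- start
    pos <- matrix(NA_real_, nat, 3)
    pos[start, ] <- frac[start, ]
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (seen[nb]) next
        df <- frac[nb, ] - pos[cur, ]
        pos[nb, ] <- pos[cur, ] + (df - round(df))
        seen[nb] <- TRUE
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
    }
    comp <- sort(comp)
    X <- pos[comp, , drop = FALSE] %*% A
    mon <- monomer(el[comp], X, name = sprintf("%s_mol%d", basename(path),
                                               length(asu) + 1))
    masses <- mon$masses
    com_f <- colSums(pos[comp, , drop = FALSE] * masses) / sum(masses)
    fit <- fit_pose(mon, X)
    asu[[length(asu) + 1]] <- list(monomer = mon, frac = com_f - floor(com_f),
                                   quat = fit$quat, invert = fit$invert)
  }
  crystal(l, sg, asu)
}
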