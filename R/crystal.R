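## Crystal data model: lattice, space-group expansion, density, contacts,
## Niggli reduction, supercell re-description.

#' Lattice from cell parameters
#'
#' @param a,b,c cell lengths (Angstrom).
#' @param alpha,beta,gamma cell angles (degrees), in (0, 180).
#' @return list of class `cspff_lattice`.
#' @export
lattice <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  l <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (lattice_volume(l) <= 1e-6) stop("degenerate lattice (volume ~ 0)")
  structure(l, class = "cspff_lattice")
}

#' Row-vector lattice matrix (rows are the cell vectors a, b, c)
#' @param l a [lattice()].
#' @return 3x3 matrix; Cartesian = fractional `%*%` matrix.
#' @export
lattice_matrix <- function(l) {
  ca <- cos(l$alpha * pi / 180); cb <- cos(l$beta * pi / 180)
  cg <- cos(l$gamma * pi / 180); sg <- sin(l$gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("impossible cell angles")
  rbind(
    c(l$a, 0, 0),
    c(l$b * cg, l$b * sg, 0),
    c(l$c * cb, l$c * (ca - cb * cg) / sg, l$c * sqrt(v2) / sg)
  )
}

lattice_volume <- function(l) {
  ca <- cos(l$alpha * pi / 180); cb <- cos(l$beta * pi / 180)
  cg <- cos(l$gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return(0)
  l$a * l$b * l$c * sqrt(v2)
}

lattice_from_matrix <- function(A) {
  a <- sqrt(sum(A[1, ]^2)); b <- sqrt(sum(A[2, ]^2)); c <- sqrt(sum(A[3, ]^2))
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  lattice(a, b, c, ang(A[2, ], A[3, ]), ang(A[1, ], A[3, ]), ang(A[1, ], A[2, ]))
}

#' Crystal structure of rigid molecules
#'
#' @param lattice a [lattice()].
#' @param sg a [spacegroup()] or Hermann-Mauguin symbol.
#' @param asu asymmetric unit: list of entries
#'   `list(monomer =, frac =, quat =, invert = FALSE)` giving each rigid
#'   molecule's fractional centre-of-mass position, scalar-first orientation
#'   quaternion and an optional body-frame inversion flag (set when a
#'   molecule image arises from an improper operation).
#' @return object of class `cspff_crystal` with `Z = length(asu) * order`.
#' @export
crystal <- function(lattice, sg, asu) {
  if (is.character(sg)) sg <- spacegroup(sg)
  stopifnot(inherits(lattice, "cspff_lattice"), inherits(sg, "cspff_spacegroup"))
  asu <- lapply(asu, function(e) {
    stopifnot(inherits(e$monomer, "cspff_monomer"), length(e$frac) == 3,
              length(e$quat) == 4)
    e$quat <- e$quat / sqrt(sum(e$quat^2))
    if (is.null(e$invert)) e$invert <- FALSE
    e
  })
  structure(list(lattice = lattice, sg = sg, asu = asu,
                 Z = length(asu) * sg$order),
            class = "cspff_crystal")
}

#' @export
print.cspff_crystal <- function(x, ...) {
  l <- x$lattice
  cat(sprintf(
    "<crystal %s, Z=%d, a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f, rho=%.3f g/cm3>\n",
    x$sg$symbol, x$Z, l$a, l$b, l$c, l$alpha, l$beta, l$gamma, density(x)))
  invisible(x)
}

## Cartesian atoms of one asymmetric-unit entry.
asu_atoms <- function(e, A) {
  body <- if (e$invert) -e$monomer$xyz else e$monomer$xyz
  sweep(body %*% t(quat_to_matrix(e$quat)), 2,
        as.vector(e$frac %*% A), "+")
}

#' Expand the asymmetric unit by the space-group operators
#'
#' Applies every general-position operator to every asymmetric-unit
#' molecule and wraps each image's centre of mass into the home cell.
#'
#' @param s a [crystal()].
#' @param check_special if `TRUE`, error when an operator maps a molecule
#'   onto itself (special position: the expansion would double-count).
#' @return list of molecule images, each
#'   `list(xyz, monomer, asu_index, op_index, com_frac)`.
#' @export
expand_symmetry <- function(s, check_special = TRUE) {
  A <- lattice_matrix(s$lattice)
  Ainv <- solve(A)
  out <- vector("list", s$Z)
  k <- 0
  for (ia in seq_along(s$asu)) {
    e <- s$asu[[ia]]
    X <- asu_atoms(e, A)
    m <- e$monomer
    for (io in seq_along(s$sg$ops)) {
      op <- s$sg$ops[[io]]
      Xf <- X %*% Ainv
      Xf2 <- Xf %*% t(op$M)
      Xf2 <- sweep(Xf2, 2, op$t, "+")
      com_f <- colSums(Xf2 * m$masses) / sum(m$masses)
      shift <- floor(com_f)
      Xf2 <- sweep(Xf2, 2, shift)
      com_f <- com_f - shift
      k <- k + 1
      out[[k]] <- list(xyz = Xf2 %*% A, monomer = m, asu_index = ia,
                       op_index = io, com_frac = com_f)
    }
  }
  if (check_special) {
    for (ia in seq_along(s$asu)) {
      idx <- which(vapply(out, function(mm) mm$asu_index == ia, TRUE))
      coms <- t(vapply(out[idx], function(mm) mm$com_frac, numeric(3)))
      if (nrow(coms) > 1) {
        d <- as.matrix(stats::dist(coms))
        ## also compare across the periodic wrap
        for (i in seq_len(nrow(coms) - 1)) for (j in (i + 1):nrow(coms)) {
          dd <- abs(coms[i, ] - coms[j, ])
          dd <- pmin(dd, 1 - dd)
          if (sqrt(sum(dd^2)) < 1e-6) {
            xi <- out[[idx[i]]]$xyz; xj <- out[[idx[j]]]$xyz
            if (max(abs(xi - xj)) < 1e-5)
              stop("molecule sits on a special position (operator ", j,
                   " maps it onto itself); half occupancy is not supported")
          }
        }
      }
    }
  }
  out
}

## Flattened per-atom view used by the compiled kernels.
crystal_atoms <- function(s) {
  mols <- expand_symmetry(s, check_special = FALSE)
  xyz <- do.call(rbind, lapply(mols, `[[`, "xyz"))
  molid <- rep(seq_along(mols) - 1L,
               vapply(mols, function(m) nrow(m$xyz), 0L))
  types <- unlist(lapply(mols, function(m) m$monomer$types))
  charges <- unlist(lapply(mols, function(m) m$monomer$charges))
  elements <- unlist(lapply(mols, function(m) m$monomer$elements))
  masses <- unlist(lapply(mols, function(m) m$monomer$masses))
  list(xyz = xyz, molid = molid, types = types, charges = charges,
       elements = elements, masses = masses, mols = mols)
}

#' Crystal density in g/cm^3
#' @param s a [crystal()].
#' @export
density <- function(s) {
  mass <- sum(vapply(s$asu, function(e) molecular_mass(e$monomer), 0)) * s$sg$order
  vol_cm3 <- lattice_volume(s$lattice) * 1e-24
  mass / (AVOGADRO * vol_cm3)
}

#' Shortest intermolecular atom-atom distance (Angstrom)
#'
#' Searched over periodic images; intramolecular pairs are ignored.
#' @param s a [crystal()].
#' @export
min_contact <- function(s) {
  at <- crystal_atoms(s)
  A <- lattice_matrix(s$lattice)
  nmax <- image_bounds(A, 4 + molecule_span(s))
  cpp_min_contact(at$xyz, at$molid, A, nmax)
}

molecule_span <- function(s) {
  max(vapply(s$asu, function(e) max(sqrt(rowSums(e$monomer$xyz^2))), 0))
}

## Number of image cells needed along each axis to cover `reach` Angstrom.
image_bounds <- function(A, reach) {
  Ainv <- solve(A)
  h <- 1 / sqrt(colSums(Ainv^2))   # interplanar spacings
  pmax(1L, as.integer(ceiling(reach / h)))
}

#' Re-describe a crystal as P1 (all molecules explicit)
#' @param s a [crystal()].
#' @return equivalent [crystal()] in P1.
#' @export
as_p1 <- function(s) {
  A <- lattice_matrix(s$lattice)
  mols <- expand_symmetry(s, check_special = FALSE)
  asu <- lapply(mols, function(mm) {
    fit <- fit_pose(mm$monomer, mm$xyz)
    list(monomer = mm$monomer, frac = as.vector(mm$com_frac),
         quat = fit$quat, invert = fit$invert)
  })
  crystal(s$lattice, spacegroup("P1"), asu)
}

## Recover (quat, invert) representing cartesian atoms X of a monomer.
fit_pose <- function(m, X) {
  com <- colSums(X * m$masses) / sum(m$masses)
  X0 <- sweep(X, 2, com)
  k1 <- kabsch(m$xyz, X0)
  if (n_atoms(m) > 1 && k1$rmsd > 1e-6) {
    k2 <- kabsch(-m$xyz, X0)
    if (k2$rmsd < k1$rmsd) return(list(quat = mat_to_quat(k2$rotation), invert = TRUE,
                                       rmsd = k2$rmsd))
  }
  list(quat = mat_to_quat(k1$rotation), invert = FALSE, rmsd = k1$rmsd)
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    ss <- sqrt(tr + 1) * 2
    q <- c(ss / 4, (R[3, 2] - R[2, 3]) / ss, (R[1, 3] - R[3, 1]) / ss,
           (R[2, 1] - R[1, 2]) / ss)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    ss <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / ss, ss / 4, (R[1, 2] + R[2, 1]) / ss,
           (R[1, 3] + R[3, 1]) / ss)
  } else if (R[2, 2] > R[3, 3]) {
    ss <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / ss, (R[1, 2] + R[2, 1]) / ss, ss / 4,
           (R[2, 3] + R[3, 2]) / ss)
  } else {
    ss <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / ss, (R[1, 3] + R[3, 1]) / ss,
           (R[2, 3] + R[3, 2]) / ss, ss / 4)
  }
  q / sqrt(sum(q^2))
}

#' Supercell re-description (always returned in P1)
#' @param s a [crystal()].
#' @param n integer vector of replication counts along a, b, c.
#' @export
supercell <- function(s, n = c(2, 1, 1)) {
  p1 <- as_p1(s)
  l <- s$lattice
  A <- lattice_matrix(l)
  A2 <- diag(n) %*% A
  asu2 <- list()
  for (i1 in seq_len(n[1]) - 1) for (i2 in seq_len(n[2]) - 1)
    for (i3 in seq_len(n[3]) - 1) {
      for (e in p1$asu) {
        f <- (e$frac + c(i1, i2, i3)) / n
        asu2[[length(asu2) + 1]] <- list(monomer = e$monomer, frac = f,
                                         quat = e$quat, invert = e$invert)
      }
    }
  crystal(lattice_from_matrix(A2), spacegroup("P1"), asu2)
}

#' Niggli-reduced form of a lattice
#'
#' Krivy-Gruber iterative reduction.  Returns the canonical reduced cell
#' parameters together with the unimodular transform `T` such that the
#' reduced cell matrix is `T %*% lattice_matrix(l)`.
#'
#' @param l a [lattice()].
#' @param eps numerical tolerance.
#' @return list with `lattice` (reduced) and `transform`.
#' @export
niggli_reduce <- function(l, eps = 1e-5) {
  M <- lattice_matrix(l)
  Tm <- diag(3)
  metric <- function(Tm) {
    B <- Tm %*% M
    list(A = sum(B[1, ]^2), B = sum(B[2, ]^2), C = sum(B[3, ]^2),
         xi = 2 * sum(B[2, ] * B[3, ]), eta = 2 * sum(B[1, ] * B[3, ]),
         zeta = 2 * sum(B[1, ] * B[2, ]))
  }
  C1 <- matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, byrow = TRUE)
  C2 <- matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, byrow = TRUE)
  for (iter in 1:200) {
    g <- metric(Tm)
    ## A1: order |a| <= |b|
    if (g$A > g$B + eps ||
        (abs(g$A - g$B) < eps && abs(g$xi) > abs(g$eta) + eps)) {
      Tm <- C1 %*% Tm; next
    }
    ## A2: order |b| <= |c|
    if (g$B > g$C + eps ||
        (abs(g$B - g$C) < eps && abs(g$eta) > abs(g$zeta) + eps)) {
      Tm <- C2 %*% Tm; next
    }
    ## A3/A4: canonical angle signs (all acute or all non-acute)
    if (g$xi * g$eta * g$zeta > eps^3) {
      D <- diag(c(if (g$xi < 0) -1 else 1, if (g$eta < 0) -1 else 1,
                  if (g$zeta < 0) -1 else 1))
      if (any(diag(D) != 1)) { Tm <- D %*% Tm; g <- metric(Tm) }
    } else {
      d <- c(1, 1, 1); r <- 0
      vals <- c(g$xi, g$eta, g$zeta)
      for (i in 1:3) {
        if (vals[i] > eps) d[i] <- -1
        else if (abs(vals[i]) <= eps) r <- i
      }
      if (prod(d) < 0) {
        if (r > 0) d[r] <- -1
        else d[which.max(abs(vals))] <- d[which.max(abs(vals))] * 1  # unreachable
      }
      if (prod(d) > 0 && any(d != 1)) { Tm <- diag(d) %*% Tm; g <- metric(Tm) }
    }
    ## A5
    if (abs(g$xi) > g$B + eps ||
        (abs(g$xi - g$B) < eps && 2 * g$eta < g$zeta - eps) ||
        (abs(g$xi + g$B) < eps && g$zeta < -eps)) {
      P <- diag(3); P[3, 2] <- -sign(g$xi)
      Tm <- P %*% Tm; next
    }
    ## A6
    if (abs(g$eta) > g$A + eps ||
        (abs(g$eta - g$A) < eps && 2 * g$xi < g$zeta - eps) ||
        (abs(g$eta + g$A) < eps && g$zeta < -eps)) {
      P <- diag(3); P[3, 1] <- -sign(g$eta)
      Tm <- P %*% Tm; next
    }
    ## A7
    if (abs(g$zeta) > g$A + eps ||
        (abs(g$zeta - g$A) < eps && 2 * g$xi < g$eta - eps) ||
        (abs(g$zeta + g$A) < eps && g$eta < -eps)) {
      P <- diag(3); P[2, 1] <- -sign(g$zeta)
      Tm <- P %*% Tm; next
    }
    ## A8
    if (g$xi + g$eta + g$zeta + g$A + g$B < -eps ||
        (abs(g$xi + g$eta + g$zeta + g$A + g$B) < eps &&
         2 * (g$A + g$eta) + g$zeta > eps)) {
      P <- diag(3); P[3, ] <- c(1, 1, 1)
      Tm <- P %*% Tm; next
    }
    break
  }
  B <- Tm %*% M
  list(lattice = lattice_from_matrix(B), transform = Tm)
}

#' Niggli-reduce a crystal's cell
#'
#' Returns the same crystal re-described (in P1) on the Niggli-reduced
#' basis; molecule geometry is untouched and the volume is preserved.
#'
#' @param s a [crystal()].
#' @export
reduce_cell <- function(s) {
  red <- niggli_reduce(s$lattice)
  A2 <- lattice_matrix(red$lattice)
  ## align the reduced basis exactly with the canonical orientation
  p1 <- as_p1(s)
  Bold <- red$transform %*% lattice_matrix(s$lattice)
  ## rotation mapping Bold onto canonical A2
  R <- solve(Bold) %*% A2   # Bold %*% R = A2 (up to orthogonal transform)
  asu2 <- lapply(p1$asu, function(e) {
    X <- asu_atoms(e, lattice_matrix(s$lattice))
    Xn <- X %*% R
    f <- colSums((Xn %*% solve(A2)) * e$monomer$masses) / sum(e$monomer$masses)
    fit <- fit_pose(e$monomer, Xn)
    list(monomer = e$monomer, frac = f - floor(f), quat = fit$quat,
         invert = fit$invert)
  })
  crystal(red$lattice, spacegroup("P1"), asu2)
}
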