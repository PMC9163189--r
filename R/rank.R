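## Polymorph de-duplication, ranking, and overlap scoring against a
## reference crystal.

#' Polymorph set
#'
#' @param structures list of [crystal()] objects (minimized).
#' @param energies lattice energies (kJ/mol per molecule).
#' @param densities optional densities (g/cm^3, recomputed if missing).
#' @param meta optional provenance data frame.
#' @return object of class `cspff_polymorphs` with an entries table
#'   (`id`, `energy`, `density`, `cluster`, `rank`).
#' @export
polymorph_set <- function(structures, energies, densities = NULL, meta = NULL) {
  stopifnot(length(structures) == length(energies))
  if (is.null(densities))
    densities <- vapply(structures, density, 0)
  tab <- data.frame(id = seq_along(structures), energy = energies,
                    density = densities, cluster = NA_integer_,
                    rank = NA_integer_)
  structure(list(structures = structures, table = tab, meta = meta),
            class = "cspff_polymorphs")
}

#' @export
print.cspff_polymorphs <- function(x, ...) {
  nclust <- length(unique(stats::na.omit(x$table$cluster)))
  cat(sprintf("<polymorph set: %d structures, %s cluster(s), E in [%.3f, %.3f] kJ/mol>\n",
              nrow(x$table),
              if (nclust) nclust else "unclustered",
              min(x$table$energy), max(x$table$energy)))
  invisible(x)
}

#' Sorted intermolecular heavy-atom distance fingerprint
#'
#' The `n_dist` shortest intermolecular heavy-atom distances of the
#' periodic structure, sorted ascending -- a cheap packing descriptor
#' that is invariant under cell re-description.
#'
#' @param s a [crystal()].
#' @param n_dist fingerprint length.
#' @export
structure_fingerprint <- function(s, n_dist = 200) {
  at <- crystal_atoms(s)
  heavy <- at$elements != "H"
  A <- lattice_matrix(s$lattice)
  reach <- 4
  repeat {
    nmax <- image_bounds(A, reach + 2 * molecule_span(s))
    shifts <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2],
                                    -nmax[3]:nmax[3]))
    xyz <- at$xyz[heavy, , drop = FALSE]
    mol <- at$molid[heavy]
    d_all <- numeric(0)
    for (k in seq_len(nrow(shifts))) {
      t3 <- as.vector(shifts[k, ] %*% A)
      home <- all(shifts[k, ] == 0)
      D <- cross_distances(xyz, sweep(xyz, 2, t3, "+"))
      if (home) D[outer(mol, mol, "==")] <- Inf
      d_all <- c(d_all, D[D < reach])
    }
    if (length(d_all) >= 2 * n_dist) break   # pairs double-counted
    reach <- reach * 1.5
  }
  d <- sort(d_all)
  ## each unordered pair appears twice in the double loop
  d[seq(2, min(length(d), 2 * n_dist), by = 2)]
}

#' Cluster polymorphs into duplicate groups
#'
#' Two structures are duplicates when their energies agree within
#' `deltaE`, their Niggli-reduced cell parameters agree within
#' `cell_tol` (relative, lengths) and `angle_tol` (degrees), and their
#' distance fingerprints agree within `fp_tol` RMS.  Duplicate relations
#' are closed transitively (union-find), so the clustering is
#' deterministic and order-independent; each cluster's representative is
#' its lowest-energy member.
#'
#' @param pset a [polymorph_set()].
#' @param deltaE energy tolerance (kJ/mol).
#' @param cell_tol relative tolerance on reduced cell lengths.
#' @param angle_tol absolute tolerance on reduced cell angles (degrees).
#' @param fp_tol RMS tolerance on the distance fingerprint (Angstrom).
#' @param n_dist fingerprint length.
#' @return the set with cluster ids assigned.
#' @export
cluster_structures <- function(pset, deltaE = 0.5, cell_tol = 0.01,
                               angle_tol = 1, fp_tol = 0.05, n_dist = 200) {
  n <- length(pset$structures)
  red <- lapply(pset$structures, function(s) niggli_reduce(s$lattice)$lattice)
  fps <- lapply(pset$structures, structure_fingerprint, n_dist = n_dist)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  E <- pset$table$energy
  same_cell <- function(l1, l2) {
    len1 <- c(l1$a, l1$b, l1$c); len2 <- c(l2$a, l2$b, l2$c)
    ang1 <- c(l1$alpha, l1$beta, l1$gamma); ang2 <- c(l2$alpha, l2$beta, l2$gamma)
    all(abs(len1 - len2) / pmax(len1, len2) < cell_tol) &&
      all(abs(ang1 - ang2) < angle_tol)
  }
  Zs <- vapply(pset$structures, function(s) s$Z, 0L)
  vpm <- vapply(seq_len(n), function(i)
    lattice_volume(red[[i]]) / Zs[i], 0)   # volume per molecule
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(E[i] - E[j]) >= deltaE) next
    ## same crystal in two descriptions: equal-Z cells must agree after
    ## reduction; different-Z descriptions (sub/super-cell settings) are
    ## compared on volume per molecule, with the fingerprint deciding
    if (Zs[i] == Zs[j]) {
      if (!same_cell(red[[i]], red[[j]])) next
    } else {
      if (abs(vpm[i] - vpm[j]) / pmax(vpm[i], vpm[j]) >= cell_tol) next
    }
    m <- min(length(fps[[i]]), length(fps[[j]]))
    if (sqrt(mean((fps[[i]][1:m] - fps[[j]][1:m])^2)) >= fp_tol) next
    union(i, j)
  }
  roots <- vapply(seq_len(n), find, 0L)
  pset$table$cluster <- match(roots, sort(unique(roots)))
  pset
}

#' Rank cluster representatives by lattice energy
#'
#' Representatives (lowest-energy member of each cluster) are sorted by
#' ascending energy; ties below 1e-6 kJ/mol break by descending density,
#' then id.  Ranks 1..K are written onto the representatives.
#'
#' @param pset a clustered [polymorph_set()].
#' @return the set with ranks assigned; `representatives` holds the
#'   entry ids in rank order.
#' @export
rank_polymorphs <- function(pset) {
  tab <- pset$table
  if (anyNA(tab$cluster)) {
    ## unclustered: every structure its own cluster
    tab$cluster <- seq_len(nrow(tab))
  }
  reps <- vapply(split(seq_len(nrow(tab)), tab$cluster), function(idx)
    idx[order(tab$energy[idx], -tab$density[idx], tab$id[idx])][1], 0L)
  o <- order(round(tab$energy[reps] / 1e-6) * 1e-6,
             -tab$density[reps], tab$id[reps])
  reps <- reps[o]
  tab$rank <- NA_integer_
  tab$rank[reps] <- seq_along(reps)
  pset$table <- tab
  pset$representatives <- tab$id[reps]
  pset
}

#' Energy-density landscape table
#'
#' @param pset a ranked [polymorph_set()].
#' @return data frame (one row per cluster representative, sorted by
#'   rank): `rank`, `energy`, `rel_energy`, `density`, `space_group`.
#' @export
landscape_table <- function(pset) {
  if (is.null(pset$representatives)) pset <- rank_polymorphs(pset)
  idx <- match(pset$representatives, pset$table$id)
  data.frame(
    rank = pset$table$rank[idx],
    energy = pset$table$energy[idx],
    rel_energy = pset$table$energy[idx] - min(pset$table$energy[idx]),
    density = pset$table$density[idx],
    space_group = vapply(pset$structures[idx], function(s) s$sg$symbol, "")
  )
}

## A cluster of n whole molecules around a central one, as Cartesian
## heavy-atom blocks.
molecule_cluster <- function(s, n, center = 1L, heavy_only = TRUE) {
  at <- crystal_atoms(s)
  mols <- at$mols
  A <- lattice_matrix(s$lattice)
  reach <- (n / max(1, s$Z))^(1 / 3) * max(lattice_volume(s$lattice)^(1 / 3), 3) + 6
  nmax <- image_bounds(A, reach)
  shifts <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2],
                                  -nmax[3]:nmax[3]))
  ccom <- as.vector(mols[[center]]$com_frac %*% A)
  all_mols <- list()
  for (k in seq_len(nrow(shifts))) {
    t3 <- as.vector(shifts[k, ] %*% A)
    for (im in seq_along(mols)) {
      m <- mols[[im]]
      com <- as.vector(m$com_frac %*% A) + t3
      all_mols[[length(all_mols) + 1]] <- list(
        xyz = sweep(m$xyz, 2, t3, "+"), monomer = m$monomer,
        com = com, d = sqrt(sum((com - ccom)^2)))
    }
  }
  dists <- vapply(all_mols, `[[`, 0, "d")
  sel <- order(dists)[seq_len(min(n, length(all_mols)))]
  out <- all_mols[sel]
  if (heavy_only) {
    out <- lapply(out, function(m) {
      hv <- m$monomer$elements != "H"
      m$xyz <- m$xyz[hv, , drop = FALSE]
      m$elements <- m$monomer$elements[hv]
      m
    })
  }
  out
}

#' RMSD over an n-molecule cluster (packing-similarity score)
#'
#' Builds an `n`-molecule cluster around a central molecule in each
#' crystal, tries every symmetry-inequivalent central molecule of the
#' candidate against the reference's, superposes the central molecules
#' (proper rotations only), matches the remaining molecules greedily by
#' centre-of-mass distance, and reports the smallest final least-squares
#' RMSD over all matched heavy atoms.
#'
#' @param cand,ref [crystal()] structures of the same monomer.
#' @param n cluster size (default 20).
#' @param threshold match threshold (Angstrom, default 0.8).
#' @param heavy_only compare heavy atoms only (default).
#' @return list (class `cspff_overlap`): `rmsd`, `n_molecules`,
#'   `matched`, `rotation`, `translation`.
#' @export
rmsd_n <- function(cand, ref, n = 20, threshold = 0.8, heavy_only = TRUE) {
  formula_of <- function(s) {
    tb <- table(s$asu[[1]]$monomer$elements)
    paste(names(tb), as.integer(tb), sep = ":", collapse = ",")
  }
  if (!identical(formula_of(ref), formula_of(cand)))
    stop("candidate and reference are built from different molecules")
  ref_cl <- molecule_cluster(ref, n, center = 1L, heavy_only = heavy_only)
  best <- NULL
  for (center in seq_len(cand$Z)) {
    ## the candidate pool is drawn larger than n: the n-th neighbour
    ## shell can be tied, and the matching must be free to pick either
    ## member of a tie
    cand_cl <- molecule_cluster(cand, n + 10, center = center,
                                heavy_only = heavy_only)
    res <- tryCatch(
      .overlap_clusters(cand_cl, ref_cl),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$rmsd < best$rmsd)) best <- res
  }
  if (is.null(best)) stop("no central-molecule pairing could be superposed")
  structure(list(rmsd = best$rmsd, n_molecules = length(ref_cl),
                 matched = best$rmsd < threshold,
                 rotation = best$rotation, translation = best$translation),
            class = "cspff_overlap")
}

#' @export
print.cspff_overlap <- function(x, ...) {
  cat(sprintf("<overlap: RMSD over %d molecules = %.4f Angstrom (%s)>\n",
              x$n_molecules, x$rmsd,
              if (x$matched) "match" else "no match"))
  invisible(x)
}

.overlap_clusters <- function(cand_cl, ref_cl) {
  stopifnot(length(cand_cl) >= length(ref_cl))
  ## superpose central molecules
  xc <- cand_cl[[1]]$xyz; xr <- ref_cl[[1]]$xyz
  if (nrow(xc) != nrow(xr)) stop("central molecules differ")
  k0 <- kabsch(xc, xr)
  apply_tf <- function(X, tf) X %*% t(tf$rotation) +
    matrix(tf$translation, nrow(X), 3, byrow = TRUE)
  for (pass in 1:2) {
    cand_t <- lapply(cand_cl, function(m) {
      m$xyz_t <- apply_tf(m$xyz, k0)
      m$com_t <- as.vector(k0$rotation %*% m$com) + k0$translation
      m
    })
    ## greedy matching by transformed COM distance
    used <- logical(length(cand_t))
    match_idx <- integer(length(ref_cl))
    for (ir in seq_along(ref_cl)) {
      dr <- vapply(seq_along(cand_t), function(ic) {
        if (used[ic] || nrow(cand_t[[ic]]$xyz) != nrow(ref_cl[[ir]]$xyz))
          return(Inf)
        sqrt(sum((cand_t[[ic]]$com_t - ref_cl[[ir]]$com)^2))
      }, 0)
      ic <- which.min(dr)
      if (!is.finite(dr[ic])) stop("cluster matching failed")
      used[ic] <- TRUE
      match_idx[ir] <- ic
    }
    X <- do.call(rbind, lapply(match_idx, function(ic) cand_cl[[ic]]$xyz))
    Y <- do.call(rbind, lapply(ref_cl, `[[`, "xyz"))
    stopifnot(nrow(X) == nrow(Y))
    kf <- kabsch(X, Y)
    if (pass == 1) k0 <- kf                 # refine matching once
  }
  list(rmsd = kf$rmsd, rotation = kf$rotation, translation = kf$translation)
}
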