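## Periodic lattice energy: direct sums for repulsion/dispersion within a
## real-space cutoff, Ewald summation for charge-charge terms with the
## short-range Tang-Toennies complement (1 - f1) folded into the
## real-space part.  Energies are normalized per molecule.

## Pack a force field for the compiled kernels: unique sorted type list,
## a (ntype x ntype) 0-based row-index matrix and the parameter matrix
## with columns (alpha, beta, a1, a2, A12, C6, C8, delta1, delta6,
## delta8, A).
ff_pack <- function(ff, types) {
  ut <- sort(unique(types))
  nt <- length(ut)
  keys <- character(0)
  pairidx <- matrix(0L, nt, nt)
  rows <- list()
  for (i in seq_len(nt)) for (j in i:nt) {
    key <- pair_key(ut[i], ut[j])
    p <- ff$pairs[[key]]
    if (is.null(p))
      stop("force field has no parameters for atom-type pair '", key, "'")
    rows[[length(rows) + 1]] <- as.numeric(p[.PAIR_FIELDS[1:11]])
    pairidx[i, j] <- pairidx[j, i] <- length(rows) - 1L
    keys <- c(keys, key)
  }
  list(types = ut, typeidx = match(types, ut) - 1L,
       pairidx = pairidx, par = do.call(rbind, rows),
       form_code = match(ff$form, c("extended", "exp61", "lj1261")) - 1L,
       keys = keys)
}

ewald_params <- function(A, accuracy = 1e-6, cutoff = 15) {
  ## erfc(eta*rc)/rc ~ accuracy-ish; eta*rc = 4.2 gives erfc ~ 2.9e-9
  eta <- 4.2 / cutoff
  kcut <- 2 * eta * 4.2
  Ainv <- solve(A)
  d <- 1 / sqrt(colSums(Ainv^2))          # interplanar spacings
  kmax <- pmax(1L, as.integer(ceiling(kcut * d / (2 * pi))))
  list(eta = eta, kmax = kmax)
}

#' Lattice energy per molecule, with diagnostics
#'
#' @param ff a [forcefield()].
#' @param s a [crystal()].
#' @param cutoff real-space cutoff (Angstrom) for the non-Coulomb terms
#'   and for the Ewald real-space sum; no tail correction is applied.
#' @param contact_floor shortest allowed intermolecular contact; below it
#'   the structure is flagged as collapsed.
#' @return list with `energy` (kJ/mol per molecule), `noncoul`, `coul`
#'   (per molecule), `min_contact`, `max_pair_energy` and `collapsed`.
#' @export
lattice_energy_detail <- function(ff, s, cutoff = 15, contact_floor = 0.3) {
  at <- crystal_atoms(s)
  pk <- ff_pack(ff, at$types)
  A <- lattice_matrix(s$lattice)
  has_charges <- any(abs(at$charges) > 0)
  if (has_charges && abs(sum(at$charges)) > 1e-6)
    stop(sprintf("unit cell is not charge neutral (net %+.4f e); Ewald Coulomb undefined",
                 sum(at$charges)))
  ew <- ewald_params(A, cutoff = cutoff)
  span <- molecule_span(s)
  nmax <- image_bounds(A, cutoff + 2 * span + 1e-6)
  res <- cpp_lattice_sums(at$xyz, at$molid, pk$typeidx, at$charges,
                          pk$pairidx, pk$par, pk$form_code, A, solve(A),
                          cutoff, nmax, has_charges, ew$eta, ew$kmax,
                          contact_floor)
  Z <- s$Z
  list(energy = (res$noncoul + res$coul) / Z,
       noncoul = res$noncoul / Z, coul = res$coul / Z,
       min_contact = res$min_contact,
       max_pair_energy = res$max_pair_energy,
       collapsed = res$collapsed)
}

## Fast repeated-evaluation path: pre-packs the force field, operator
## matrices and per-atom metadata once; each call only rebuilds
## coordinates.  Used by the minimizer.
make_lattice_evaluator <- function(ff, s, cutoff = 15, contact_floor = 0.3) {
  entries <- lapply(s$asu, function(e) {
    body <- if (e$invert) -e$monomer$xyz else e$monomer$xyz
    list(body = body, types = e$monomer$types, charges = e$monomer$charges)
  })
  nop <- s$sg$order
  Ms <- do.call(rbind, lapply(s$sg$ops, `[[`, "M"))
  ts <- do.call(rbind, lapply(s$sg$ops, `[[`, "t"))
  types <- unlist(lapply(entries, function(e) rep(e$types, nop)))
  charges <- unlist(lapply(entries, function(e) rep(e$charges, nop)))
  molid <- unlist(lapply(seq_along(entries), function(i) {
    nat <- nrow(entries[[i]]$body)
    rep((i - 1) * nop + seq_len(nop) - 1L, each = nat)
  }))
  pk <- ff_pack(ff, types)
  has_charges <- any(abs(charges) > 0)
  if (has_charges && abs(sum(charges)) > 1e-6)
    stop("unit cell is not charge neutral; Ewald Coulomb undefined")
  span <- max(vapply(entries, function(e) max(sqrt(rowSums(e$body^2))), 0))
  Z <- s$Z
  function(l, poses) {
    A <- lattice_matrix(l)
    Ainv <- solve(A)
    blocks <- vector("list", length(entries))
    for (i in seq_along(entries)) {
      p <- poses[[i]]
      X <- entries[[i]]$body %*% t(quat_to_matrix(p$quat))
      X <- sweep(X, 2, as.vector(p$frac %*% A), "+")
      blocks[[i]] <- cpp_expand_ops(X, A, Ainv, Ms, ts)
    }
    xyz <- do.call(rbind, blocks)
    ew <- ewald_params(A, cutoff = cutoff)
    nmax <- image_bounds(A, cutoff + 2 * span + 1e-6)
    res <- cpp_lattice_sums(xyz, molid, pk$typeidx, charges,
                            pk$pairidx, pk$par, pk$form_code, A, Ainv,
                            cutoff, nmax, has_charges, ew$eta, ew$kmax,
                            contact_floor)
    list(energy = (res$noncoul + res$coul) / Z,
         noncoul = res$noncoul / Z, coul = res$coul / Z,
         min_contact = res$min_contact,
         max_pair_energy = res$max_pair_energy,
         collapsed = res$collapsed)
  }
}

#' Lattice energy per molecule (kJ/mol)
#'
#' Half-sum of all two-body intermolecular interactions between a
#' reference molecule and its periodic environment, averaged over the
#' molecules of the cell.
#'
#' @inheritParams lattice_energy_detail
#' @export
lattice_energy <- function(ff, s, cutoff = 15) {
  det <- lattice_energy_detail(ff, s, cutoff = cutoff)
  if (det$min_contact < 0.3)
    stop(sprintf("atom overlap: intermolecular contact %.3f Angstrom < 0.3", det$min_contact))
  det$energy
}
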