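#' @keywords internal
#' @useDynLib cspff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Unit system: lengths in Angstrom, energies in kJ/mol, charges in
## elementary charge units, masses in amu.  The Coulomb prefactor converts
## q_a*q_b/r [e^2/Angstrom] to kJ/mol.
COULOMB_KJ <- 1389.35458      # kJ mol^-1 Angstrom e^-2
AVOGADRO <- 6.02214076e23

## Atomic masses (amu) and single-bond covalent radii (Angstrom) for the
## elements the fixtures and CIF reader need.
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Cl = 35.45, S = 32.06, P = 30.974, Cs = 132.905,
  Zn = 65.38, B = 10.811, Br = 79.904
)

.COVALENT_RADIUS <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Cl = 1.02, S = 1.05, P = 1.07, Cs = 2.44,
  Zn = 1.22, B = 0.84, Br = 1.20
)

element_mass <- function(el) {
  m <- .ELEMENT_MASS[el]
  if (anyNA(m)) stop("unknown element(s): ", paste(el[is.na(m)], collapse = ", "))
  unname(m)
}

covalent_radius <- function(el) {
  r <- .COVALENT_RADIUS[el]
  if (anyNA(r)) stop("unknown element(s): ", paste(el[is.na(r)], collapse = ", "))
  unname(r)
}
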