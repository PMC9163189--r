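## Built-in small rigid molecules for examples and tests, with exact
## coordinates embedded in code (synthetic stand-ins for the small
## organic molecules such searches are run on).

#' Built-in fixture monomers
#'
#' Programmatically constructed rigid molecules: `"diatomic"` (a polar
#' NO-like diatomic, two atom types), `"triatomic"` (a bent NO2-like
#' molecule whose shape anisotropy plus dipole lock crystal orientations,
#' making it the preferred planted-truth test system), `"methanol"` (a
#' 6-atom methanol-like molecule with hydroxyl/methyl hydrogen types)
#' and `"ring"` (a benzene-like planar C6H6 ring).  All are charge
#' neutral with centre of mass at the origin.
#'
#' @param name fixture name; omit for the list of all three.
#' @return a [monomer()], or a named list of all fixtures.
#' @export
fixture_monomers <- function(name = NULL) {
  all <- list(
    diatomic = monomer(
      c("N", "O"),
      rbind(c(0, 0, 0), c(0, 0, 1.15)),
      charges = c(0.35, -0.35),
      name = "diatomic"),
    triatomic = monomer(
      c("N", "O", "O"),
      rbind(c(0, 0.33, 0), c(-1.10, -0.25, 0), c(1.10, -0.25, 0)),
      charges = c(0.44, -0.22, -0.22),
      name = "triatomic"),
    methanol = monomer(
      c("C", "O", "H", "H", "H", "H"),
      rbind(
        c(-0.046, 0.662, 0.000),    # C
        c(-0.046, -0.758, 0.000),   # O
        c(0.860, -1.055, 0.000),    # H (hydroxyl)
        c(0.986, 1.021, 0.000),     # H (methyl)
        c(-0.556, 1.044, 0.889),    # H (methyl)
        c(-0.556, 1.044, -0.889)),  # H (methyl)
      charges = c(0.130, -0.650, 0.400, 0.040, 0.040, 0.040),
      types = c("C", "O", "HO", "HC", "HC", "HC"),
      name = "methanol"),
    ring = monomer(
      c(rep("C", 6), rep("H", 6)),
      {
        th <- (0:5) * pi / 3
        rbind(cbind(1.396 * cos(th), 1.396 * sin(th), 0),
              cbind(2.480 * cos(th), 2.480 * sin(th), 0))
      },
      charges = c(rep(-0.115, 6), rep(0.115, 6)),
      name = "ring")
  )
  if (is.null(name)) return(all)
  m <- all[[name]]
  if (is.null(m)) stop("unknown fixture '", name, "'; have: ",
                       paste(names(all), collapse = ", "))
  m
}

#' Example ground-truth force field for a fixture monomer
#'
#' A physically plausible extended-form potential over the fixture's
#' atom-type pairs (exponential repulsion around the van der Waals
#' contact, dispersion coefficients of typical first-row magnitude,
#' dampings near the repulsion steepness).  Used as the hidden truth of
#' the synthetic oracle in examples, tests and the worked pipeline runs.
#'
#' @param name fixture name (see [fixture_monomers()]).
#' @return an extended-form [forcefield()].
#' @export
fixture_truth_ff <- function(name = "diatomic") {
  if (name %in% c("diatomic", "triatomic")) {
    return(forcefield("extended", list(
      "N:N" = pair_params(alpha = 10.2, beta = 3.4, a1 = 0.25, a2 = -0.02,
                          A12 = 4000, C6 = 1300, C8 = 9000,
                          delta1 = 3.2, delta6 = 2.8, delta8 = 2.8),
      "N:O" = pair_params(alpha = 10.0, beta = 3.5, a1 = 0.15, a2 = -0.015,
                          A12 = 3500, C6 = 1100, C8 = 8000,
                          delta1 = 3.4, delta6 = 2.9, delta8 = 2.9),
      "O:O" = pair_params(alpha = 9.8, beta = 3.6, a1 = 0.2, a2 = -0.01,
                          A12 = 3000, C6 = 900, C8 = 7000,
                          delta1 = 3.6, delta6 = 3.0, delta8 = 3.0))))
  }
  if (name == "methanol") {
    types <- c("C", "HC", "HO", "O")
    base <- list(C = c(a = 11.0, b = 3.4, A12 = 6000, C6 = 1500, C8 = 10000),
                 O = c(a = 10.4, b = 3.7, A12 = 3500, C6 = 800, C8 = 6000),
                 HC = c(a = 8.2, b = 3.9, A12 = 300, C6 = 150, C8 = 800),
                 HO = c(a = 7.8, b = 4.1, A12 = 150, C6 = 90, C8 = 500))
    pairs <- list()
    for (i in seq_along(types)) for (j in i:length(types)) {
      pi_ <- base[[types[i]]]; pj <- base[[types[j]]]
      pairs[[pair_key(types[i], types[j])]] <- pair_params(
        alpha = (pi_[["a"]] + pj[["a"]]) / 2,
        beta = (pi_[["b"]] + pj[["b"]]) / 2,
        a1 = 0.1, a2 = -0.01,
        A12 = sqrt(pi_[["A12"]] * pj[["A12"]]),
        C6 = sqrt(pi_[["C6"]] * pj[["C6"]]),
        C8 = sqrt(pi_[["C8"]] * pj[["C8"]]),
        delta1 = 3.3, delta6 = 2.9, delta8 = 2.9)
    }
    return(forcefield("extended", pairs))
  }
  if (name == "ring") {
    return(forcefield("extended", list(
      "C:C" = pair_params(alpha = 11.0, beta = 3.5, a1 = 0.1, a2 = -0.01,
                          A12 = 6000, C6 = 1700, C8 = 11000,
                          delta1 = 3.3, delta6 = 2.9, delta8 = 2.9),
      "C:H" = pair_params(alpha = 9.4, beta = 3.7, a1 = 0.1, a2 = -0.01,
                          A12 = 1300, C6 = 520, C8 = 3300,
                          delta1 = 3.5, delta6 = 3.1, delta8 = 3.1),
      "H:H" = pair_params(alpha = 7.8, beta = 3.9, a1 = 0.1, a2 = -0.01,
                          A12 = 280, C6 = 160, C8 = 1000,
                          delta1 = 3.7, delta6 = 3.3, delta8 = 3.3))))
  }
  stop("no built-in truth force field for fixture '", name, "'")
}
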