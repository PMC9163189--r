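## Analytic two-body atom-atom pair potentials.
##
## Three functional forms are supported:
##   extended : [1 + a1 r + a2 r^2] e^(alpha - beta r) + A12/r^12
##              - sum_{n=6,8} f_n(delta_n, r) C_n/r^n
##              + f_1(delta_1, r) k_C q_a q_b / r
##   exp61    : A e^(-beta r) - C6/r^6 + k_C q_a q_b / r
##   lj1261   : A12/r^12     - C6/r^6 + k_C q_a q_b / r
## with f_n the Tang-Toennies damping functions.  exp61 stores the
## prefactor A directly (A = e^alpha of the extended form) for numerical
## conditioning; the conversion is alpha = log(A).

#' Tang-Toennies damping function
#'
#' `f_n(delta, r) = 1 - exp(-delta r) * sum_{m=0}^{n} (delta r)^m / m!`,
#' which switches an `1/r^n` term off smoothly at short range.  For small
#' `delta*r` the complement is evaluated through the exponential series
#' remainder to avoid catastrophic cancellation.
#'
#' @param n integer order (1, 6 or 8 in the potentials used here).
#' @param delta damping range parameter (1/Angstrom), >= 0.
#' @param r distance (Angstrom), >= 0; vectorized.
#' @return damping factor in `[0, 1]`, monotone non-decreasing in `r`.
#' @export
tang_toennies <- function(n, delta, r) {
  if (any(delta < 0)) stop("delta must be non-negative")
  if (any(r < 0)) stop("r must be non-negative")
  x <- delta * r
  ## 1 - e^-x sum_{m<=n} x^m/m!  ==  e^-x sum_{m>n} x^m/m!
  out <- numeric(length(x))
  small <- x < n + 1          # series remainder converges fast here
  if (any(small)) {
    xs <- x[small]
    term <- xs^(n + 1) / factorial(n + 1)
    acc <- term
    for (m in (n + 2):(n + 40)) {
      term <- term * xs / m
      acc <- acc + term
    }
    out[small] <- exp(-xs) * acc
  }
  if (any(!small)) {
    xl <- x[!small]
    s <- 1
    term <- rep(1, length(xl))
    for (m in seq_len(n)) {
      term <- term * xl / m
      s <- s + term
    }
    out[!small] <- 1 - exp(-xl) * s
  }
  pmin(pmax(out, 0), 1)
}

.PAIR_FIELDS <- c("alpha", "beta", "a1", "a2", "A12", "C6", "C8",
                  "delta1", "delta6", "delta8", "A")

#' Parameters of one atom-type pair
#'
#' Houses every symbol any of the three forms can read: `alpha`
#' (dimensionless), `beta` (1/Angstrom), `a1` (1/Angstrom), `a2`
#' (1/Angstrom^2), `A12` (kJ/mol Angstrom^12), `C6` (kJ/mol Angstrom^6),
#' `C8` (kJ/mol Angstrom^8), `delta1`, `delta6`, `delta8` (1/Angstrom) and
#' the exp-6-1 prefactor `A` (kJ/mol).
#'
#' @param ... named numeric parameter values; unnamed fields default to 0
#'   except the dampings, which default to a large value (undamped).
#' @return named numeric vector of class `cspff_pair_params`.
#' @export
pair_params <- function(...) {
  p <- c(alpha = 0, beta = 1, a1 = 0, a2 = 0, A12 = 0, C6 = 0, C8 = 0,
         delta1 = 50, delta6 = 50, delta8 = 50, A = 0)
  args <- list(...)
  if (length(args)) {
    bad <- setdiff(names(args), .PAIR_FIELDS)
    if (length(bad)) stop("unknown pair parameter(s): ", paste(bad, collapse = ", "))
    p[names(args)] <- unlist(args)
  }
  if (p[["beta"]] <= 0) stop("beta must be > 0")
  if (any(p[c("delta1", "delta6", "delta8")] <= 0)) stop("dampings must be > 0")
  if (any(p[c("C6", "C8", "A12")] < 0)) stop("C6, C8 and A12 must be >= 0")
  class(p) <- "cspff_pair_params"
  p
}

pair_key <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = ":")
}

#' Force field container
#'
#' @param form one of `"extended"`, `"exp61"`, `"lj1261"`; decides which
#'   fields of each pair's parameters are read.
#' @param pairs named list of [pair_params()], keyed `"type1:type2"` with
#'   the two labels in sorted order (see [pair_key()]).
#' @return object of class `cspff_forcefield`.  Partial charges live on the
#'   monomers, not here, so one charge set serves all three forms.
#' @export
forcefield <- function(form = c("extended", "exp61", "lj1261"), pairs) {
  form <- match.arg(form)
  stopifnot(is.list(pairs), length(pairs) >= 1, !is.null(names(pairs)))
  pairs <- lapply(pairs, function(p) {
    if (!inherits(p, "cspff_pair_params")) p <- do.call(pair_params, as.list(p))
    p
  })
  structure(list(form = form, pairs = pairs), class = "cspff_forcefield")
}

#' @export
print.cspff_forcefield <- function(x, ...) {
  cat(sprintf("<%s force field, %d atom-type pair(s): %s>\n",
              x$form, length(x$pairs), paste(names(x$pairs), collapse = ", ")))
  invisible(x)
}

ff_lookup <- function(ff, t1, t2) {
  key <- pair_key(t1, t2)
  p <- ff$pairs[[key]]
  if (is.null(p))
    stop("force field has no parameters for atom-type pair '", key, "'")
  p
}

#' Extended-form pair energy
#'
#' Single atom-atom term of the extended potential (see the package
#' vignette): polynomial-prefactored exponential repulsion, `A12/r^12`
#' wall, Tang-Toennies damped `-C6/r^6 - C8/r^8`, and damped Coulomb.
#'
#' @param p a [pair_params()].
#' @param qa,qb partial charges (e).
#' @param r distance (Angstrom), > 0; vectorized.
#' @return energy in kJ/mol.
#' @export
pair_energy_extended <- function(p, qa, qb, r) {
  if (any(r <= 0)) stop("r must be > 0")
  (1 + p[["a1"]] * r + p[["a2"]] * r^2) * exp(p[["alpha"]] - p[["beta"]] * r) +
    p[["A12"]] / r^12 -
    tang_toennies(6, p[["delta6"]], r) * p[["C6"]] / r^6 -
    tang_toennies(8, p[["delta8"]], r) * p[["C8"]] / r^8 +
    tang_toennies(1, p[["delta1"]], r) * COULOMB_KJ * qa * qb / r
}

#' Buckingham exp-6-1 pair energy: `A e^(-beta r) - C6/r^6 + k_C qa qb/r`
#' @inheritParams pair_energy_extended
#' @param A repulsion prefactor (kJ/mol).
#' @param beta repulsion range (1/Angstrom).
#' @param C6 dispersion coefficient (kJ/mol Angstrom^6).
#' @export
pair_energy_exp61 <- function(A, beta, C6, qa, qb, r) {
  if (any(r <= 0)) stop("r must be > 0")
  A * exp(-beta * r) - C6 / r^6 + COULOMB_KJ * qa * qb / r
}

#' Lennard-Jones 12-6-1 pair energy: `A12/r^12 - C6/r^6 + k_C qa qb/r`
#' @inheritParams pair_energy_exp61
#' @param A12 repulsive wall coefficient (kJ/mol Angstrom^12).
#' @export
pair_energy_lj1261 <- function(A12, C6, qa, qb, r) {
  if (any(r <= 0)) stop("r must be > 0")
  A12 / r^12 - C6 / r^6 + COULOMB_KJ * qa * qb / r
}

## Dispatch a single pair interaction for any form.
pair_energy <- function(ff, p, qa, qb, r) {
  switch(ff$form,
    extended = pair_energy_extended(p, qa, qb, r),
    exp61 = pair_energy_exp61(p[["A"]], p[["beta"]], p[["C6"]], qa, qb, r),
    lj1261 = pair_energy_lj1261(p[["A12"]], p[["C6"]], qa, qb, r)
  )
}

#' Write a force field as a human-readable key-value table
#'
#' One block per atom-type pair; exact decimal round-trip via `%.17g`.
#'
#' @param ff a [forcefield()].
#' @param path output path.
#' @export
write_forcefield <- function(ff, path) {
  lines <- c(sprintf("form %s", ff$form))
  for (key in names(ff$pairs)) {
    p <- ff$pairs[[key]]
    lines <- c(lines, sprintf("pair %s", key),
               sprintf("  %-7s %.17g", .PAIR_FIELDS, as.numeric(p[.PAIR_FIELDS])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a force field written by [write_forcefield()]
#' @param path file path.
#' @return a [forcefield()].
#' @export
read_forcefield <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  form <- sub("^form\\s+", "", lines[1])
  starts <- grep("^pair ", lines)
  pairs <- list()
  for (i in seq_along(starts)) {
    key <- sub("^pair\\s+", "", lines[starts[i]])
    end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    vals <- lines[(starts[i] + 1):end]
    kv <- strsplit(vals, "\\s+")
    p <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                         vapply(kv, `[`, "", 1))
    pairs[[key]] <- do.call(pair_params, as.list(p))
  }
  forcefield(form, pairs)
}
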