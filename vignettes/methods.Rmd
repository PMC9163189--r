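---
title: "Lattice-energy crystal structure prediction with fitted pair potentials: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-energy crystal structure prediction with fitted pair potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cspff)
```

This vignette is the package's own account of the science it implements:
the potential model, the fitting protocol, the search and ranking
machinery, the synthetic reference oracle, and the numerical choices that
were genuinely open.  Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The potential model

All energetics are two-body and rigid-monomer: a crystal's lattice energy
is a sum of dimer interaction energies, and each dimer energy is a sum of
atom–atom terms.  The extended pair form for an atom pair at distance
$r$ is

$$
v(r) = \bigl[1 + a_1 r + a_2 r^2\bigr]\,e^{\alpha-\beta r}
     + \frac{A_{12}}{r^{12}}
     - \sum_{n=6,8} f_n(\delta_n, r)\,\frac{C_n}{r^n}
     + f_1(\delta_1, r)\,\frac{k_C\,q_a q_b}{r},
$$

with the Tang–Toennies damping
$f_n(\delta,r) = 1 - e^{-\delta r}\sum_{m=0}^{n} (\delta r)^m/m!$.
The polynomial-prefactored exponential carries the exchange repulsion and
absorbs short-range charge-overlap effects; the $A_{12}/r^{12}$ wall
guarantees a repulsive core even where the exponential turns over; the
damped $C_6$, $C_8$ terms carry dispersion plus induction; the damped
point-charge term carries electrostatics without higher multipoles.
Units are fixed package-wide: Å, kJ/mol, elementary charges, and
$k_C = 1389.35458$ kJ mol⁻¹ Å e⁻².  The classical exp-6-1 and 12-6-1
forms are retained as baselines; exp-6-1 stores the prefactor $A$
directly rather than $e^\alpha$ for numerical conditioning
($\alpha = \log A$).

Atom typing defaults to the element symbol, with user labels for
symmetry-distinct atoms (the methanol-like fixture distinguishes hydroxyl
from methyl hydrogens).  Charges live on the monomers, not in the pair
table, so one charge set serves all three forms.

### Damping conventions

In `tang_toennies()` the complement $1-f_n$ is evaluated through the
exponential series remainder when $\delta r < n+1$, avoiding the
catastrophic cancellation of the naive formula at small arguments.  The
fitted model carries one damping range per pair for both dispersion
orders ($\delta_8 = \delta_6$) by default — the damping range is a
property of the atom pair, not of the inverse power.  This is not merely
cosmetic: with both orders free per pair, noiseless synthetic data admit
*label-switched* local minima in which the $n=6$ and $n=8$ channels trade
roles at a residual within numerical noise of the true one, so the
parameters are not practically identifiable even though the potential
is.  `fit_dispersion_damping(..., tie_dampings = FALSE)` restores the
fully free fit.

## The synthetic reference oracle

The oracle stands in for the quantum-mechanical stage that would supply
component-resolved dimer energies in production use.  A hidden
extended-form potential (the *truth*) is evaluated at sampled dimer
configurations and split into the four conventional components:
electrostatics (`elst`, the damped charge–charge part), first-order
exchange (`exch`, the repulsive wall), and the damped $C_6$/$C_8$
attractions booked as dispersion (`dispx`) and induction (`indx`)
according to a configurable rule — the fit only ever uses their sum, so
any split exercises it.  Independent Gaussian noise of configurable
standard deviation is added per component and the total re-summed, so
`total = elst + exch + indx + dispx` holds exactly even with noise.

Sampling emulates how potential-surface datasets are built: uniform
random orientations (uniform quaternions), 70% of separations uniform
over the interaction region and 30% log-spaced out to three times its
upper edge for the asymptotics.  The frozen study conditions are **700
configurations per dimer**, centre-of-mass separations 2.5–9 Å with the
tail to 27 Å, and a minimum intermolecular contact of **1.4 Å**.  The
contact floor matters: the repulsive wall (interaction energies up to a
few thousand kJ/mol) is what pins the dampings and the repulsion block;
sampling only the attractive well leaves them underdetermined.  What the
oracle does *not* emulate: many-body effects, monomer flexibility,
basis-set artefacts, or any systematic (non-Gaussian) error structure of
real electronic-structure components.  Passing recovery tests therefore
demonstrates the *fitting and search machinery*, not the accuracy of any
quantum method.

## The component-wise fit

`fit_forcefield()` runs four stages in a fixed order, each consuming the
component the parameters belong to:

1. **Long range** (`fit_long_range`): per-type charges from the
   electrostatic tail (quadratic least squares with each monomer's net
   charge constrained; for a neutral homodimer the overall charge sign is
   a gauge, fixed by making the first type's charge non-negative), and
   non-negative $C_6$, $C_8$ per pair from the summed `indx + dispx`
   tail.  The tail is $R > 2.5 \times R_\min$ by default.  The $C_6$/$C_8$
   columns are nearly collinear on the tail, so the solve uses
   near-relative weights (residuals scaled by $1/(|y| + 0.05)$): the wide
   dynamic range of the tail is exactly what separates the two inverse
   powers, and the floor keeps noise-dominated far points from taking
   over.
2. **Electrostatic damping** (`fit_electrostatic_damping`): $\delta_1$
   per pair by Levenberg–Marquardt with an analytic Jacobian
   ($\partial f_1/\partial\delta = r e^{-x} x$, $x = \delta r$).  Pairs
   with vanishing charge product are unidentifiable, flagged, and set to
   the configured default.
3. **Attraction damping** (`fit_dispersion_damping`): the per-pair
   damping range against `indx + dispx` over all separations, alternated
   with a linear tail re-solve of $C_6$/$C_8$ in which the current
   damping factors are divided out — this removes the residual-damping
   bias of the plain tail estimate while keeping both subproblems well
   posed (a free joint fit of coefficients and dampings is where the
   label-switching pathology lives).
4. **Repulsion** (`fit_repulsion`): $\alpha, \beta, a_1, a_2, A_{12}$ per
   pair by weighted nonlinear least squares against *total* energies with
   everything else frozen ($\beta > 0$ and $A_{12} \ge 0$ by
   parametrization).  The weights are $w = 1$ for $E \le 0$ and
   $w = (E_0/(E+E_0))^2$, $E_0 = 20$ kJ/mol, so the attractive well
   dominates — matching the negative-energy RMSE by which fits are
   judged.  Because that weighting carries almost no wall information,
   the stage first fits the repulsive-wall component alone on a
   *relative* scale (residuals scaled by $1/(|E_\mathrm{exch}|+1)$, where
   the flat directions of the polynomial-exponential block are far better
   conditioned) and uses the result as the starting point.

Component stages use uniform weights: the short-range points that the
$E_0$-weighting suppresses are precisely where damping acts.

**What is identifiable.**  On noiseless data the charges, $C_6$, $C_8$,
$\delta_1$ and the tied dispersion damping are recovered essentially
exactly, and the total-energy RMSE sits at the numerical floor
(`recovery_total_energy_rmse` in the acceptance output, order $10^{-6}$
kJ/mol).  The polynomial-repulsion block $(\alpha, \beta, a_1, a_2,
A_{12})$ has genuinely flat directions — only the function values over
the sampled window are determined — so recovery tests assert the
identifiable groups and the pointwise agreement of the potential, not
the raw repulsion parameters.

**Holes.**  Fitted exponential-repulsion potentials can turn over at very
short range and dive below the physical minimum.  `detect_holes()` scans
a set of orientations radially inward, takes the deepest well found in
the van der Waals region (separations beyond `r_physical`, 2.2 Å by
default) as the global physical minimum, and flags any ray whose energy
later drops meaningfully below it; the reported barrier is the highest
energy met along that ray before the drop.  Anchoring the reference to
the physical region matters twice over: a collapsing ray's own hole
bottom must not masquerade as the physical minimum, and a monotone
collapse with no protective bump at all is reported as a zero-barrier
hole rather than escaping detection.  `ensure_barrier()` scales
$A_{12}$ up by doubling-then-bisection until no hole remains below the
configured 100 kJ/mol barrier floor.  A 12-6-1 potential with a positive
wall cannot have holes, which is why it drives the first stage of every
minimization.

## Crystal model and lattice energies

A crystal is a lattice (cell parameters), a space group (operator table;
the 13 random-search and 26 orientation-grid groups are built in, and any
group can be supplied as explicit x,y,z triplets), and an asymmetric unit
of rigid-molecule poses (fractional centre of mass + scalar-first
quaternion, with a body-inversion flag for images generated by improper
operations).  Symmetry expansion, density, minimum intermolecular
contact, Niggli reduction (Krivý–Gruber), supercell re-description and
core-CIF 1.1 I/O are provided.

The lattice energy per molecule is the half-sum of two-body interactions
between a reference molecule and all periodic neighbours, averaged over
the cell: repulsion and dispersion by direct summation within a
real-space cutoff (15 Å default, no tail correction), charge–charge by
Ewald summation with the damping complement $(1-f_1)\,k_C q q/r$ — which
decays exponentially — folded into the real-space part, and
intramolecular pairs excluded.  The splitting parameter is
$\eta = 4.2/r_c$ with reciprocal-space extent matched to it, targeting
about $10^{-6}$ kJ/mol; the Madelung constants of rock-salt-type toys are
reproduced to that level (checked in the tests against literature values
and an independent neutral-shell direct sum).  Cells must be neutral for
the Coulomb part.  Energies are invariant under supercell re-description
and cell re-basis to well below the polymorph energy spacings.

## Search, minimization, ranking

**Generation.**  The deterministic generator crosses 51 coordination
geometries (26 space groups × two cell-contraction schemes, minus the
degenerate pair for P1 — a systematically constructed stand-in preserving
the search combinatorics, since the historical geometry definitions are
not public) with an inclusive Euler-angle grid (19³ orientations at the
default 10° step, i.e. 349,809 candidates), contracting the cell
directions against a pure $1/r^{12}$ contact repulsion until a threshold
is reached, then keeping the densest 500 per geometry.  The random
generator works per space group in two steps: unrestricted sampling to
estimate cell-length ranges (5th–95th percentiles of accepted cells),
then restricted sampling (±20% of the estimate) with a short, loose
12-6-1 pre-optimization; in both steps any structure whose worst
intermolecular atom–atom 12-6-1 energy exceeds 2000 kJ/mol is rejected.

**Minimization.**  Bounded quasi-Newton (L-BFGS-B, numerical gradients)
over a symmetry-reduced parameter vector: the crystal system's free cell
parameters plus 7 pose degrees of freedom per asymmetric-unit molecule
(quaternion renormalized every evaluation), so the space group is
preserved exactly by construction.  Staged protocol: minimize first with
the hole-free fitted 12-6-1 form, then with the extended form; a state
with an intermolecular contact below 0.7 Å or a per-molecule energy below
−500 kJ/mol flags a collapse and the best safe state is returned.  The
gradient check is numerical-only (the optimizer is derivative-free in the
analytic sense); determinism is exact for fixed settings.

**Clustering and ranking.**  Duplicates are detected by energy (0.5
kJ/mol), Niggli-reduced cell parameters (1% lengths, 1° angles) — or
volume per molecule when the two descriptions have different Z, with the
fingerprint deciding — and a sorted 200-distance intermolecular
heavy-atom fingerprint (0.05 Å RMS), closed transitively.  Ranking sorts
cluster representatives by energy with density tie-breaks.  Overlap
against a reference crystal is the least-squares RMSD over an optimally
superposed n-molecule cluster (n = 20, heavy atoms, proper rotations
only, 0.8 Å match threshold); the candidate pool is drawn larger than n
because the n-th neighbour shell can be tied, and matching must be free
to pick either member of a tie.  The matcher is greedy
(centre-of-mass-nearest after central-molecule superposition, refined
once) — exact for near-identical packings, which is its job here.

**Pipeline.**  `run_csp()` chains oracle → fits (extended + rough
12-6-1 from the same data) → random generation → clustering of the
rough-optimized pool → tight staged minimization of the lowest
`fine_top` representatives → clustering/ranking → landscape, with CIF
and CSV outputs and a reproducibility manifest.  Reducing the pool on
rough energies before the expensive stage mirrors standard practice
(rough minimization plus clustering, then fine minimization of the
reduced set).

## The refinement loop

`alt_csp_loop()` iterates: extract the nearest-neighbour dimers of the
top-ranked polymorphs, evaluate the reference oracle there, pool the new
references, and test convergence by comparing each polymorph's finite
5×5×5-cell block energy computed purely from the model against the
hybrid value in which every pair whose geometry matches a pooled
reference takes the reference energy instead.  If the largest gap
exceeds the threshold (1 kJ/mol per cluster by default, the fit
uncertainty scale the protocol targets), the force field is refitted on
training-plus-pool and the top polymorphs re-minimized.  Two tolerances
matter and were set deliberately: substitution requires essentially
identical geometries (0.02 Å sorted-distance RMS) and the pool keeps
everything except true duplicates (10⁻³ Å), because near the repulsive
wall the pair energy changes by tens of kJ/mol per Å — substituting a
reference computed 0.05 Å away injects several kJ/mol per pair and the
gap would plateau far above any meaningful threshold no matter how good
the fit is.  Only the top 20 polymorphs are re-minimized per iteration
(configurable), which resolves the ambiguity of whether the full pool
should be.

## Desk-scale study conditions

The planted-truth experiments run on a bent polar triatomic fixture
(NO₂-like: 3 atoms, two atom types, dipole from charges ±0.22/+0.44 e).
A polar *diatomic* was deliberately rejected for this role: its packing
landscape is plastic-crystal-like, with orientational valleys so flat
that two potentials agreeing to 10⁻⁵ kJ/mol can still relax the same
start to points 1 Å apart.  The triatomic's shape anisotropy plus dipole
lock the packing, giving a well-separated global minimum.  The search
uses four space groups (P1, P−1, P2₁, P2₁/c), 25 accepted candidates
per group, the lowest 24 distinct rough-optimized candidates fine
minimized, and the planted reference defined as the rank-1 structure of
the identical pipeline run with the hidden truth potential in place of
the fitted one.  These sizes are the package's chosen demonstration
scale; the machinery accepts arbitrary quotas.

## Known limitations

Rigid monomers only; two-body energetics only (no many-body
polarization); no thermal or zero-point effects (0 K ranking); Z′ ≤ 1
generation; the coordination-geometry library is a combinatorial
stand-in, not a reimplementation of the historical definitions; the
synthetic oracle's noise model is i.i.d. Gaussian per component, which
real electronic-structure errors are not; and the overlap matcher is
greedy rather than exhaustive, so for grossly different packings its
RMSD is an upper bound (it is exact in the near-duplicate regime where
the match/no-match decision lives).
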