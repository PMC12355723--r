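---
title: "Open-shell projection-based embedding with the Huzinaga equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-shell projection-based embedding with the Huzinaga equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huzembed)
```

## The problem

Many chemical questions concern a small reactive region — a radical center,
a bond being broken, a carbene lone pair — inside a molecule that is too
large for an accurate wave-function or hybrid-DFT treatment as a whole.
Multilevel ("focused") models treat the chemically active subsystem A with
a high-level method and the environment B with a cheaper one.  This package
implements projection-based embedding (PbE) for *open-shell* systems: the
supersystem is solved at the low level, its occupied orbitals are
partitioned between A and B, and the orbitals of A are then reoptimized at
the high level in the frozen potential of B while the Huzinaga projection
keeps them orthogonal to the frozen environment orbitals.

The multilevel energy is a first-order expansion of the subtractive
composite energy around the low-level density of A:

$$E_{\mathrm{PbE}} = E_2[AB] - E_2[A] + E_1[\tilde A] + V_{nn}
  + \mathrm{Tr}\!\left\{(\tilde D^{A} - D^{A})\,
    \frac{\partial E_{12}}{\partial D^{A}}\right\},$$

where tildes mark quantities of the reoptimized (high-level) subsystem and
the derivative defines the frozen embedding potential.  The defining
property of the construction is *same-level exactness*: embedding a method
in itself reproduces the supersystem energy to numerical precision, because
the low-level partition is a fixed point of the embedded equations.  Every
part of the pipeline is validated against this property in the test suite.

## Spin treatments

Two open-shell formalisms are implemented, plus their combinations:

* **Unrestricted (UHF/UKS).**  Independent spatial orbitals per spin.  Each
  spin channel is localized and partitioned on its own, the environment
  projector is the per-spin environment density, and the embedded SCF runs
  on the spin-dependent Huzinaga operator
  $\tilde H^\sigma = \tilde F^\sigma - \tilde F^\sigma R^{\sigma,B} S -
  S R^{\sigma,B} \tilde F^\sigma$.
* **Restricted open-shell (ROHF/ROKS).**  Shared spatial orbitals in the
  Roothaan ensemble formalism, restricted here to the high-spin case of
  half-filled open shells with parallel spins: a single microstate with
  fractional open-shell occupation $f = 1/2$ and the orbital-independent
  coupling parameters $a = 1$, $b = 2$.  With the per-spin views
  $D^\alpha = D^c/2 + D^o$ and $D^\beta = D^c/2$ the ensemble energy
  coincides with the unrestricted expression evaluated at those views,
  which is how the energy and the shell Fock matrices
  ($F^c = \partial E/\partial D^c = (F^\alpha + F^\beta)/2$,
  $F^o = \partial E/\partial D^o = F^\alpha$) are computed.  The two shell
  equations are folded into one symmetric pseudoeigenvalue problem
  $F = F^c - Q[D^o] + T$ with the coupling correction
  $Q = a_{\mathrm{HF}} K[D^o]$ and a shell-coupling matrix $T$ built from
  the shell projectors and the closed/open potential difference.  We
  verified by block analysis (and the suite verifies operationally, via
  stationarity of the shell blocks and agreement with direct energy
  minimization) that the occupied-virtual and closed-open blocks of this
  operator vanish exactly at the shell-equation solutions.
* **Mixed schemes.**  `uks_in_roks()` solves the restricted supersystem and
  continues with the unrestricted embedding machinery (useful when spin
  polarization matters only in A); `roks_in_uks()` solves the unrestricted
  supersystem, classifies the natural orbitals of the total density into
  doubly/singly occupied sets, and continues with the restricted embedding
  (useful when the restricted supersystem SCF will not converge).

A caveat the package makes explicit: the mixed schemes are *exactly* exact
at the same level only for closed-shell molecules, where the two
supersystem descriptions coincide.  For open shells the reconstructed
density is not a stationary point of the other ansatz, so the embedded
relaxation recovers a small amount of energy (second order in the density
difference; about $10^{-3}$ hartree for UHF-in-ROHF on the propyl-radical
fixture, and about $10^{-6}$ hartree in the ROHF-in-UHF direction).  The
test suite therefore asserts strict exactness for the pure schemes on
open-shell fixtures and for the mixed schemes on closed-shell fixtures,
with a few-kcal/mol consistency guard for the open-shell mixed runs.

The restricted embedding potential has two pieces,
$\partial E_{12}/\partial D^{c,A}$ and $\partial E_{12}/\partial D^{o,A}$.
Because the environment carries no open shells, both share the same
Coulomb/exchange core $\Delta J - \tfrac{a_{\mathrm{HF},2}}{2}\Delta K$
(which also defines the embedded core Hamiltonian), and they differ only in
the exchange-correlation channel: the closed-shell derivative carries the
spin-averaged supersystem-minus-subsystem potential difference, the
open-shell derivative the $\alpha$-channel difference.  The embedded
unified operator's coupling kernel is computed as
$G = \tilde F^c - \tilde F^o - Q/2$, an algebraically equivalent form of
the closed/open xc difference that remains well defined for a pure
Hartree-Fock high level.  Both potential matrices are validated against
directional finite differences of the composite energy (relative error
below $10^{-4}$, typically $10^{-5}$).

## The engine

No quantum-chemistry engine exists in the R ecosystem, so the package
carries a compact native one; it is part of the package's surface, not a
stand-in, and is tested against closed forms and independent quadrature:

* **Integrals.** McMurchie-Davidson recursions over contracted Cartesian
  Gaussians with $s$ and $p$ shells (Rcpp): overlap, kinetic, nuclear
  attraction, arbitrary point-charge fields, dipole moments, and the full
  two-electron tensor with eightfold symmetry.  The Boys function uses a
  downward-recursion series at small arguments and the closed form with
  upward recursion at large ones.
* **Bases.**  Generated at run time rather than shipped: each occupied
  Slater shell (1s; 2s/2p sharing exponents; 3s/3p sharing exponents) is
  expanded in $n$ Gaussians by maximizing the overlap with the normalized
  $\zeta = 1$ Slater radial function, and exponents are scaled by
  $\zeta^2$ per element using Slater's screening rules (hydrogen uses the
  customary molecular exponent 1.24).  For $\zeta = 1$, $n = 3$ this
  reproduces the classic universal three-Gaussian 1s expansion, which the
  suite asserts.  `min3g` (default), `min6g`, and a decontracted
  split-valence `split3g` are available.  Elements H-Ar are supported.
* **Quadrature.**  Becke fuzzy-cell weights (three smoothing iterations,
  Bragg-Slater radii) over a Gauss-Chebyshev radial rule with Becke's
  mapping and small closed-form Lebedev angular rules (26 or 50 points;
  grid levels 1-3 select 20x26, 30x50, 45x50 radial x angular points).
  One grid is built per context and reused for *every* xc evaluation —
  supersystem, subsystem, and embedded — so the subtractive energy
  differences cancel at the grid level and same-level exactness holds to
  machine precision independent of grid quality.
* **Functionals.**  `hf`, `lda` (Slater exchange + PW92 correlation),
  `pbe`, and `pbe0` (25% exact exchange).  Functionals are implemented as
  energy densities of $(\rho_\alpha, \rho_\beta, \gamma_{\alpha\alpha},
  \gamma_{\alpha\beta}, \gamma_{\beta\beta})$; the potential matrices are
  obtained by numerically exact per-point differentiation of the energy
  density (proportional central steps, one-sided at the $\rho \ge 0$
  boundary) followed by the usual density/gradient contractions.  This
  trades a little per-iteration cost for a single generic derivative path;
  the derivative consistency invariant (directional finite difference of
  $E_{xc}$ versus $\mathrm{Tr}\{V\Delta\}$) is tested for LDA and PBE.
* **Correlation.**  Canonical MP2 over semicanonicalized orbitals.  In
  embedded calculations the occupied space is the embedded active set and
  the virtual space is the full S-orthogonal complement of *all* occupied
  orbitals (active plus frozen environment) — the full-virtual-space
  convention — with orbital energies from the embedded Fock.  Environment
  occupied orbitals are excluded from the correlation treatment.  For
  restricted references the per-spin views are correlated with the
  spin-resolved embedded Fock matrices (off-diagonal couplings between the
  semicanonical blocks are neglected, the standard choice for
  non-Brillouin references).  Coupled-cluster methods are out of scope.
* **Dispersion.**  A BJ-damped pairwise $-C_6/R^6$ model over approximate
  free-atom $C_6$ coefficients, off by default.  What the multilevel
  machinery relies on — and what is tested — is the subsystem partition
  rule: a subsystem correction sums only pairs lying entirely inside the
  chosen atom set, with no three-body terms.

## Partitioning

Occupied orbitals are localized and assigned per spin (unrestricted) or
per shell (restricted; open shells are always active).  Two selectors are
provided:

* **SPADE** (default): rotate the occupied block by the right singular
  vectors of the active-atom rows of the symmetrically orthogonalized
  coefficients and split at the largest successive gap of the singular
  values (a zero is appended so a fully active spectrum gives an empty
  environment).  Singular-vector signs are fixed (largest component
  positive) so partitions are reproducible, and gap ties resolve to the
  smaller active set.  A spectrum with no gap (all values equal within
  1e-8) raises an error asking for a different active set.
* **Mulliken selection**: Boys-Foster localization (Jacobi sweeps over the
  dipole-center spread) followed by the population criterion
  $\sum_{\mu \in A}(SL)_{\mu i} L_{\mu i} > 0.3$.

A singly occupied orbital localized mostly on the environment is a
modelling error rather than a numerical one, so the restricted partition
keeps open shells active unconditionally and the documentation of
`fixture()` points users toward active sets containing the radical center.

## Numerical choices

* SCF: DIIS (subspace 8) on the orthonormal-basis commutator
  $[F, D]_S$ per spin (unrestricted) or with the total density and the
  unified operator (restricted); energy tolerance $10^{-9}$ hartree,
  residual tolerance $10^{-7}$; at most 150 iterations.  The restricted
  solver applies a 0.2-hartree level shift for five iterations whenever
  the closed-open gap drops below 0.01 hartree.  Initial guesses come from
  a superposition of spin-averaged atomic Hartree-Fock densities.
* Embedded SCF: warm start from the low-level active orbitals; occupied
  selection takes the lowest eigenvectors of the Huzinaga operator whose
  overlap with the environment projector is below 0.5 (the projection
  pushes environment orbitals to $+|\varepsilon|$, so this guard only
  trips on pathological inputs, where it raises an electron-count error).
* The reported first-order correction vanishes at the same-level fixed
  point only up to the SCF residual; with the default tolerances that
  means about $10^{-8}$ hartree, and the exactness checks use a
  $10^{-6}$-hartree criterion.
* Degenerate aufbau choices break ties by eigenvalue order; open shells
  are chosen by eigenvalue (highest occupied), reflecting the view that
  radical orbitals are the high-energy frontier of the occupied space.

## Baseline models

For assessment the package includes the competing focused models: vacuum
embedding (high-level energy of the hydrogen-capped active fragment),
subtractive ONIOM with mechanical embedding, and ONIOM with electronic
embedding, where the environment enters both model calculations as point
charges (IAO or Mulliken populations of the low-level supersystem; border
charges zeroed; the residual spread evenly over the remaining environment
charges so the field total equals parent minus model charge).  Link
hydrogens sit on the cut bond, 1.08 angstrom from the active atom.  The
telescoping identities (high = low collapses to the low-level supersystem;
model = whole molecule collapses to the high level; electronic embedding
reduces to mechanical as the charges are scaled to zero) hold to
$10^{-12}$ hartree and are tested.

## What the fixtures do and do not show

All test molecules are generated from idealized internal coordinates:
radicals (OH, CH3, propyl, pent-4-en-1-yl, an ester-chain radical), a
triplet carbene and triplet CH2, thiol/thiyl pairs, water clusters, and
helium dimers at parametric separation.  They are deliberately desk-scale
(up to ~35 AOs in the minimal basis) so that every acceptance property —
exactness, oracle equivalence, derivative validation, the
error-versus-subsystem-size trend for the hydrogen-abstraction reaction
pentene + OH -> pentenyl + H2O — runs in minutes on one CPU.  Passing
these tests demonstrates the correctness of the embedding algebra and its
implementation, not the production accuracy of any functional/basis
combination: real applications need larger bases, tighter grids, and
d-function-bearing elements beyond this engine's s/p scope, for which the
same algorithms apply unchanged on top of a full-featured integral
backend.

## Known limitations

* High-spin open shells only (half-filled, parallel spins); no
  configuration-averaged or low-spin ensembles.
* $s$/$p$ basis functions, elements H-Ar, generated minimal and
  split-valence sets; no d shells, no effective core potentials.
* The environment is frozen after partitioning (no freeze-and-thaw), and
  no level-shift ($\mu$-projector) variant is provided.
* MP2 is the only correlation treatment; dispersion is a simplified
  pairwise model rather than a coordination-number-dependent D3
  parameterization.
* Analytic nuclear gradients are not implemented.

## A worked example

```{r example, eval = FALSE}
mol <- fixture("propyl_radical")          # CH3-CH2-CH2., doublet
res <- pbe_roks(mol, xc_low = "pbe", xc_high = "pbe0",
                active_atoms = c(3, 9, 10), grid_level = 1)
print(res)
res$E_pbe                                  # multilevel total energy
```

The printed report decomposes the multilevel energy term by term
(supersystem low level, subtracted subsystem, embedded high level,
first-order correction, nuclear repulsion) and states the residual overlap
between embedded and environment orbitals.  `run_scheme()` drives the same
calculation from a YAML configuration, and `error_vs_subsystem_curve()`
reproduces the error-versus-active-size tables used in the acceptance
script.
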