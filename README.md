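# huzembed

Projection-based quantum embedding (PbE) for **open-shell molecules**,
built on the Huzinaga equation, in R.

## The problem and who this is for

Radical reactions, bond homolysis, and carbene chemistry usually happen in
a small region of a larger molecule.  Multilevel ("focused") models treat
that active subsystem A with an expensive, accurate method and the
environment B with a cheap one.  This package implements the
projection-based flavor of that idea for open-shell systems: solve the
supersystem at the low level, partition its occupied orbitals between A
and B, and reoptimize the orbitals of A at the high level in the frozen
potential of B, with the Huzinaga projector

    H = F − F R_B S − S R_B F

keeping the embedded orbitals exactly orthogonal to the frozen environment
orbitals.  The multilevel energy is first-order corrected:

    E_PbE = E_low(AB) − E_low(A) + E_high(Ã) + V_nn
            + Tr{(D̃^A − D^A) ∂E12/∂D^A}

Its defining property — *same-level exactness*: embedding a method in
itself returns the supersystem energy — holds here to ~1e−13 hartree and
anchors the test suite.

Supported spin treatments:

* **UHF/UKS** (spin-unrestricted) embedding with per-spin localization,
  projectors, and Huzinaga operators;
* **ROHF/ROKS** (restricted open-shell, Roothaan-ensemble high-spin
  formalism: f = 1/2, a = 1, b = 2) embedding with closed/open shell
  potentials and a unified embedded Fock operator;
* the mixed schemes **UKS-in-ROKS** and **ROKS-in-UKS**, including
  natural-orbital classification and quasi-restricted orbitals for
  correlation;
* baselines: **vacuum embedding**, **ONIOM-ME**, **ONIOM-EE** with link
  hydrogens at 1.08 Å and IAO/Mulliken point-charge fields;
* **MP2** on the embedded orbitals with the full supersystem virtual
  space.

Because no electronic-structure engine exists on CRAN/Bioconductor, the
package ships a compact native engine: McMurchie–Davidson Gaussian
integrals (s/p shells, H–Ar) in Rcpp, run-time-generated Slater-expansion
minimal and split-valence bases, Becke-grid LDA/PBE/PBE0
exchange–correlation, and canonical MP2.  It is desk-scale by design; the
embedding algebra is the point, and it is written against an engine
contract (`ao_context`) that a full-featured backend could satisfy.

## A worked example

Embed PBE0 in PBE around the radical carbon of the 1-propyl radical
(atoms 3, 9, 10 = CH2• group), restricted open-shell ansatz:

```r
library(huzembed)
mol <- fixture("propyl_radical")      # CH3–CH2–CH2•, doublet, 10 atoms
print(mol)
#> molecule: 10 atoms, charge +0, multiplicity 2, 25 electrons

res <- pbe_roks(mol, xc_low = "pbe", xc_high = "pbe0",
                active_atoms = c(3, 9, 10), grid_level = 1)
print(res)
#> projection-based embedding (roks)
#>   E_low(AB)    =    -192.3807519770
#>   E_low(A)     =     -84.4880133323
#>   E_high(A~)   =     -84.4883724472
#>   correction   =      -0.0138534357
#>   V_nn         =      75.5656873592
#>   E_PbE        =    -116.8292771685
#>   max |C~' S L^B| = 1.38e-14
```

Reading the report: the PBE supersystem contributes −192.3808 hartree of
electronic energy; the PBE energy of the active CH2• fragment's orbitals
(−84.4880) is subtracted and replaced by the PBE0 energy of the same
fragment reoptimized in the frozen PBE environment (−84.4884); the trace
term (−0.0139) makes the result stationary in the low-level density; with
nuclear repulsion the multilevel total is **−116.8293 hartree**, compared
with −116.8643 for full PBE0 — the gap is the environment treated at PBE,
and it shrinks systematically as the active region grows (see below).  The
last line confirms the embedded orbitals are orthogonal to the frozen
environment to machine precision.

The same run from a shell:

```sh
exec/huzembed pbe --xyz propyl.xyz --multiplicity 2 --active 3,9,10 \
    --low pbe --high pbe0 --ansatz roks --grid 1
```

or from a YAML configuration via `run_scheme("config.yaml")`.  Atom
indices are 1-based throughout.

## Package layout

* `R/` — molecule/basis/integral context, Becke grids and functionals,
  UKS and ROKS SCF, partitioning (SPADE, Boys + Mulliken), UKS and ROKS
  Huzinaga embedding, mixed schemes, baselines, MP2, fixtures, config
  drivers.
* `src/` — McMurchie–Davidson integral engine (Rcpp).
* `vignettes/open-shell-embedding.Rmd` — the model, its assumptions,
  numerical choices, and limitations.
* `tests/testthat/` — unit, property, and acceptance suites with
  independent oracles (closed forms, literal transcription scripts,
  quadruple-loop MP2, direct orbital-rotation minimization).
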