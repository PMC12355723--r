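# Pairwise dispersion correction with subsystem partitioning.
#
# A Becke-Johnson-damped -C6/R^6 two-body model over approximate free-atom
# C6 coefficients.  This is a simplified pairwise dispersion model (not
# Grimme's coordination-number-interpolated D3 data); what the multilevel
# machinery relies on is the *partition rule*: a subsystem correction sums
# only pairs whose two atoms both belong to the chosen atom subset, and
# three-body terms are not included.

# approximate free-atom C6 coefficients (hartree bohr^6)
.C6_FREE <- c(H = 6.5, He = 1.46, Li = 1387, Be = 214, B = 99.5, C = 46.6,
              N = 24.2, O = 15.6, F = 9.52, Ne = 6.38, Na = 1556, Mg = 627,
              Al = 528, Si = 305, P = 185, S = 134, Cl = 94.6, Ar = 64.3)

# covalent radii (Angstrom) for the damping radius
.RCOV <- c(H = 0.32, He = 0.46, Li = 1.33, Be = 1.02, B = 0.85, C = 0.75,
           N = 0.71, O = 0.63, F = 0.64, Ne = 0.67, Na = 1.55, Mg = 1.39,
           Al = 1.26, Si = 1.16, P = 1.11, S = 1.03, Cl = 0.99, Ar = 0.96)

#' Pairwise dispersion energy of an atom subset
#'
#' Sums the BJ-damped \eqn{-C_6/R^6} two-body terms over all pairs with
#' both atoms inside `atom_subset`; with the full atom set this is the
#' standard whole-molecule correction.  An empty or single-atom subset
#' contributes zero.
#'
#' @param mol a [molecule()].
#' @param atom_subset 1-based atom indices (default: all atoms).
#' @param s6 global scaling (default 1).
#' @param a1,a2 damping-radius parameters (dimensionless / bohr).
#' @return dispersion energy in hartree (non-positive).
#' @export
dispersion_energy <- function(mol, atom_subset = seq_along(mol$z),
                              s6 = 1.0, a1 = 1.6, a2 = 0.8) {
  atom_subset <- sort(unique(as.integer(atom_subset)))
  if (length(atom_subset) < 2) return(0)
  xyz <- mol$coords[atom_subset, , drop = FALSE] * .BOHR_PER_ANGSTROM
  sym <- mol$symbols[atom_subset]
  c6 <- .C6_FREE[sym]
  rc <- .RCOV[sym] * .BOHR_PER_ANGSTROM
  e <- 0
  for (i in seq_len(length(atom_subset) - 1)) {
    for (j in (i + 1):length(atom_subset)) {
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      c6ij <- sqrt(c6[i] * c6[j])
      r0 <- a1 * (rc[i] + rc[j]) + a2
      e <- e - s6 * c6ij / (r2^3 + r0^6)
    }
  }
  unname(e)
}
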