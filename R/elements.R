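# Element tables for H-Ar: symbols, nuclear charges, Bragg-Slater radii
# (for molecular quadrature cells) and shell-group populations used by the
# Slater screening rules of the basis generator.

.ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
               "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar")

# Bragg-Slater radii in Angstrom (H set to 0.35 as is customary in
# Becke-type quadratures)
.BRAGG_ANGSTROM <- c(0.35, 0.31, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50,
                     0.38, 1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 0.71)

.BOHR_PER_ANGSTROM <- 1.0 / 0.52917721092
.HARTREE_TO_KCAL <- 627.509474

element_number <- function(symbol) {
  z <- match(symbol, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(z)], collapse = ", "),
         " (supported: H-Ar)")
  }
  z
}

# electrons per Slater shell group (1s | 2s2p | 3s3p) in the ground state
shell_populations <- function(z) {
  n1 <- min(z, 2L)
  n2 <- min(max(z - 2L, 0L), 8L)
  n3 <- min(max(z - 10L, 0L), 8L)
  c(n1, n2, n3)
}

# Slater's screening rules for ns/np shell groups; returns zeta per occupied
# shell group.  Hydrogen uses the customary molecular-environment exponent
# 1.24 instead of the free-atom value 1.0.
slater_exponents <- function(z) {
  if (z == 1L) return(c(`1` = 1.24))
  pop <- shell_populations(z)
  zeta <- numeric(0)
  if (pop[1] > 0) {
    s <- 0.30 * (pop[1] - 1)
    zeta <- c(zeta, `1` = (z - s) / 1)
  }
  if (pop[2] > 0) {
    s <- 0.35 * (pop[2] - 1) + 0.85 * pop[1]
    zeta <- c(zeta, `2` = (z - s) / 2)
  }
  if (pop[3] > 0) {
    s <- 0.35 * (pop[3] - 1) + 0.85 * pop[2] + 1.00 * pop[1]
    zeta <- c(zeta, `3` = (z - s) / 3)
  }
  zeta
}
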