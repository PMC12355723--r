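#' Build the AO integral context for a molecule
#'
#' Computes and caches everything the SCF and embedding solvers need for one
#' molecule and basis: the AO overlap `S`, core Hamiltonian `h_core`, nuclear
#' repulsion `V_nn`, the full two-electron integral tensor with fast Coulomb
#' (`J`) and exchange (`K`) contraction closures, per-atom AO ranges, and a
#' lazily constructed molecular quadrature grid shared by every
#' exchange-correlation evaluation on this context (so that subtractive
#' multilevel energies cancel at the grid level).
#'
#' @param mol a [molecule()].
#' @param basis basis-set name, see [build_shells()].
#' @param grid_level quadrature size: 1 (coarse), 2 (default), 3 (fine).
#' @param point_charges optional external field: a list with `xyz`
#'   (k x 3 matrix, Angstrom) and `q` (length-k charges); the electrostatic
#'   interaction with the electrons enters `h_core` and the interaction with
#'   the nuclei enters `V_nn`.
#' @return an object of class `ao_context`.
#' @export
build_context <- function(mol, basis = "min3g", grid_level = 2L,
                          point_charges = NULL) {
  shells <- build_shells(mol, basis)
  xyz <- mol$coords * .BOHR_PER_ANGSTROM
  oe <- cpp_one_electron(shells, xyz, as.numeric(mol$z))
  S <- oe$S
  h <- oe$T - oe$V       # V returned with +Z/r kernel
  vnn <- nuclear_repulsion(mol$z, xyz)
  if (!is.null(point_charges)) {
    cxyz <- as.matrix(point_charges$xyz) * .BOHR_PER_ANGSTROM
    q <- as.numeric(point_charges$q)
    h <- h - cpp_point_charge_ints(shells, cxyz, q)
    for (a in seq_along(mol$z)) {
      vnn <- vnn + sum(mol$z[a] * q /
                         sqrt(rowSums(sweep(cxyz, 2, xyz[a, ])^2)))
    }
  }
  n <- attr(shells, "nao")
  eri <- cpp_eri(shells)
  dim(eri) <- c(n, n, n, n)
  Jmat <- matrix(eri, n * n, n * n)
  Kmat <- matrix(aperm(eri, c(1L, 3L, 2L, 4L)), n * n, n * n)

  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    stop("AO overlap is near-singular (min eigenvalue ",
         format(min(es$values)), ")")
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)

  ctx <- new.env(parent = emptyenv())
  ctx$mol <- mol
  ctx$basis <- basis
  ctx$shells <- shells
  ctx$n_ao <- n
  ctx$S <- S
  ctx$T <- oe$T
  ctx$Vne <- -oe$V
  ctx$h_core <- h
  ctx$V_nn <- vnn
  ctx$X <- X
  ctx$atom_ao_ranges <- attr(shells, "atom_ao_ranges")
  ctx$grid_level <- grid_level
  ctx$eri <- eri
  ctx$.Jmat <- Jmat
  ctx$.Kmat <- Kmat
  ctx$J <- function(D) matrix(Jmat %*% as.vector(D), n, n)
  ctx$K <- function(D) matrix(Kmat %*% as.vector(D), n, n)
  ctx$grid <- NULL       # built on first xc evaluation
  class(ctx) <- "ao_context"
  ctx
}

#' @export
print.ao_context <- function(x, ...) {
  cat(sprintf("ao_context: %d AOs (%s), %d atoms, V_nn = %.8f hartree\n",
              x$n_ao, x$basis, length(x$mol$z), x$V_nn))
  invisible(x)
}

# grid accessor (built once per context)
context_grid <- function(ctx) {
  if (is.null(ctx$grid)) {
    ctx$grid <- becke_grid(ctx$mol, ctx$grid_level)
    ao <- cpp_ao_eval(ctx$shells, ctx$grid$points)
    ctx$grid$ao <- ao$ao
    ctx$grid$aox <- ao$x
    ctx$grid$aoy <- ao$y
    ctx$grid$aoz <- ao$z
  }
  ctx$grid
}

#' Electrostatic potential integrals of external point charges
#'
#' Returns the matrix of \eqn{\sum_k q_k \langle\mu|1/|r-R_k||\nu\rangle}
#' (positive kernel; multiply by -1 for the electron interaction).
#'
#' @param ctx an `ao_context`.
#' @param xyz k x 3 matrix of charge positions in Angstrom.
#' @param q charges.
#' @export
point_charge_matrix <- function(ctx, xyz, q) {
  cpp_point_charge_ints(ctx$shells, as.matrix(xyz) * .BOHR_PER_ANGSTROM,
                        as.numeric(q))
}

# AO dipole integrals about an origin (Angstrom)
dipole_matrices <- function(ctx, origin = c(0, 0, 0)) {
  cpp_dipole(ctx$shells, origin * .BOHR_PER_ANGSTROM)
}

# overlap between the AO bases of two contexts (atoms may differ)
cross_overlap <- function(ctx1, ctx2) {
  cpp_overlap_cross(ctx1$shells, ctx2$shells)
}
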