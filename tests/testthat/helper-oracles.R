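# Independent oracles used across the suite.  These deliberately avoid the
# package's Fock/DIIS machinery: energies are computed from explicit
# orbital sums and minimized directly over orbital-rotation parameters.

# Cayley parameterization of an orthogonal rotation restricted to the
# index pairs in `idx` (rows = (row, col) with row > col)
.oracle_rotate <- function(C0, par, idx, n) {
  A <- matrix(0, n, n)
  A[idx] <- par
  A <- A - t(A)
  # Cayley transform: orthogonal for any antisymmetric A
  Q <- solve(diag(n) - A / 2, diag(n) + A / 2)
  C0 %*% Q
}

# index pairs whose rotations change the energy for occupation groups
# (group id per orbital; rotations within a group are redundant)
.oracle_rot_idx <- function(groups) {
  n <- length(groups)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- groups[idx[, 1]] != groups[idx[, 2]]
  idx[keep, , drop = FALSE]
}

# energy of a single determinant with per-spin occupations taken from the
# leading columns of Ca/Cb: explicit orbital-pair J/K sums
.oracle_det_energy <- function(ctx, Ca, Cb, na, nb) {
  occ <- list(a = Ca[, seq_len(na), drop = FALSE],
              b = Cb[, seq_len(nb), drop = FALSE])
  e <- 0
  for (sp in c("a", "b")) {
    Cm <- occ[[sp]]
    for (i in seq_len(ncol(Cm))) {
      e <- e + drop(t(Cm[, i]) %*% ctx$h_core %*% Cm[, i])
    }
  }
  allC <- cbind(occ$a, occ$b)
  spin <- c(rep("a", na), rep("b", nb))
  m <- ncol(allC)
  for (i in seq_len(m)) {
    Di <- tcrossprod(allC[, i])
    Ji <- ctx$J(Di); Ki <- ctx$K(Di)
    for (j in seq_len(m)) {
      Dj <- tcrossprod(allC[, j])
      e <- e + 0.5 * sum(Dj * Ji)
      if (spin[i] == spin[j]) e <- e - 0.5 * sum(Dj * Ki)
    }
  }
  e + ctx$V_nn
}

# direct-minimization UHF oracle
uhf_oracle <- function(mol, ctx, reltol = 1e-13) {
  nocc <- huzembed:::spin_counts(mol)
  n <- ctx$n_ao
  C0 <- ctx$X
  ga <- c(rep(1, nocc[1]), rep(2, n - nocc[1]))
  gb <- c(rep(1, nocc[2]), rep(2, n - nocc[2]))
  ia <- .oracle_rot_idx(ga); ib <- .oracle_rot_idx(gb)
  en <- function(par) {
    Ca <- .oracle_rotate(C0, par[seq_len(nrow(ia))], ia, n)
    Cb <- .oracle_rotate(C0, par[nrow(ia) + seq_len(nrow(ib))], ib, n)
    .oracle_det_energy(ctx, Ca, Cb, nocc[1], nocc[2])
  }
  p0 <- rep(0, nrow(ia) + nrow(ib))
  o <- stats::optim(p0, en, method = "BFGS",
                    control = list(maxit = 3000, reltol = reltol))
  o <- stats::optim(o$par, en, method = "BFGS",
                    control = list(maxit = 3000, reltol = reltol))
  o$value
}

# direct-minimization ROHF oracle (shared spatial orbitals; closed shells
# doubly occupied, open shells singly occupied with alpha spin)
rohf_oracle <- function(mol, ctx, reltol = 1e-13) {
  nocc <- huzembed:::spin_counts(mol)
  nc <- nocc[["beta"]]; no <- nocc[["alpha"]] - nc
  n <- ctx$n_ao
  C0 <- ctx$X
  groups <- c(rep(1, nc), rep(2, no), rep(3, n - nc - no))
  idx <- .oracle_rot_idx(groups)
  en <- function(par) {
    C <- .oracle_rotate(C0, par, idx, n)
    .oracle_det_energy(ctx, C, C, nc + no, nc)
  }
  o <- stats::optim(rep(0, nrow(idx)), en, method = "BFGS",
                    control = list(maxit = 3000, reltol = reltol))
  o <- stats::optim(o$par, en, method = "BFGS",
                    control = list(maxit = 3000, reltol = reltol))
  o$value
}

# literal quadruple-loop MO two-electron integral (pq|rs)
mo_eri_loop <- function(eri, cp, cq, cr, cs) {
  n <- dim(eri)[1]
  acc <- 0
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (abs(cp[p]) < 1e-14) next
    for (r in seq_len(n)) for (s in seq_len(n)) {
      acc <- acc + cp[p] * cq[q] * cr[r] * cs[s] * eri[p, q, r, s]
    }
  }
  acc
}

# directional finite difference of a scalar function of a matrix argument
fd_directional <- function(f, D, Delta, h = 1e-5) {
  (f(D + h * Delta) - f(D - h * Delta)) / (2 * h)
}

# deterministic random symmetric matrix
rand_sym <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  (M + t(M)) / 2
}
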