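# Canonical MP2 correlation over (semicanonicalized) orbital spaces.
#
# The embedded variants treat the embedded active occupied orbitals together
# with the full supersystem virtual space (every direction S-orthogonal to
# all occupied orbitals, active and environment), per the full-virtual-space
# convention of the multilevel energy.

# S-orthonormal basis of the complement of span(occ) + span(R_env)
.virtual_space <- function(ctx, C_occ, R_env = NULL) {
  n <- ctx$n_ao
  S <- ctx$S
  P <- if (ncol(C_occ)) tcrossprod(C_occ) else matrix(0, n, n)
  if (!is.null(R_env)) P <- P + R_env
  V <- ctx$X - P %*% S %*% ctx$X
  M <- t(V) %*% S %*% V
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- which(es$values > 1e-8)
  V %*% es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), length(keep))
}

# diagonalize F within the span of S-orthonormal C; returns rotated C and
# eigenvalues
.semicanonicalize <- function(C, F) {
  if (!ncol(C)) return(list(C = C, eps = numeric(0)))
  M <- t(C) %*% F %*% C
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  list(C = C %*% es$vectors[, ord, drop = FALSE], eps = es$values[ord])
}

# (ia|jb) block of the MO-transformed two-electron integrals
.ao2mo_ovov <- function(eri, Co1, Cv1, Co2, Cv2) {
  n <- dim(eri)[1]
  no1 <- ncol(Co1); nv1 <- ncol(Cv1); no2 <- ncol(Co2); nv2 <- ncol(Cv2)
  if (no1 * nv1 * no2 * nv2 == 0) {
    return(array(0, c(no1, nv1, no2, nv2)))
  }
  h <- t(Co1) %*% matrix(eri, n, n^3)              # [i, (nu la si)]
  dim(h) <- c(no1, n, n, n)
  h <- aperm(h, c(2, 1, 3, 4))                     # [nu, i, la, si]
  h <- t(Cv1) %*% matrix(h, n, no1 * n * n)        # [a, (i la si)]
  dim(h) <- c(nv1, no1, n, n)
  h <- aperm(h, c(3, 1, 2, 4))                     # [la, a, i, si]
  h <- t(Co2) %*% matrix(h, n, nv1 * no1 * n)      # [j, (a i si)]
  dim(h) <- c(no2, nv1, no1, n)
  h <- aperm(h, c(4, 1, 2, 3))                     # [si, j, a, i]
  h <- t(Cv2) %*% matrix(h, n, no2 * nv1 * no1)    # [b, (j a i)]
  dim(h) <- c(nv2, no2, nv1, no1)
  aperm(h, c(4, 3, 2, 1))                          # [i, a, j, b]
}

# same-spin MP2 pair energy: 1/4 sum |(ia|jb)-(ib|ja)|^2 / D
.mp2_same_spin <- function(g, eo, ev) {
  no <- length(eo); nv <- length(ev)
  if (no < 2 || nv < 2) return(0)
  e <- 0
  for (i in seq_len(no)) for (j in seq_len(no)) {
    if (i == j) next
    den <- outer(eo[i] + eo[j] - ev, ev, `-`)
    gij <- g[i, , j, ]
    tij <- gij - t(gij)           # (ia|jb) - (ib|ja)
    e <- e + 0.25 * sum(tij^2 / den)
  }
  e
}

.mp2_opposite_spin <- function(g, eo1, ev1, eo2, ev2) {
  no1 <- length(eo1); no2 <- length(eo2)
  if (no1 == 0 || no2 == 0 || length(ev1) == 0 || length(ev2) == 0) return(0)
  e <- 0
  for (i in seq_len(no1)) for (j in seq_len(no2)) {
    den <- outer(eo1[i] + eo2[j] - ev1, ev2, `-`)
    e <- e + sum(g[i, , j, ]^2 / den)
  }
  e
}

#' MP2 correlation energy for given occupied spaces
#'
#' Semicanonicalizes the occupied orbitals and the virtual space (the full
#' S-orthogonal complement of all occupied orbitals, including any frozen
#' environment space) against the supplied Fock matrices and evaluates the
#' canonical unrestricted MP2 pair energies.  Environment occupied orbitals
#' are excluded from the correlation treatment.
#'
#' @param ctx `ao_context`.
#' @param occ_a,occ_b S-orthonormal occupied coefficients per spin.
#' @param Fa,Fb Fock matrices defining the orbital energies (for embedded
#'   calculations: the embedded Fock).
#' @param R_env_a,R_env_b optional frozen environment projectors excluded
#'   from both the occupied and the virtual spaces.
#' @param method only `"mp2"`.
#' @return correlation energy in hartree.
#' @export
correlation_energy <- function(ctx, occ_a, occ_b, Fa, Fb,
                               R_env_a = NULL, R_env_b = NULL,
                               method = "mp2") {
  if (!identical(method, "mp2")) stop("unsupported correlation method")
  S <- ctx$S
  for (C in list(occ_a, occ_b)) {
    if (ncol(C) && max(abs(t(C) %*% S %*% C - diag(ncol(C)))) > 1e-6) {
      stop("occupied orbitals are not S-orthonormal")
    }
  }
  if (ncol(occ_a) + ncol(occ_b) == 0) return(0)
  oa <- .semicanonicalize(occ_a, Fa)
  ob <- .semicanonicalize(occ_b, Fb)
  va <- .semicanonicalize(.virtual_space(ctx, occ_a, R_env_a), Fa)
  vb <- .semicanonicalize(.virtual_space(ctx, occ_b, R_env_b), Fb)
  gaa <- .ao2mo_ovov(ctx$eri, oa$C, va$C, oa$C, va$C)
  gbb <- .ao2mo_ovov(ctx$eri, ob$C, vb$C, ob$C, vb$C)
  gab <- .ao2mo_ovov(ctx$eri, oa$C, va$C, ob$C, vb$C)
  .mp2_same_spin(gaa, oa$eps, va$eps) +
    .mp2_same_spin(gbb, ob$eps, vb$eps) +
    .mp2_opposite_spin(gab, oa$eps, va$eps, ob$eps, vb$eps)
}

#' MP2 on a converged unrestricted SCF solution
#'
#' @param scf [solve_uks()] result.
#' @param ctx `ao_context`.
#' @return MP2 correlation energy in hartree.
#' @export
mp2_from_uks <- function(scf, ctx) {
  fk <- build_uks_fock(list(Da = scf$Da, Db = scf$Db), ctx, scf$xc)
  correlation_energy(ctx,
                     scf$Ca[, seq_len(scf$n_occ[1]), drop = FALSE],
                     scf$Cb[, seq_len(scf$n_occ[2]), drop = FALSE],
                     fk$Fa, fk$Fb)
}

# embedded MP2, unrestricted path: embedded active occupieds + full virtual
# space, orbital energies from the embedded Fock
embedded_mp2_uks <- function(emb, part, ctx, xc_high, pot) {
  fk <- build_uks_fock(list(Da = emb$Da, Db = emb$Db), ctx, "hf")
  # correlation orbital energies use the (HF-type) embedded Fock: for a
  # hybrid/DFT high level the MP2 step is defined on its HF-like reference
  Fa <- fk$Fa + pot$Va
  Fb <- fk$Fb + pot$Vb
  correlation_energy(ctx, emb$Ca, emb$Cb, Fa, Fb,
                     part$a$R_env, part$b$R_env)
}

# embedded MP2, restricted open-shell path: per-spin views of the embedded
# shells with the spin-resolved embedded Fock matrices
embedded_mp2_roks <- function(emb, part, ctx, xc_high, pot, ensemble) {
  nc <- part$n_closed_A; no <- part$n_open
  occ_a <- emb$C                                  # closed + open
  occ_b <- emb$C[, seq_len(nc), drop = FALSE]     # closed only
  fk <- build_uks_fock(list(Da = emb$dens$Da, Db = emb$dens$Db), ctx, "hf")
  Fa <- fk$Fa + pot$dE_dDo
  Fb <- fk$Fb + 2 * pot$dE_dDc - pot$dE_dDo
  correlation_energy(ctx, occ_a, occ_b, Fa, Fb, part$R_cB, part$R_cB)
}
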