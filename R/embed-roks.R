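# Restricted open-shell projection-based embedding via the Huzinaga
# equation: embedding potentials for the closed and open shells, the
# embedded unified Fock operator, and its Huzinaga projection.

#' Build the frozen restricted open-shell embedding potential
#'
#' Derivatives of the subtractive composite energy with respect to the
#' active closed- and open-shell densities at the low level.  Because the
#' environment carries no open shells, both share the same Coulomb/exchange
#' core \eqn{\Delta J - \frac{a_{HF,2}}{2}\Delta K} (which also defines the
#' embedded core Hamiltonian), and differ in the xc part:
#' \eqn{\partial E/\partial D^{c,A}} carries the spin-averaged difference
#' potential while \eqn{\partial E/\partial D^{o,A}} carries the
#' alpha-channel difference.
#'
#' @param dens_AB supersystem [shell_densities()] (low level).
#' @param dens_A active-subsystem shell densities from the partition.
#' @param ctx `ao_context`.
#' @param xc_low low-level functional.
#' @return object of class `roks_embedding_potential` with `dE_dDc`,
#'   `dE_dDo`, `h_core_AinB`, `Vxc_emb_c`, `Vxc_emb_o`.
#' @export
build_embedding_potential_roks <- function(dens_AB, dens_A, ctx, xc_low) {
  xc_low <- as_xc_spec(xc_low)
  n <- ctx$n_ao
  dD <- dens_AB$D - dens_A$D
  dJK <- ctx$J(dD)
  if (xc_low$a_hf > 0) dJK <- dJK - 0.5 * xc_low$a_hf * ctx$K(dD)
  z <- matrix(0, n, n)
  dVa <- dVb <- z
  if (!is.null(xc_low$fun)) {
    vAB <- xc_eval(ctx, dens_AB$Da, dens_AB$Db, xc_low)
    vA <- xc_eval(ctx, dens_A$Da, dens_A$Db, xc_low)
    dVa <- vAB$Va - vA$Va
    dVb <- vAB$Vb - vA$Vb
  }
  Vxc_c <- (1 - xc_low$a_hf) * 0.5 * (dVa + dVb)
  Vxc_o <- (1 - xc_low$a_hf) * dVa
  structure(list(
    dE_dDc = dJK + Vxc_c, dE_dDo = dJK + Vxc_o,
    h_core_AinB = ctx$h_core + dJK,
    Vxc_emb_c = Vxc_c, Vxc_emb_o = Vxc_o,
    a_hf_low = xc_low$a_hf), class = "roks_embedding_potential")
}

#' Assemble the embedded unified restricted open-shell Fock operator
#'
#' Shell Fock matrices of the high-level method augmented by the frozen
#' embedding potential, combined into the single symmetric operator
#' \eqn{\tilde F = \tilde F^c - Q_1[\tilde D^o] + \tilde T} with the
#' shell-coupling matrix built from the current embedded shell projectors.
#'
#' @param dens_t current embedded [shell_densities()].
#' @param pot frozen [build_embedding_potential_roks()] result.
#' @param ensemble [build_ensemble()].
#' @param ctx `ao_context`.
#' @param xc_high high-level functional.
#' @return list of class `embedded_ro_fock` with `F_c`, `F_o`, `Q`,
#'   `T`, `gamma`, `F_unified`.
#' @export
build_embedded_unified_fock <- function(dens_t, pot, ensemble, ctx, xc_high) {
  xc_high <- as_xc_spec(xc_high)
  fk <- build_uks_fock(list(Da = dens_t$Da, Db = dens_t$Db), ctx, xc_high)
  F_c <- (fk$Fa + fk$Fb) / 2 + pot$dE_dDc
  F_o <- fk$Fa + pot$dE_dDo
  n <- ctx$n_ao
  if (ensemble$n_open == 0L) {
    z <- matrix(0, n, n)
    return(structure(list(F_c = F_c, F_o = F_o, Q = z, T = z, gamma = z,
                          F_unified = F_c, Exc = fk$Exc),
                     class = "embedded_ro_fock"))
  }
  S <- ctx$S
  f <- ensemble$f; cb <- ensemble$c_bar
  Q <- if (xc_high$a_hf > 0) xc_high$a_hf * ctx$K(dens_t$Do) else
    matrix(0, n, n)
  gamma <- dens_t$Rc %*% S - diag(n) / cb + (cb / 2) * dens_t$Ro %*% S
  G <- F_c - F_o - Q / 2
  T_ <- S %*% dens_t$Rc %*% Q + Q %*% dens_t$Rc %*% S +
    f * (S %*% dens_t$Ro %*% Q + Q %*% dens_t$Ro %*% S) +
    cb * (t(gamma) %*% G %*% dens_t$Ro %*% S + S %*% dens_t$Ro %*% G %*% gamma)
  T_ <- (T_ + t(T_)) / 2
  Fu <- F_c - Q + T_
  Fu <- (Fu + t(Fu)) / 2
  structure(list(F_c = F_c, F_o = F_o, Q = Q, T = T_, gamma = gamma,
                 F_unified = Fu, Exc = fk$Exc), class = "embedded_ro_fock")
}

#' Huzinaga operator of the restricted open-shell embedding
#'
#' \eqn{H = F - F R^{c,B} S - S R^{c,B} F} with the closed-shell environment
#' projector \eqn{R^{c,B} = L^{c,B} (L^{c,B})^T}.
#'
#' @param F_unified_emb embedded unified Fock matrix.
#' @param R_cB environment closed-shell projector.
#' @param S AO overlap.
#' @return symmetric matrix.
#' @export
huzinaga_operator_roks <- function(F_unified_emb, R_cB, S) {
  huzinaga_operator(F_unified_emb, R_cB, S)
}

#' Reoptimize the active subsystem in the frozen environment (ROKS)
#'
#' Iterative diagonalization of the ROKS Huzinaga operator; the lowest
#' environment-orthogonal eigenvectors become the closed shells and the
#' next `n_open` the open shells.
#'
#' @param partition a `roks_partition`.
#' @param pot frozen embedding potential.
#' @param ensemble [build_ensemble()].
#' @param ctx `ao_context`.
#' @param xc_high high-level functional.
#' @param control SCF controls.
#' @return list with `C` (active occupied orbitals, closed then open),
#'   `dens` (embedded shell densities), `converged`,
#'   `orthogonality_residual`, `stationarity`.
#' @export
solve_embedded_roks <- function(partition, pot, ensemble, ctx, xc_high,
                                control = list()) {
  xc_high <- as_xc_spec(xc_high)
  ct <- modifyList(list(max_iter = 150L, e_tol = 1e-9, r_tol = 1e-7,
                        diis_size = 8L, verbose = FALSE), control)
  n <- ctx$n_ao
  S <- ctx$S; X <- ctx$X
  nc <- partition$n_closed_A
  no <- partition$n_open
  R_cB <- partition$R_cB
  # warm start: active closed orbitals + open orbitals
  C <- cbind(partition$closed$L[, partition$closed$active_idx, drop = FALSE],
             partition$L_open)
  dens <- shell_densities(C, nc, no, ensemble)
  diis <- .diis_new(ct$diis_size)
  e_old <- Inf
  converged <- FALSE
  for (it in seq_len(ct$max_iter)) {
    fk <- build_embedded_unified_fock(dens, pot, ensemble, ctx, xc_high)
    H <- huzinaga_operator(fk$F_unified, R_cB, S)
    err <- t(X) %*% (H %*% dens$D %*% S - S %*% dens$D %*% H) %*% X
    resid <- max(abs(err))
    e_elec <- ro_energy(dens, ensemble, ctx, xc_high) +
      sum(pot$dE_dDc * dens$Dc) + sum(pot$dE_dDo * dens$Do)
    if (ct$verbose) {
      message(sprintf("embed-roks iter %3d  E1+emb = %.10f  resid = %.2e",
                      it, e_elec, resid))
    }
    if (abs(e_elec - e_old) < ct$e_tol && resid < ct$r_tol) {
      converged <- TRUE
      break
    }
    e_old <- e_elec
    .diis_push(diis, as.vector(H), as.vector(err))
    H <- matrix(.diis_extrapolate(diis), n, n)
    sol <- .diag_fock(H, X)
    occ <- .select_occupied(sol$C, sol$eps, nc + no, S, R_cB)
    C <- sol$C[, occ, drop = FALSE]
    dens <- shell_densities(C, nc, no, ensemble)
  }
  if (!converged) warning("embedded ROKS SCF did not converge")
  fk <- build_embedded_unified_fock(dens, pot, ensemble, ctx, xc_high)
  stat <- ro_stationarity(
    cbind(C, matrix(0, n, 0)), nc, no,
    list(F_c = fk$F_c, F_o = fk$F_o))
  LcB <- partition$closed$L[, partition$closed$env_idx, drop = FALSE]
  orth <- if (ncol(LcB) && ncol(C)) max(abs(t(C) %*% S %*% LcB)) else 0
  list(C = C, dens = dens, converged = converged, n_iter = it,
       orthogonality_residual = orth, stationarity = stat)
}

#' Assemble the first-order-corrected multilevel energy (ROKS)
#'
#' \eqn{E_{PbE} = E_2[AB] - E_2[A] + E_1[\tilde A] + V_{nn} +
#' Tr\{(\tilde D^{c,A}-D^{c,A})\partial E/\partial D^{c,A}\} +
#' Tr\{(\tilde D^{o,A}-D^{o,A})\partial E/\partial D^{o,A}\}}.
#'
#' @param E_low_AB low-level supersystem electronic energy.
#' @param dens_A low-level active shell densities.
#' @param emb embedded solution from [solve_embedded_roks()].
#' @param pot embedding potential.
#' @param ctx `ao_context`.
#' @param ensemble [build_ensemble()].
#' @param xc_low,xc_high functionals.
#' @param E_cor optional correlation energy.
#' @return `embedding_result`.
#' @export
assemble_energy_roks <- function(E_low_AB, dens_A, emb, pot, ctx, ensemble,
                                 xc_low, xc_high, E_cor = 0) {
  E_low_A <- ro_energy(dens_A, ensemble, ctx, xc_low)
  E_high_A <- ro_energy(emb$dens, ensemble, ctx, xc_high)
  correction <- sum((emb$dens$Dc - dens_A$Dc) * pot$dE_dDc) +
    sum((emb$dens$Do - dens_A$Do) * pot$dE_dDo)
  E_pbe <- E_low_AB - E_low_A + E_high_A + ctx$V_nn + correction
  structure(list(
    E_low_AB = E_low_AB, E_low_A = E_low_A, E_high_A = E_high_A,
    correction = correction, V_nn = ctx$V_nn,
    E_pbe = E_pbe, E_cor = E_cor, E_total = E_pbe + E_cor,
    orthogonality_residual = emb$orthogonality_residual,
    ansatz = "roks"), class = "embedding_result")
}

#' Run the full restricted open-shell Huzinaga embedding workflow
#'
#' @inheritParams pbe_uks
#' @return `embedding_result`.
#' @export
pbe_roks <- function(mol, xc_low, xc_high, active_atoms = mol$active_atoms,
                     ctx = NULL, basis = "min3g", grid_level = 2L,
                     method = "spade", correlation = "none",
                     control = list()) {
  if (!length(active_atoms)) stop("active_atoms must be nonempty")
  if (is.null(ctx)) ctx <- build_context(mol, basis, grid_level)
  ensemble <- build_ensemble(mol$multiplicity)
  low <- solve_ro(mol, ctx, xc_low, ensemble, control = control)
  part <- partition_roks(low, ctx, active_atoms, method = method)
  dens_A <- shell_densities_from_matrices(part$Dc_A, part$Do_A, ensemble$f)
  pot <- build_embedding_potential_roks(low$dens, dens_A, ctx, xc_low)
  emb <- solve_embedded_roks(part, pot, ensemble, ctx, xc_high,
                             control = control)
  E_cor <- 0
  if (identical(correlation, "mp2")) {
    E_cor <- embedded_mp2_roks(emb, part, ctx, xc_high, pot, ensemble)
  }
  res <- assemble_energy_roks(low$E_elec, dens_A, emb, pot, ctx, ensemble,
                              xc_low, xc_high, E_cor)
  res$supersystem <- low
  res$partition <- part
  res$embedded <- emb
  res
}
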