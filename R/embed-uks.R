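# Spin-unrestricted projection-based embedding via the Huzinaga equation.

#' Build the frozen unrestricted embedding potential
#'
#' The derivative of the subtractive composite energy with respect to the
#' active-subsystem spin densities, evaluated at the low level:
#' \eqn{V_{emb}^\sigma = \Delta J - a_{HF,2}\Delta K_\sigma +
#' (1-a_{HF,2})\Delta V_{xc}^\sigma} with
#' \eqn{\Delta X = X[D^{AB}] - X[D^A]}.
#'
#' @param D_AB supersystem spin densities (list `Da`, `Db`).
#' @param D_A active-subsystem spin densities (list `Da`, `Db`).
#' @param ctx `ao_context`.
#' @param xc_low low-level functional.
#' @return object of class `uks_embedding_potential` with `Va`, `Vb` and the
#'   stored components `dJ`, `dKa`, `dKb`, `dVxa`, `dVxb`.
#' @export
build_embedding_potential_uks <- function(D_AB, D_A, ctx, xc_low) {
  xc_low <- as_xc_spec(xc_low)
  n <- ctx$n_ao
  stopifnot(all(dim(D_A$Da) == c(n, n)))
  dJ <- ctx$J(D_AB$Da + D_AB$Db - D_A$Da - D_A$Db)
  z <- matrix(0, n, n)
  dKa <- if (xc_low$a_hf > 0) ctx$K(D_AB$Da - D_A$Da) else z
  dKb <- if (xc_low$a_hf > 0) ctx$K(D_AB$Db - D_A$Db) else z
  dVxa <- dVxb <- z
  if (!is.null(xc_low$fun)) {
    vAB <- xc_eval(ctx, D_AB$Da, D_AB$Db, xc_low)
    vA <- xc_eval(ctx, D_A$Da, D_A$Db, xc_low)
    dVxa <- vAB$Va - vA$Va
    dVxb <- vAB$Vb - vA$Vb
  }
  structure(list(
    Va = dJ - xc_low$a_hf * dKa + (1 - xc_low$a_hf) * dVxa,
    Vb = dJ - xc_low$a_hf * dKb + (1 - xc_low$a_hf) * dVxb,
    dJ = dJ, dKa = dKa, dKb = dKb, dVxa = dVxa, dVxb = dVxb,
    a_hf_low = xc_low$a_hf), class = "uks_embedding_potential")
}

#' The Huzinaga projection operator
#'
#' \eqn{H = F - F R S - S R F}: eigenvalue inversion of the environment
#' subspace that keeps the solutions of the embedded eigenproblem orthogonal
#' to the frozen environment orbitals.
#'
#' @param F symmetric Fock-type matrix.
#' @param R_env environment projector (sum of occupied environment orbital
#'   dyads).
#' @param S AO overlap.
#' @return symmetric matrix.
#' @export
huzinaga_operator <- function(F, R_env, S) {
  H <- F - F %*% R_env %*% S - S %*% R_env %*% F
  (H + t(H)) / 2
}

# occupied selection that skips eigenvectors dominated by the environment
.select_occupied <- function(C, eps, n_occ, S, R_env, guard = 0.5) {
  if (n_occ == 0) return(integer(0))
  ov <- colSums((S %*% R_env %*% S %*% C) * C)
  cand <- which(ov <= guard)
  if (length(cand) < n_occ) {
    stop("electron-count drift: embedded SCF tried to occupy an ",
         "environment-spanned eigenvector")
  }
  cand[seq_len(n_occ)]
}

#' Reoptimize the active subsystem in the frozen environment (UKS)
#'
#' SCF on the spin-dependent Huzinaga operator
#' \eqn{\tilde H^\sigma = \tilde F^\sigma - \tilde F^\sigma R^{\sigma,B} S -
#' S R^{\sigma,B} \tilde F^\sigma}, with
#' \eqn{\tilde F^\sigma = F_1^\sigma[\tilde D^A] + V_{emb}^\sigma}.
#'
#' @param partition a `uks_partition` from the low-level supersystem.
#' @param pot frozen [build_embedding_potential_uks()] result.
#' @param ctx `ao_context`.
#' @param xc_high high-level functional.
#' @param control SCF controls as in [solve_uks()].
#' @return list with `Ca`, `Cb` (embedded orbitals), `Da`, `Db`, `eps_a`,
#'   `eps_b`, `n_occ`, `converged`, `orthogonality_residual`.
#' @export
solve_embedded_uks <- function(partition, pot, ctx, xc_high,
                               control = list()) {
  xc_high <- as_xc_spec(xc_high)
  ct <- modifyList(list(max_iter = 150L, e_tol = 1e-9, r_tol = 1e-7,
                        diis_size = 8L, verbose = FALSE), control)
  n <- ctx$n_ao
  S <- ctx$S; X <- ctx$X
  nA <- c(length(partition$a$active_idx), length(partition$b$active_idx))
  Renv <- list(a = partition$a$R_env, b = partition$b$R_env)
  # warm start from the low-level active orbitals
  Ca <- partition$a$L[, partition$a$active_idx, drop = FALSE]
  Cb <- partition$b$L[, partition$b$active_idx, drop = FALSE]
  dens <- list(Da = tcrossprod(Ca), Db = tcrossprod(Cb))
  diis <- .diis_new(ct$diis_size)
  e_old <- Inf
  converged <- FALSE
  eps_a <- eps_b <- NULL
  for (it in seq_len(ct$max_iter)) {
    fk <- build_uks_fock(dens, ctx, xc_high)
    Fta <- fk$Fa + pot$Va
    Ftb <- fk$Fb + pot$Vb
    Ha <- huzinaga_operator(Fta, Renv$a, S)
    Hb <- huzinaga_operator(Ftb, Renv$b, S)
    erra <- t(X) %*% (Ha %*% dens$Da %*% S - S %*% dens$Da %*% Ha) %*% X
    errb <- t(X) %*% (Hb %*% dens$Db %*% S - S %*% dens$Db %*% Hb) %*% X
    resid <- max(abs(erra), abs(errb))
    e_elec <- uks_energy(dens, ctx, xc_high) +
      sum(pot$Va * dens$Da) + sum(pot$Vb * dens$Db)
    if (ct$verbose) {
      message(sprintf("embed-uks iter %3d  E1+emb = %.10f  resid = %.2e",
                      it, e_elec, resid))
    }
    if (abs(e_elec - e_old) < ct$e_tol && resid < ct$r_tol) {
      converged <- TRUE
      break
    }
    e_old <- e_elec
    .diis_push(diis, c(as.vector(Ha), as.vector(Hb)),
               c(as.vector(erra), as.vector(errb)))
    Hvec <- .diis_extrapolate(diis)
    Ha <- matrix(Hvec[seq_len(n * n)], n, n)
    Hb <- matrix(Hvec[n * n + seq_len(n * n)], n, n)
    sa <- .diag_fock(Ha, X); sb <- .diag_fock(Hb, X)
    ia <- .select_occupied(sa$C, sa$eps, nA[1], S, Renv$a)
    ib <- .select_occupied(sb$C, sb$eps, nA[2], S, Renv$b)
    Ca <- sa$C[, ia, drop = FALSE]; eps_a <- sa$eps
    Cb <- sb$C[, ib, drop = FALSE]; eps_b <- sb$eps
    dens <- list(Da = tcrossprod(Ca), Db = tcrossprod(Cb))
  }
  if (!converged) warning("embedded UKS SCF did not converge")
  LenvA <- partition$a$L[, partition$a$env_idx, drop = FALSE]
  LenvB <- partition$b$L[, partition$b$env_idx, drop = FALSE]
  orth <- max(0,
              if (ncol(LenvA) && ncol(Ca)) abs(t(Ca) %*% S %*% LenvA) else 0,
              if (ncol(LenvB) && ncol(Cb)) abs(t(Cb) %*% S %*% LenvB) else 0)
  list(Ca = Ca, Cb = Cb, Da = dens$Da, Db = dens$Db,
       eps_a = eps_a, eps_b = eps_b, n_occ = nA,
       converged = converged, n_iter = it,
       orthogonality_residual = orth)
}

#' Assemble the first-order-corrected multilevel energy (UKS)
#'
#' \eqn{E_{PbE} = E_2[AB] - E_2[A] + E_1[\tilde A] + V_{nn} +
#' \sum_\sigma Tr\{(\tilde D^{\sigma,A} - D^{\sigma,A}) V_{emb}^\sigma\}},
#' optionally followed by a correlation term.
#'
#' @param E_low_AB low-level supersystem electronic energy.
#' @param D_A low-level active spin densities (list `Da`, `Db`).
#' @param emb embedded solution from [solve_embedded_uks()].
#' @param pot embedding potential.
#' @param ctx `ao_context`.
#' @param xc_low,xc_high functionals.
#' @param E_cor optional correlation energy (hartree).
#' @return object of class `embedding_result`.
#' @export
assemble_energy_uks <- function(E_low_AB, D_A, emb, pot, ctx,
                                xc_low, xc_high, E_cor = 0) {
  E_low_A <- uks_energy(D_A, ctx, xc_low)
  E_high_A <- uks_energy(list(Da = emb$Da, Db = emb$Db), ctx, xc_high)
  correction <- sum((emb$Da - D_A$Da) * pot$Va) +
    sum((emb$Db - D_A$Db) * pot$Vb)
  E_pbe <- E_low_AB - E_low_A + E_high_A + ctx$V_nn + correction
  structure(list(
    E_low_AB = E_low_AB, E_low_A = E_low_A, E_high_A = E_high_A,
    correction = correction, V_nn = ctx$V_nn,
    E_pbe = E_pbe, E_cor = E_cor, E_total = E_pbe + E_cor,
    orthogonality_residual = emb$orthogonality_residual,
    ansatz = "uks"), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("projection-based embedding (%s)\n", x$ansatz))
  cat(sprintf("  E_low(AB)    = %18.10f\n", x$E_low_AB))
  cat(sprintf("  E_low(A)     = %18.10f\n", x$E_low_A))
  cat(sprintf("  E_high(A~)   = %18.10f\n", x$E_high_A))
  cat(sprintf("  correction   = %18.10f\n", x$correction))
  cat(sprintf("  V_nn         = %18.10f\n", x$V_nn))
  cat(sprintf("  E_PbE        = %18.10f\n", x$E_pbe))
  if (abs(x$E_cor) > 0) {
    cat(sprintf("  E_cor        = %18.10f\n", x$E_cor))
    cat(sprintf("  E_total      = %18.10f\n", x$E_total))
  }
  cat(sprintf("  max |C~' S L^B| = %.2e\n", x$orthogonality_residual))
  invisible(x)
}

#' Run the full unrestricted Huzinaga embedding workflow
#'
#' Low-level supersystem SCF, per-spin localization and partitioning,
#' frozen embedding potential, embedded high-level SCF, and energy
#' assembly; optionally MP2 on the embedded orbitals.
#'
#' @param mol a [molecule()] with a nonempty `active_atoms` set (or pass
#'   `active_atoms`).
#' @param ctx optional prebuilt `ao_context`.
#' @param xc_low,xc_high functionals.
#' @param active_atoms 1-based active atoms (defaults to `mol$active_atoms`).
#' @param basis,grid_level used when `ctx` is NULL.
#' @param method partition method, `"spade"` (default) or `"mulliken"`.
#' @param correlation `"none"` or `"mp2"` (applied on top of `xc_high`).
#' @param control SCF controls.
#' @return `embedding_result`.
#' @export
pbe_uks <- function(mol, xc_low, xc_high, active_atoms = mol$active_atoms,
                    ctx = NULL, basis = "min3g", grid_level = 2L,
                    method = "spade", correlation = "none",
                    control = list()) {
  if (!length(active_atoms)) stop("active_atoms must be nonempty")
  if (is.null(ctx)) ctx <- build_context(mol, basis, grid_level)
  low <- solve_uks(mol, ctx, xc_low, control = control)
  part <- partition_uks(low, ctx, active_atoms, method = method)
  D_AB <- list(Da = low$Da, Db = low$Db)
  D_A <- list(Da = part$a$D_active, Db = part$b$D_active)
  pot <- build_embedding_potential_uks(D_AB, D_A, ctx, xc_low)
  emb <- solve_embedded_uks(part, pot, ctx, xc_high, control = control)
  E_cor <- 0
  if (identical(correlation, "mp2")) {
    E_cor <- embedded_mp2_uks(emb, part, ctx, xc_high, pot)
  }
  res <- assemble_energy_uks(low$E_elec, D_A, emb, pot, ctx,
                             xc_low, xc_high, E_cor)
  res$supersystem <- low
  res$partition <- part
  res$embedded <- emb
  res
}
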