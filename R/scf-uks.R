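# Spin-unrestricted HF/KS self-consistent field.

#' Assemble the spin-unrestricted Fock matrices
#'
#' \eqn{F_\sigma = h_{core} + J[D_\alpha+D_\beta] - a_{HF} K[D_\sigma]
#' + (1-a_{HF}) V_{xc,\sigma}}.
#'
#' @param dens list with symmetric `Da`, `Db`.
#' @param ctx an `ao_context`.
#' @param xc an [xc_spec()] or functional name.
#' @return list with `Fa`, `Fb`, `Exc` (the (1-a_HF)-weighted xc energy).
#' @export
build_uks_fock <- function(dens, ctx, xc) {
  xc <- as_xc_spec(xc)
  D <- dens$Da + dens$Db
  Jm <- ctx$J(D)
  Fa <- ctx$h_core + Jm
  Fb <- ctx$h_core + Jm
  if (xc$a_hf > 0) {
    Fa <- Fa - xc$a_hf * ctx$K(dens$Da)
    Fb <- Fb - xc$a_hf * ctx$K(dens$Db)
  }
  Exc <- 0
  if (!is.null(xc$fun)) {
    v <- xc_eval(ctx, dens$Da, dens$Db, xc)
    Fa <- Fa + (1 - xc$a_hf) * v$Va
    Fb <- Fb + (1 - xc$a_hf) * v$Vb
    Exc <- (1 - xc$a_hf) * v$E
  }
  list(Fa = Fa, Fb = Fb, Exc = Exc)
}

#' Spin-unrestricted electronic energy
#'
#' The electronic energy (nuclear repulsion is added separately by the
#' drivers): one-electron + Coulomb + scaled exact exchange +
#' (1-a_HF)-weighted xc.
#'
#' @inheritParams build_uks_fock
#' @return energy in hartree.
#' @export
uks_energy <- function(dens, ctx, xc) {
  xc <- as_xc_spec(xc)
  D <- dens$Da + dens$Db
  e <- sum(ctx$h_core * D) + 0.5 * sum(D * ctx$J(D))
  if (xc$a_hf > 0) {
    e <- e - 0.5 * xc$a_hf * (sum(dens$Da * ctx$K(dens$Da)) +
                              sum(dens$Db * ctx$K(dens$Db)))
  }
  if (!is.null(xc$fun)) {
    e <- e + (1 - xc$a_hf) * xc_eval(ctx, dens$Da, dens$Db, xc)$E
  }
  e
}

# density from occupied coefficients
density_from_C <- function(C, nocc) {
  if (nocc == 0) return(matrix(0, nrow(C), nrow(C)))
  tcrossprod(C[, seq_len(nocc), drop = FALSE])
}

# DIIS extrapolation helper (shared by all solvers)
.diis_new <- function(size = 8L) {
  env <- new.env(parent = emptyenv())
  env$F <- list(); env$E <- list(); env$size <- size
  env
}

.diis_push <- function(d, Fvec, Evec) {
  d$F[[length(d$F) + 1L]] <- Fvec
  d$E[[length(d$E) + 1L]] <- Evec
  if (length(d$F) > d$size) {
    d$F <- d$F[-1L]; d$E <- d$E[-1L]
  }
}

.diis_extrapolate <- function(d) {
  m <- length(d$F)
  if (m < 2) return(d$F[[m]])
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in i:m) {
    B[i, j] <- B[j, i] <- sum(d$E[[i]] * d$E[[j]])
  }
  B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
  rhs <- c(numeric(m), -1)
  coef <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(coef) || any(!is.finite(coef))) return(d$F[[m]])
  Reduce(`+`, Map(`*`, d$F, coef))
}

# superposition-of-atomic-densities guess (spin-averaged atomic UHF blocks)
.sad_cache <- new.env(parent = emptyenv())

.sad_guess <- function(mol, ctx) {
  n <- ctx$n_ao
  D <- matrix(0, n, n)
  for (ia in seq_along(mol$z)) {
    z <- mol$z[ia]
    key <- sprintf("z%d_%s", z, ctx$basis)
    Datom <- .sad_cache[[key]]
    if (is.null(Datom)) {
      sym <- .ELEMENTS[z]
      # Hund ground-state unpaired count for the valence s/p shell
      pop <- shell_populations(z)
      val <- pop[max(which(pop > 0))]
      unpaired <- switch(as.character(val),
                         "1" = 1L, "2" = 0L, "3" = 1L, "4" = 2L, "5" = 3L,
                         "6" = 2L, "7" = 1L, "8" = 0L, 0L)
      atom <- molecule(sym, matrix(0, 1, 3), charge = 0L,
                       multiplicity = unpaired + 1L)
      actx <- build_context(atom, ctx$basis)
      res <- solve_uks(atom, actx, "hf", guess = "core",
                       control = list(max_iter = 80, e_tol = 1e-8))
      Datom <- (res$Da + res$Db) / 2
      .sad_cache[[key]] <- Datom
    }
    idx <- ctx$atom_ao_ranges[[ia]]
    D[idx, idx] <- D[idx, idx] + Datom
  }
  list(Da = D / 2, Db = D / 2)
}

# generalized-eigenproblem diagonalization in the orthonormal basis
.diag_fock <- function(F, X) {
  Fo <- t(X) %*% F %*% X
  Fo <- (Fo + t(Fo)) / 2
  es <- eigen(Fo, symmetric = TRUE)
  ord <- order(es$values)
  list(C = X %*% es$vectors[, ord, drop = FALSE], eps = es$values[ord])
}

#' Solve the spin-unrestricted SCF equations
#'
#' Conventional UHF/UKS with DIIS acceleration on the commutator residual
#' \eqn{[F, D]_S} per spin and aufbau occupation.
#'
#' @param mol a [molecule()].
#' @param ctx matching `ao_context`.
#' @param xc functional ([xc_spec()] or name).
#' @param guess `"sad"` (superposition of atomic densities), `"core"`, or a
#'   list with `Da`, `Db`.
#' @param control list: `max_iter` (150), `e_tol` (1e-9), `r_tol` (1e-7),
#'   `diis_size` (8), `level_shift` (0), `verbose` (FALSE).
#' @return object of class `uks_result`.
#' @export
solve_uks <- function(mol, ctx, xc, guess = "sad", control = list()) {
  xc <- as_xc_spec(xc)
  ct <- modifyList(list(max_iter = 150L, e_tol = 1e-9, r_tol = 1e-7,
                        diis_size = 8L, level_shift = 0, verbose = FALSE),
                   control)
  nocc <- spin_counts(mol)
  n <- ctx$n_ao
  if (any(nocc > n)) stop("more electrons than basis functions")
  S <- ctx$S; X <- ctx$X

  dens <- if (is.list(guess)) {
    guess
  } else if (identical(guess, "core")) {
    sol <- .diag_fock(ctx$h_core, X)
    list(Da = density_from_C(sol$C, nocc[1]), Db = density_from_C(sol$C, nocc[2]))
  } else {
    .sad_guess(mol, ctx)
  }

  diis <- .diis_new(ct$diis_size)
  e_old <- Inf
  converged <- FALSE
  Ca <- Cb <- NULL; eps_a <- eps_b <- NULL
  for (it in seq_len(ct$max_iter)) {
    fk <- build_uks_fock(dens, ctx, xc)
    e_elec <- uks_energy(dens, ctx, xc)
    erra <- t(X) %*% (fk$Fa %*% dens$Da %*% S - S %*% dens$Da %*% fk$Fa) %*% X
    errb <- t(X) %*% (fk$Fb %*% dens$Db %*% S - S %*% dens$Db %*% fk$Fb) %*% X
    resid <- max(abs(erra), abs(errb))
    if (ct$verbose) {
      message(sprintf("uks iter %3d  E = %.10f  |[F,D]| = %.2e  dE = %.2e",
                      it, e_elec + ctx$V_nn, resid, e_elec - e_old))
    }
    if (abs(e_elec - e_old) < ct$e_tol && resid < ct$r_tol) {
      converged <- TRUE
      e_old <- e_elec
      break
    }
    e_old <- e_elec
    .diis_push(diis, c(as.vector(fk$Fa), as.vector(fk$Fb)),
               c(as.vector(erra), as.vector(errb)))
    Fvec <- .diis_extrapolate(diis)
    Fa <- matrix(Fvec[seq_len(n * n)], n, n)
    Fb <- matrix(Fvec[n * n + seq_len(n * n)], n, n)
    if (ct$level_shift > 0) {
      Fa <- Fa + ct$level_shift * (S - S %*% dens$Da %*% S)
      Fb <- Fb + ct$level_shift * (S - S %*% dens$Db %*% S)
    }
    sa <- .diag_fock(Fa, X); sb <- .diag_fock(Fb, X)
    Ca <- sa$C; Cb <- sb$C; eps_a <- sa$eps; eps_b <- sb$eps
    dens <- list(Da = density_from_C(Ca, nocc[1]),
                 Db = density_from_C(Cb, nocc[2]))
  }
  # the reported orbitals are those that generated the final density, so
  # orbitals, densities, and energy are mutually consistent
  if (is.null(Ca)) {
    fk <- build_uks_fock(dens, ctx, xc)
    sa <- .diag_fock(fk$Fa, X); sb <- .diag_fock(fk$Fb, X)
    Ca <- sa$C; Cb <- sb$C; eps_a <- sa$eps; eps_b <- sb$eps
    dens <- list(Da = density_from_C(Ca, nocc[1]),
                 Db = density_from_C(Cb, nocc[2]))
    e_old <- uks_energy(dens, ctx, xc)
  }
  res <- structure(list(
    energy = e_old + ctx$V_nn, E_elec = e_old,
    Ca = Ca, Cb = Cb, eps_a = eps_a, eps_b = eps_b,
    n_occ = nocc, Da = dens$Da, Db = dens$Db,
    converged = converged, n_iter = it, xc = xc$name), class = "uks_result")
  res$s_squared <- s_squared_uhf(res, ctx$S)
  if (!converged) {
    warning("UKS SCF did not converge in ", ct$max_iter, " iterations")
  }
  res
}

#' @export
print.uks_result <- function(x, ...) {
  cat(sprintf("UKS/%s  E = %.10f hartree  (%s in %d iter)  <S^2> = %.6f\n",
              toupper(x$xc), x$energy,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$s_squared))
  invisible(x)
}

#' Spin expectation value of an unrestricted determinant
#'
#' \eqn{\langle S^2\rangle = S_z(S_z+1) + n_\beta -
#' \sum_{ij} |\langle\phi_i^\alpha|\phi_j^\beta\rangle|^2}.
#'
#' @param result a `uks_result` (or list with `Ca`, `Cb`, `n_occ`).
#' @param S AO overlap matrix.
#' @return the \eqn{\langle S^2 \rangle} value.
#' @export
s_squared_uhf <- function(result, S) {
  na <- unname(result$n_occ[1]); nb <- unname(result$n_occ[2])
  sz <- (na - nb) / 2
  if (nb == 0) return(sz * (sz + 1))
  ov <- t(result$Ca[, seq_len(na), drop = FALSE]) %*% S %*%
    result$Cb[, seq_len(nb), drop = FALSE]
  sz * (sz + 1) + nb - sum(ov^2)
}
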