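# Mixed restricted/unrestricted embedding schemes and natural-orbital
# machinery (UKS-in-ROKS, ROKS-in-UKS, quasi-restricted orbitals).

#' Natural orbitals of a density matrix
#'
#' Diagonalizes the total density in the S-metric:
#' eigenvectors of \eqn{S^{1/2} D S^{1/2}} back-transformed with
#' \eqn{S^{-1/2}}, ordered by descending occupation.
#'
#' @param D total (spin-summed) density matrix.
#' @param ctx `ao_context`.
#' @return list with `coefficients` (S-orthonormal) and `occupations`.
#' @export
natural_orbitals <- function(D, ctx) {
  Shalf <- ctx$S %*% ctx$X       # S^(1/2)
  M <- t(Shalf) %*% D %*% Shalf
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  list(coefficients = ctx$X %*% es$vectors[, ord, drop = FALSE],
       occupations = es$values[ord])
}

#' Quasi-restricted orbitals from an unrestricted solution
#'
#' Builds a spatially restricted, S-orthonormal orbital set spanning the
#' unrestricted occupied space by diagonalizing the spin-averaged density
#' \eqn{(D^\alpha + D^\beta)/2}, and classifies the orbitals as doubly
#' occupied, singly occupied, or virtual by occupation order.
#'
#' @param uks_result converged [solve_uks()] result.
#' @param ctx `ao_context`.
#' @return object of class `natural_orbital_set`: `coefficients`,
#'   `occupations` (of the total density, in `[0, 2]`), `classification`.
#' @export
quasi_restricted_orbitals <- function(uks_result, ctx) {
  no <- natural_orbitals(uks_result$Da + uks_result$Db, ctx)
  na <- unname(uks_result$n_occ[1]); nb <- unname(uks_result$n_occ[2])
  n_closed <- nb; n_open <- na - nb
  nmo <- length(no$occupations)
  cls <- c(rep("doubly", n_closed), rep("singly", n_open),
           rep("virtual", nmo - n_closed - n_open))
  if (n_open > 0 && n_closed > 0) {
    gap <- no$occupations[n_closed] - no$occupations[n_closed + 1]
    if (gap < 0.05) {
      warning("ambiguous doubly/singly occupation split (gap ",
              format(gap, digits = 3), "); proceeding by count")
    }
  }
  structure(list(coefficients = no$coefficients,
                 occupations = no$occupations,
                 classification = cls,
                 n_closed = n_closed, n_open = n_open),
            class = "natural_orbital_set")
}

#' UKS-in-ROKS embedding
#'
#' Restricted open-shell supersystem SCF; the restricted orbitals define
#' per-spin views whose unrestricted energy is the low-level supersystem
#' energy, and the standard unrestricted embedding steps (per-spin
#' localization, frozen potential, Huzinaga reoptimization) follow.
#'
#' @inheritParams pbe_uks
#' @return `embedding_result` (ansatz `"uks-in-roks"`).
#' @export
uks_in_roks <- function(mol, xc_low, xc_high,
                        active_atoms = mol$active_atoms,
                        ctx = NULL, basis = "min3g", grid_level = 2L,
                        method = "spade", correlation = "none",
                        control = list()) {
  if (!length(active_atoms)) stop("active_atoms must be nonempty")
  if (is.null(ctx)) ctx <- build_context(mol, basis, grid_level)
  ensemble <- build_ensemble(mol$multiplicity)
  low <- tryCatch(solve_ro(mol, ctx, xc_low, ensemble, control = control),
                  warning = function(w) {
                    stop("RO supersystem SCF failed (", conditionMessage(w),
                         "); consider roks_in_uks()", call. = FALSE)
                  })
  # unrestricted view of the restricted solution
  nocc <- spin_counts(mol)
  uks_view <- list(Ca = low$C, Cb = low$C, n_occ = nocc,
                   Da = low$dens$Da, Db = low$dens$Db)
  E_low_AB <- uks_energy(list(Da = low$dens$Da, Db = low$dens$Db), ctx, xc_low)
  part <- partition_uks(uks_view, ctx, active_atoms, method = method)
  D_AB <- list(Da = low$dens$Da, Db = low$dens$Db)
  D_A <- list(Da = part$a$D_active, Db = part$b$D_active)
  pot <- build_embedding_potential_uks(D_AB, D_A, ctx, xc_low)
  emb <- solve_embedded_uks(part, pot, ctx, xc_high, control = control)
  E_cor <- 0
  if (identical(correlation, "mp2")) {
    E_cor <- embedded_mp2_uks(emb, part, ctx, xc_high, pot)
  }
  res <- assemble_energy_uks(E_low_AB, D_A, emb, pot, ctx,
                             xc_low, xc_high, E_cor)
  res$ansatz <- "uks-in-roks"
  res$supersystem <- low
  res$partition <- part
  res$embedded <- emb
  res
}

#' ROKS-in-UKS embedding
#'
#' Unrestricted supersystem SCF; natural orbitals of the total density are
#' classified into doubly/singly occupied sets, reconstructed into
#' restricted shell densities, and the restricted open-shell embedding
#' machinery proceeds from there.  The supersystem energy entering the
#' subtraction is the true unrestricted low-level energy.
#'
#' @inheritParams pbe_uks
#' @return `embedding_result` (ansatz `"roks-in-uks"`).
#' @export
roks_in_uks <- function(mol, xc_low, xc_high,
                        active_atoms = mol$active_atoms,
                        ctx = NULL, basis = "min3g", grid_level = 2L,
                        method = "spade", correlation = "none",
                        control = list()) {
  if (!length(active_atoms)) stop("active_atoms must be nonempty")
  if (is.null(ctx)) ctx <- build_context(mol, basis, grid_level)
  ensemble <- build_ensemble(mol$multiplicity)
  low <- solve_uks(mol, ctx, xc_low, control = control)
  qro <- quasi_restricted_orbitals(low, ctx)
  nc <- qro$n_closed; no_ <- qro$n_open
  C_rest <- qro$coefficients
  # restricted shell densities with exact 2/1/0 occupations
  ro_like <- list(C = C_rest, n_closed = nc, n_open = no_,
                  dens = shell_densities(C_rest, nc, no_, ensemble))
  part <- partition_roks(ro_like, ctx, active_atoms, method = method)
  dens_A <- shell_densities_from_matrices(part$Dc_A, part$Do_A, ensemble$f)
  dens_AB <- ro_like$dens
  pot <- build_embedding_potential_roks(dens_AB, dens_A, ctx, xc_low)
  emb <- solve_embedded_roks(part, pot, ensemble, ctx, xc_high,
                             control = control)
  E_cor <- 0
  if (identical(correlation, "mp2")) {
    E_cor <- embedded_mp2_roks(emb, part, ctx, xc_high, pot, ensemble)
  }
  res <- assemble_energy_roks(low$E_elec, dens_A, emb, pot, ctx, ensemble,
                              xc_low, xc_high, E_cor)
  res$ansatz <- "roks-in-uks"
  res$supersystem <- low
  res$natural_occupations <- qro$occupations
  res$partition <- part
  res$embedded <- emb
  res
}

#' Dispatch an embedding calculation by ansatz pair
#'
#' @param mol a [molecule()].
#' @param ansatz_low,ansatz_high `"uks"` or `"roks"`.
#' @param ... forwarded to the scheme drivers.
#' @return `embedding_result`.
#' @export
pbe_embedding <- function(mol, ansatz_low = "uks", ansatz_high = "uks", ...) {
  key <- paste(ansatz_high, ansatz_low, sep = "-in-")
  switch(key,
         "uks-in-uks" = pbe_uks(mol, ...),
         "roks-in-roks" = pbe_roks(mol, ...),
         "uks-in-roks" = uks_in_roks(mol, ...),
         "roks-in-uks" = roks_in_uks(mol, ...),
         stop("unknown ansatz combination: ", key))
}
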