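# Competing focused models: vacuum embedding and subtractive ONIOM with
# mechanical or electronic (point-charge) embedding, including link-atom
# capping and charge-field construction.

#' Cap an active subsystem with link hydrogen atoms
#'
#' Each border pair (active atom, environment atom) is replaced by a link
#' hydrogen placed on the segment from the active atom toward the
#' environment atom, 1.08 Angstrom away from the active atom.
#'
#' @param mol parent [molecule()].
#' @param active_atoms 1-based active atom indices.
#' @param border_pairs two-column matrix (or list of length-2 vectors):
#'   first entry active atom, second environment atom of each cut bond.
#' @param charge,multiplicity of the model system; by default the model
#'   inherits the parent multiplicity (the radical is assumed to sit in the
#'   active region) and neutral charge.
#' @param link_distance link bond length in Angstrom (1.08).
#' @return object of class `model_system`: `model` (a molecule of the
#'   active atoms plus link hydrogens), `parent`, `border_pairs`,
#'   `link_positions`.
#' @export
cap_with_link_atoms <- function(mol, active_atoms, border_pairs = NULL,
                                charge = 0L, multiplicity = mol$multiplicity,
                                link_distance = 1.08) {
  active_atoms <- sort(unique(as.integer(active_atoms)))
  if (is.list(border_pairs)) border_pairs <- do.call(rbind, border_pairs)
  if (is.null(border_pairs)) border_pairs <- matrix(0L, 0, 2)
  link_pos <- matrix(0, nrow(border_pairs), 3)
  if (nrow(border_pairs)) {
    for (k in seq_len(nrow(border_pairs))) {
      a <- border_pairs[k, 1]; b <- border_pairs[k, 2]
      if (!(a %in% active_atoms) || (b %in% active_atoms)) {
        stop("border pair ", k, " must link one active atom to one ",
             "environment atom")
      }
      d <- mol$coords[b, ] - mol$coords[a, ]
      link_pos[k, ] <- mol$coords[a, ] + link_distance * d / sqrt(sum(d^2))
    }
  }
  symbols <- c(mol$symbols[active_atoms], rep("H", nrow(border_pairs)))
  coords <- rbind(mol$coords[active_atoms, , drop = FALSE], link_pos)
  model <- molecule(symbols, coords, charge = charge,
                    multiplicity = multiplicity)
  structure(list(model = model, parent = mol,
                 active_atoms = active_atoms,
                 border_pairs = border_pairs, link_positions = link_pos),
            class = "model_system")
}

# dispatch a single-point energy for a method spec
.method_energy <- function(mol, method, basis, grid_level,
                           point_charges = NULL, control = list()) {
  if (is.character(method)) method <- list(xc = method)
  method <- modifyList(list(xc = "hf", ansatz = "uks", correlation = "none"),
                       method)
  ctx <- build_context(mol, basis, grid_level, point_charges = point_charges)
  res <- if (identical(method$ansatz, "roks")) {
    solve_ro(mol, ctx, method$xc, control = control)
  } else {
    solve_uks(mol, ctx, method$xc, control = control)
  }
  e <- res$energy
  if (identical(method$correlation, "mp2")) {
    e <- e + if (identical(method$ansatz, "roks")) {
      fk <- build_uks_fock(list(Da = res$dens$Da, Db = res$dens$Db), ctx, "hf")
      nc <- res$n_closed; no <- res$n_open
      correlation_energy(ctx, res$C[, seq_len(nc + no), drop = FALSE],
                         res$C[, seq_len(nc), drop = FALSE], fk$Fa, fk$Fb)
    } else {
      mp2_from_uks(res, ctx)
    }
  }
  list(energy = e, scf = res, ctx = ctx)
}

#' Vacuum-embedding energy of a capped model system
#'
#' The high-level energy of the hydrogen-saturated active subsystem alone.
#'
#' @param model a [cap_with_link_atoms()] result (or a `molecule`).
#' @param method_high method spec: functional name or list with `xc`,
#'   `ansatz`, `correlation`.
#' @param basis,grid_level engine settings.
#' @param control SCF controls.
#' @return energy in hartree.
#' @export
vacuum_embedding_energy <- function(model, method_high, basis = "min3g",
                                    grid_level = 2L, control = list()) {
  mol <- if (inherits(model, "model_system")) model$model else model
  .method_energy(mol, method_high, basis, grid_level,
                 control = control)$energy
}

#' ONIOM with mechanical embedding
#'
#' \eqn{E = E_{low}(AB) - E_{low}(model) + E_{high}(model)}.
#'
#' @param mol parent molecule.
#' @param model a `model_system`.
#' @param method_high,method_low method specs (see
#'   [vacuum_embedding_energy()]).
#' @param basis,grid_level engine settings.
#' @param control SCF controls.
#' @return list with `energy` and the three components.
#' @export
oniom_me <- function(mol, model, method_high, method_low, basis = "min3g",
                     grid_level = 2L, control = list()) {
  e_low_ab <- .method_energy(mol, method_low, basis, grid_level,
                             control = control)$energy
  e_low_m <- .method_energy(model$model, method_low, basis, grid_level,
                            control = control)$energy
  e_high_m <- .method_energy(model$model, method_high, basis, grid_level,
                             control = control)$energy
  list(energy = e_low_ab - e_low_m + e_high_m,
       E_low_AB = e_low_ab, E_low_model = e_low_m, E_high_model = e_high_m)
}

#' Build the environment charge field for electronic embedding
#'
#' Charges on environment border atoms are zeroed; the residual (total
#' charge assigned to active atoms and zeroed border atoms minus the
#' integer model charge) is distributed evenly over the remaining
#' environment charges, so the field total equals the parent charge minus
#' the model charge.
#'
#' @param charges per-atom charges of the parent molecule.
#' @param model a `model_system`.
#' @return list with `xyz` (Angstrom), `q`, `env_atoms`, `zeroed`.
#' @export
charge_field <- function(charges, model) {
  mol <- model$parent
  env_atoms <- setdiff(seq_along(mol$z), model$active_atoms)
  border_env <- intersect(unique(model$border_pairs[, 2]), env_atoms)
  remaining <- setdiff(env_atoms, border_env)
  residual <- sum(charges[model$active_atoms]) + sum(charges[border_env]) -
    model$model$charge
  q <- charges
  q[border_env] <- 0
  if (length(remaining)) {
    q[remaining] <- q[remaining] + residual / length(remaining)
  }
  list(xyz = mol$coords[env_atoms, , drop = FALSE], q = q[env_atoms],
       env_atoms = env_atoms, zeroed = border_env)
}

#' ONIOM with electronic embedding
#'
#' As [oniom_me()], but both model calculations are polarized by the
#' environment represented as point charges derived from a low-level
#' supersystem calculation (IAO or Mulliken populations).
#'
#' @inheritParams oniom_me
#' @param charge_scheme `"iao"` or `"mulliken"`.
#' @param charge_scale scale factor on the field (1; 0 recovers ONIOM-ME).
#' @return list with `energy`, components, and the `field`.
#' @export
oniom_ee <- function(mol, model, method_high, method_low,
                     charge_scheme = c("iao", "mulliken"),
                     charge_scale = 1.0, basis = "min3g", grid_level = 2L,
                     control = list()) {
  charge_scheme <- match.arg(charge_scheme)
  low_ab <- .method_energy(mol, method_low, basis, grid_level,
                           control = control)
  charges <- iao_or_mulliken_charges(low_ab$scf, low_ab$ctx, charge_scheme)
  field <- charge_field(charges, model)
  field$q <- field$q * charge_scale
  pc <- if (any(field$q != 0)) list(xyz = field$xyz, q = field$q) else NULL
  e_low_m <- .method_energy(model$model, method_low, basis, grid_level,
                            point_charges = pc, control = control)$energy
  e_high_m <- .method_energy(model$model, method_high, basis, grid_level,
                             point_charges = pc, control = control)$energy
  list(energy = low_ab$energy - e_low_m + e_high_m,
       E_low_AB = low_ab$energy, E_low_model = e_low_m,
       E_high_model = e_high_m, field = field, charges = charges)
}

#' Atomic partial charges from a converged SCF solution
#'
#' Mulliken populations of the total density, or intrinsic atomic orbital
#' (IAO) charges computed against the package's minimal reference basis.
#' If the IAO construction is not applicable (fewer computational than
#' reference functions), Mulliken charges are returned with a warning.
#'
#' @param scf a `uks_result` or `ro_result`.
#' @param ctx the matching `ao_context`.
#' @param scheme `"mulliken"` or `"iao"`.
#' @return per-atom charges summing to the molecular charge.
#' @export
iao_or_mulliken_charges <- function(scf, ctx, scheme = c("mulliken", "iao")) {
  scheme <- match.arg(scheme)
  D <- if (inherits(scf, "ro_result")) scf$dens$D else scf$Da + scf$Db
  if (scheme == "mulliken") {
    pop <- rowSums(D * ctx$S)    # diag(D S)
    q <- vapply(seq_along(ctx$mol$z), function(a) {
      ctx$mol$z[a] - sum(pop[ctx$atom_ao_ranges[[a]]])
    }, numeric(1))
    return(q)
  }
  iao_charges(scf, ctx)
}

# intrinsic atomic orbital charges against the min3g reference basis
iao_charges <- function(scf, ctx) {
  ref_ctx <- build_context(ctx$mol, "min3g", grid_level = ctx$grid_level)
  S1 <- ctx$S
  S2 <- ref_ctx$S
  S12 <- cross_overlap(ctx, ref_ctx)
  if (ncol(S12) > nrow(S12)) {
    warning("IAO reference basis larger than the computational basis; ",
            "falling back to Mulliken charges")
    return(iao_or_mulliken_charges(scf, ctx, "mulliken"))
  }
  sym_orth <- function(C, S) {
    M <- t(C) %*% S %*% C
    es <- eigen((M + t(M)) / 2, symmetric = TRUE)
    keep <- es$values > 1e-10
    C %*% es$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(es$values[keep]), sum(keep)) %*%
      t(es$vectors[, keep, drop = FALSE])
  }
  pops <- numeric(length(ctx$mol$z))
  spins <- if (inherits(scf, "ro_result")) {
    nc <- scf$n_closed; no <- scf$n_open
    list(list(C = scf$C[, seq_len(nc + no), drop = FALSE]),
         list(C = scf$C[, seq_len(nc), drop = FALSE]))
  } else {
    list(list(C = scf$Ca[, seq_len(scf$n_occ[1]), drop = FALSE]),
         list(C = scf$Cb[, seq_len(scf$n_occ[2]), drop = FALSE]))
  }
  P12 <- solve(S1, S12)
  for (sp in spins) {
    C <- sp$C
    if (!ncol(C)) next
    Ct <- sym_orth(P12 %*% solve(S2, t(S12) %*% C), S1)
    O1 <- tcrossprod(C) %*% S1
    O2 <- tcrossprod(Ct) %*% S1
    A <- O1 %*% O2 %*% P12 +
      (diag(nrow(S1)) - O1) %*% (diag(nrow(S1)) - O2) %*% P12
    A <- sym_orth(A, S1)
    D <- tcrossprod(C)
    piao <- t(A) %*% S1 %*% D %*% S1 %*% A
    # reference AOs are atom-blocked in the same order as ref_ctx
    for (a in seq_along(ctx$mol$z)) {
      idx <- ref_ctx$atom_ao_ranges[[a]]
      pops[a] <- pops[a] + sum(diag(piao)[idx])
    }
  }
  ctx$mol$z - pops
}
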