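# Occupied-orbital localization and active/environment partitioning.

# SVD sign convention: largest-magnitude component of each right singular
# vector made positive, so partitions are reproducible.
.fix_svd_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# SPADE rotation: SVD of the active-AO block of the symmetrically
# orthogonalized occupied coefficients
.spade_svd <- function(C_occ, ctx, active_atoms) {
  act_ao <- unlist(ctx$atom_ao_ranges[active_atoms])
  # symmetric orthogonalization representation: C_orth = S^(1/2) C = S X C
  Corth <- ctx$S %*% ctx$X %*% C_occ
  block <- Corth[act_ao, , drop = FALSE]
  sv <- svd(block, nu = 0, nv = ncol(C_occ))
  V <- .fix_svd_signs(sv$v)
  list(V = V, d = c(sv$d, rep(0, ncol(C_occ) - length(sv$d))))
}

#' Localize occupied orbitals
#'
#' Rotates a set of occupied orbitals by a unitary matrix: either the SPADE
#' rotation (right singular vectors of the active-atom block of the
#' orthogonalized coefficients) or Boys-Foster localization by Jacobi
#' sweeps over the dipole-center spread.
#'
#' @param C_occ S-orthonormal occupied coefficients (columns).
#' @param ctx an `ao_context`.
#' @param method `"spade"` or `"boys"`.
#' @param active_atoms required for SPADE: 1-based atom indices.
#' @return list with `L` (localized coefficients), `W` (the unitary),
#'   and for SPADE also `sigma` (singular values, descending).
#' @export
localize_orbitals <- function(C_occ, ctx, method = c("spade", "boys"),
                              active_atoms = NULL) {
  method <- match.arg(method)
  nocc <- ncol(C_occ)
  if (nocc == 0) {
    return(list(L = C_occ, W = matrix(0, 0, 0), sigma = numeric(0)))
  }
  if (method == "spade") {
    if (is.null(active_atoms) || !length(active_atoms)) {
      stop("SPADE localization requires active_atoms")
    }
    sv <- .spade_svd(C_occ, ctx, active_atoms)
    return(list(L = C_occ %*% sv$V, W = sv$V, sigma = sv$d))
  }
  # Boys-Foster: maximize sum_i |<i|r|i>|^2 by 2x2 Jacobi rotations
  dip <- dipole_matrices(ctx)
  L <- C_occ
  W <- diag(nocc)
  for (sweep in seq_len(200)) {
    change <- 0
    for (i in seq_len(nocc - 1)) {
      for (j in (i + 1):nocc) {
        rii <- rij <- rjj <- numeric(3)
        for (k in 1:3) {
          M <- dip[[k]]
          rii[k] <- drop(t(L[, i]) %*% M %*% L[, i])
          rjj[k] <- drop(t(L[, j]) %*% M %*% L[, j])
          rij[k] <- drop(t(L[, i]) %*% M %*% L[, j])
        }
        Aij <- sum(rij^2) - 0.25 * sum((rii - rjj)^2)
        Bij <- sum(rij * (rii - rjj))
        if (abs(Aij) < 1e-14 && abs(Bij) < 1e-14) next
        theta <- 0.25 * atan2(Bij, -Aij)
        if (abs(theta) < 1e-10) next
        co <- cos(theta); si <- sin(theta)
        Li <- co * L[, i] + si * L[, j]
        Lj <- -si * L[, i] + co * L[, j]
        L[, i] <- Li; L[, j] <- Lj
        Wi <- co * W[, i] + si * W[, j]
        Wj <- -si * W[, i] + co * W[, j]
        W[, i] <- Wi; W[, j] <- Wj
        change <- change + abs(theta)
      }
    }
    if (change < 1e-9) break
  }
  if (sweep >= 200 && change >= 1e-9) {
    stop("Boys localization did not converge")
  }
  list(L = L, W = W, sigma = NULL)
}

#' SPADE partition of a set of occupied orbitals
#'
#' Rotates the orbitals by the SPADE unitary and splits them at the largest
#' successive gap of the singular-value spectrum (appending a zero after the
#' last singular value, so a fully active spectrum yields an empty
#' environment).
#'
#' @inheritParams localize_orbitals
#' @param active_atoms 1-based active atom indices.
#' @return object of class `orbital_partition`: `L`, `W`, `sigma`,
#'   `active_idx`, `env_idx` (column indices into `L`), `n_active`.
#' @export
spade_partition <- function(C_occ, ctx, active_atoms) {
  nocc <- ncol(C_occ)
  if (!length(active_atoms)) stop("active_atoms must be nonempty")
  if (length(setdiff(seq_along(ctx$mol$z), active_atoms)) == 0L) {
    loc <- localize_orbitals(C_occ, ctx, "spade", active_atoms)
    return(structure(list(L = loc$L, W = loc$W, sigma = loc$sigma,
                          active_idx = seq_len(nocc), env_idx = integer(0),
                          n_active = nocc), class = "orbital_partition"))
  }
  loc <- localize_orbitals(C_occ, ctx, "spade", active_atoms)
  sig <- loc$sigma
  gaps <- sig - c(sig[-1], 0)
  if (nocc > 1 && diff(range(sig)) < 1e-8) {
    stop("ambiguous SPADE partition: all singular values are equal; ",
         "choose a different active-atom set or use mulliken_select()")
  }
  best <- max(gaps)
  cand <- which(gaps > best - 1e-8)
  k <- min(cand)  # tie-break: smaller active set
  structure(list(L = loc$L, W = loc$W, sigma = sig,
                 active_idx = seq_len(k),
                 env_idx = if (k < nocc) (k + 1L):nocc else integer(0),
                 n_active = as.integer(k)), class = "orbital_partition")
}

#' Mulliken-population orbital selection
#'
#' Assigns each localized orbital to the active subsystem when its Mulliken
#' population on the active atoms exceeds `threshold` (default 0.3).
#'
#' @param L localized S-orthonormal occupied coefficients.
#' @param ctx `ao_context`.
#' @param active_atoms 1-based active atom indices.
#' @param threshold population threshold.
#' @param force_active column indices always assigned active (open shells).
#' @return `orbital_partition` (without singular values).
#' @export
mulliken_select <- function(L, ctx, active_atoms, threshold = 0.3,
                            force_active = integer(0)) {
  act_ao <- unlist(ctx$atom_ao_ranges[active_atoms])
  SL <- ctx$S %*% L
  pop <- colSums(SL[act_ao, , drop = FALSE] * L[act_ao, , drop = FALSE])
  active <- which(pop > threshold)
  active <- sort(union(active, force_active))
  structure(list(L = L, W = NULL, sigma = NULL,
                 populations = pop,
                 active_idx = active,
                 env_idx = setdiff(seq_len(ncol(L)), active),
                 n_active = length(active)), class = "orbital_partition")
}

#' Subsystem densities from an orbital partition
#'
#' @param partition an `orbital_partition`.
#' @param occupation per-orbital occupation of the partitioned set (1 for a
#'   spin channel, 2 for closed shells).
#' @return list with `D_active`, `D_env`, `R_active`, `R_env` (projectors,
#'   occupation-1 convention).
#' @export
subsystem_densities <- function(partition, occupation = 1) {
  n <- nrow(partition$L)
  mk <- function(idx) {
    if (!length(idx)) return(matrix(0, n, n))
    tcrossprod(partition$L[, idx, drop = FALSE])
  }
  Ra <- mk(partition$active_idx)
  Rb <- mk(partition$env_idx)
  list(D_active = occupation * Ra, D_env = occupation * Rb,
       R_active = Ra, R_env = Rb)
}

# --- spin-resolved partition of a UKS solution --------------------------

# partition each spin channel's occupied space; open-shell character is
# handled naturally because the alpha channel simply has more orbitals
partition_uks <- function(scf, ctx, active_atoms,
                          method = c("spade", "mulliken"), threshold = 0.3) {
  method <- match.arg(method)
  out <- list()
  for (sp in c("a", "b")) {
    C <- if (sp == "a") scf$Ca else scf$Cb
    nocc <- scf$n_occ[[if (sp == "a") 1 else 2]]
    C_occ <- C[, seq_len(nocc), drop = FALSE]
    part <- if (method == "spade") {
      spade_partition(C_occ, ctx, active_atoms)
    } else {
      loc <- localize_orbitals(C_occ, ctx, "boys")
      mulliken_select(loc$L, ctx, active_atoms, threshold)
    }
    dens <- subsystem_densities(part, occupation = 1)
    out[[sp]] <- c(part, dens)
  }
  structure(out, class = "uks_partition")
}

# --- shell-resolved partition of an RO solution -------------------------

# closed shells are localized and partitioned; open shells are localized
# among themselves and always assigned to the active subsystem
partition_roks <- function(ro, ctx, active_atoms,
                           method = c("spade", "mulliken"), threshold = 0.3) {
  method <- match.arg(method)
  nc <- ro$n_closed; no <- ro$n_open
  C_c <- ro$C[, seq_len(nc), drop = FALSE]
  C_o <- if (no > 0) ro$C[, nc + seq_len(no), drop = FALSE] else
    matrix(0, ctx$n_ao, 0)
  part_c <- if (method == "spade") {
    spade_partition(C_c, ctx, active_atoms)
  } else {
    loc <- localize_orbitals(C_c, ctx, "boys")
    mulliken_select(loc$L, ctx, active_atoms, threshold)
  }
  L_o <- if (no > 0) {
    localize_orbitals(C_o, ctx, "spade", active_atoms)$L
  } else C_o
  dens_c <- subsystem_densities(part_c, occupation = 2)
  n <- ctx$n_ao
  Do_A <- if (no > 0) tcrossprod(L_o) else matrix(0, n, n)  # 2f = 1
  structure(list(
    closed = c(part_c, dens_c), L_open = L_o,
    Dc_A = dens_c$D_active, Dc_B = dens_c$D_env, Do_A = Do_A,
    R_cB = dens_c$R_env,
    D_A = dens_c$D_active + Do_A,
    n_closed_A = part_c$n_active, n_open = no),
    class = "roks_partition")
}
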