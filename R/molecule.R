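#' Define a molecule
#'
#' Creates the molecular specification used by every solver in the package:
#' element symbols, Cartesian coordinates in Angstrom, total charge, spin
#' multiplicity, and (optionally) the set of active atoms for focused
#' multilevel models.
#'
#' @param symbols character vector of element symbols (H-Ar).
#' @param coords numeric matrix (n_atoms x 3) of positions in Angstrom.
#' @param charge integer total charge.
#' @param multiplicity spin multiplicity 2S+1 (>= 1); its parity must be
#'   consistent with the electron count.
#' @param active_atoms integer vector of 1-based atom indices forming the
#'   active subsystem (may be empty).
#' @return an object of class `molecule`.
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                     active_atoms = integer(0)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(symbols)) {
    stop("coords must be an n_atoms x 3 matrix matching symbols")
  }
  z <- element_number(symbols)
  nelec <- sum(z) - charge
  if (nelec < 1) stop("molecule has no electrons")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  n_open <- multiplicity - 1L
  if ((nelec - n_open) %% 2L != 0L || nelec < n_open) {
    stop("multiplicity ", multiplicity,
         " is inconsistent with an electron count of ", nelec)
  }
  active_atoms <- as.integer(sort(unique(active_atoms)))
  if (length(active_atoms) &&
      (min(active_atoms) < 1L || max(active_atoms) > length(symbols))) {
    stop("active_atoms must be 1-based atom indices within the molecule")
  }
  structure(list(symbols = symbols, coords = coords, z = z,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 n_elec = nelec, active_atoms = active_atoms),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %+d, multiplicity %d, %d electrons\n",
              length(x$symbols), x$charge, x$multiplicity, x$n_elec))
  if (length(x$active_atoms)) {
    cat("active atoms:", paste(x$active_atoms, collapse = ", "), "\n")
  }
  invisible(x)
}

# per-spin electron counts for the high-spin state
spin_counts <- function(mol) {
  n_open <- mol$multiplicity - 1L
  na <- (mol$n_elec + n_open) / 2L
  c(alpha = as.integer(na), beta = as.integer(mol$n_elec - na))
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z`
#' records in Angstrom.
#'
#' @param path file path.
#' @inheritParams molecule
#' @return a `molecule`.
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L,
                     active_atoms = integer(0)) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  recs <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(recs, `[[`, "", 1L)
  coords <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(symbols, coords, charge = charge, multiplicity = multiplicity,
           active_atoms = active_atoms)
}

#' Write a molecule to an XYZ file
#' @param mol a `molecule`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(mol$symbols)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", mol$symbols,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]), con)
}

# nuclear repulsion in hartree from coordinates in bohr
nuclear_repulsion <- function(z, xyz_bohr) {
  n <- length(z)
  if (n < 2) return(0)
  e <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      e <- e + z[a] * z[b] / sqrt(sum((xyz_bohr[a, ] - xyz_bohr[b, ])^2))
    }
  }
  e
}
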