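# Molecular quadrature: Becke fuzzy-cell partitioning with a Gauss-Chebyshev
# radial rule (Becke mapping) and small Lebedev angular rules.

# Lebedev rules with simple closed-form weights (degrees 3, 5, 7, 11)
.lebedev <- function(n) {
  oct6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  s <- 1 / sqrt(2)
  oct12 <- rbind(c(s, s, 0), c(s, -s, 0), c(-s, s, 0), c(-s, -s, 0),
                 c(s, 0, s), c(s, 0, -s), c(-s, 0, s), c(-s, 0, -s),
                 c(0, s, s), c(0, s, -s), c(0, -s, s), c(0, -s, -s))
  t3 <- 1 / sqrt(3)
  oct8 <- as.matrix(expand.grid(c(t3, -t3), c(t3, -t3), c(t3, -t3)))
  if (n == 6) {
    return(list(points = oct6, weights = rep(1 / 6, 6)))
  }
  if (n == 14) {
    return(list(points = rbind(oct6, oct8),
                weights = c(rep(1 / 15, 6), rep(3 / 40, 8))))
  }
  if (n == 26) {
    return(list(points = rbind(oct6, oct12, oct8),
                weights = c(rep(1 / 21, 6), rep(4 / 105, 12), rep(27 / 840, 8))))
  }
  if (n == 50) {
    l <- 1 / sqrt(11); m <- 3 / sqrt(11)
    g <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
    b24 <- rbind(cbind(l * g[, 1], l * g[, 2], m * g[, 3]),
                 cbind(l * g[, 1], m * g[, 2], l * g[, 3]),
                 cbind(m * g[, 1], l * g[, 2], l * g[, 3]))
    return(list(points = rbind(oct6, oct12, oct8, b24),
                weights = c(rep(4 / 315, 6), rep(64 / 2835, 12),
                            rep(27 / 1280, 8), rep(14641 / 725760, 24))))
  }
  stop("unsupported Lebedev order: ", n)
}

# Becke smoothing polynomial, 3 iterations
.becke_s <- function(mu) {
  p <- mu
  for (i in 1:3) p <- 1.5 * p - 0.5 * p^3
  0.5 * (1 - p)
}

#' Molecular Becke quadrature grid
#'
#' @param mol a [molecule()].
#' @param level 1 (20 radial x 26 angular), 2 (30 x 50), 3 (45 x 50).
#' @return list with `points` (bohr) and `weights`.
#' @export
becke_grid <- function(mol, level = 2L) {
  nrad <- c(20L, 30L, 45L)[level]
  nang <- c(26L, 50L, 50L)[level]
  leb <- .lebedev(nang)
  xyz <- mol$coords * .BOHR_PER_ANGSTROM
  natom <- nrow(xyz)
  rb <- .BRAGG_ANGSTROM[mol$z] * .BOHR_PER_ANGSTROM

  pts_list <- list(); w_list <- list()
  i <- seq_len(nrad)
  for (a in seq_len(natom)) {
    R <- rb[a]
    x <- cos(i * pi / (nrad + 1))
    r <- R * (1 + x) / (1 - x)
    wch <- pi / (nrad + 1) * sin(i * pi / (nrad + 1))^2
    drdx <- 2 * R / (1 - x)^2
    wr <- wch * drdx * r^2 / sqrt(1 - x^2)   # Gauss-Chebyshev 2nd kind on dx
    keep <- r < 35
    pts <- kronecker(r[keep], leb$points)           # (nrad*nang) x 3
    # radius-major ordering matches kronecker(): block i holds all angular
    # points of radius r_i
    w <- as.vector(outer(leb$weights * 4 * pi, wr[keep]))
    pts <- sweep(pts, 2, xyz[a, ], "+")
    # Becke cell weights
    if (natom > 1) {
      dists <- vapply(seq_len(natom), function(b) {
        sqrt(rowSums(sweep(pts, 2, xyz[b, ])^2))
      }, numeric(nrow(pts)))
      Rab <- as.matrix(dist(xyz))
      P <- matrix(1, nrow(pts), natom)
      for (b in seq_len(natom)) {
        for (c in seq_len(natom)) {
          if (b == c) next
          mu <- (dists[, b] - dists[, c]) / Rab[b, c]
          P[, b] <- P[, b] * .becke_s(mu)
        }
      }
      wb <- P[, a] / rowSums(P)
      w <- w * wb
    }
    pts_list[[a]] <- pts
    w_list[[a]] <- w
  }
  pts <- do.call(rbind, pts_list)
  w <- unlist(w_list)
  keep <- w > 1e-14
  list(points = pts[keep, , drop = FALSE], weights = w[keep])
}
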