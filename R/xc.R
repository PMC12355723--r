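# Exchange-correlation functionals and their grid evaluation.
#
# Each functional is an energy-density function f(ra, rb, gaa, gab, gbb)
# (hartree/bohr^3) of the spin densities and gradient invariants
# g_ss' = grad(rho_s) . grad(rho_s').  Potentials are obtained from f by
# numerically exact directional differentiation at every grid point; the
# hybrid convention follows the Fock expression
# F_s = h + J - a_HF K[D_s] + (1 - a_HF) V_xc,s, i.e. the stored energy
# density is pre-divided by (1 - a_HF).

.slater_x <- function(ra, rb) {
  cx <- -0.75 * (6 / pi)^(1 / 3)
  cx * (pmax(ra, 0)^(4 / 3) + pmax(rb, 0)^(4 / 3))
}

# PW92 local correlation
.pw92_G <- function(rs, A, a1, b1, b2, b3, b4) {
  den <- 2 * A * (b1 * sqrt(rs) + b2 * rs + b3 * rs^1.5 + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log1p(1 / den)
}

.pw92_eps <- function(rs, zeta) {
  e0 <- .pw92_G(rs, 0.031091, 0.21370, 7.5957, 3.5876, 1.6382, 0.49294)
  e1 <- .pw92_G(rs, 0.015545, 0.20548, 14.1189, 6.1977, 3.3662, 0.62517)
  mac <- -.pw92_G(rs, 0.016887, 0.11125, 10.357, 3.6231, 0.88026, 0.49671)
  fz <- ((1 + zeta)^(4 / 3) + (1 - zeta)^(4 / 3) - 2) / (2^(4 / 3) - 2)
  fpp0 <- 1.709920934161366
  e0 + mac * fz / fpp0 * (1 - zeta^4) + (e1 - e0) * fz * zeta^4
}

.pw92_c <- function(ra, rb) {
  ra <- pmax(ra, 0); rb <- pmax(rb, 0)
  rho <- ra + rb
  out <- numeric(length(rho))
  ok <- rho > 1e-14
  if (any(ok)) {
    rs <- (3 / (4 * pi * rho[ok]))^(1 / 3)
    zeta <- pmin(pmax((ra[ok] - rb[ok]) / rho[ok], -1), 1)
    out[ok] <- rho[ok] * .pw92_eps(rs, zeta)
  }
  out
}

# PBE exchange via the spin-scaling relation
.pbe_x_closed <- function(rho, gamma) {
  kappa <- 0.804; mu <- 0.2195149727645171
  ex_lda <- -0.75 * (3 / pi)^(1 / 3) * rho^(4 / 3)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  s2 <- gamma / pmax(4 * kf^2 * rho^2, 1e-300)
  Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  ex_lda * Fx
}

.pbe_x <- function(ra, rb, gaa, gbb) {
  ra <- pmax(ra, 0); rb <- pmax(rb, 0)
  gaa <- pmax(gaa, 0); gbb <- pmax(gbb, 0)
  out <- numeric(length(ra))
  ok <- ra > 1e-14
  out[ok] <- 0.5 * .pbe_x_closed(2 * ra[ok], 4 * gaa[ok])
  ok <- rb > 1e-14
  out[ok] <- out[ok] + 0.5 * .pbe_x_closed(2 * rb[ok], 4 * gbb[ok])
  out
}

.pbe_c <- function(ra, rb, gaa, gab, gbb) {
  ra <- pmax(ra, 0); rb <- pmax(rb, 0)
  rho <- ra + rb
  out <- numeric(length(rho))
  ok <- rho > 1e-14
  if (!any(ok)) return(out)
  ra <- ra[ok]; rb <- rb[ok]; rho <- rho[ok]
  gamma <- pmax(gaa[ok] + 2 * gab[ok] + gbb[ok], 0)
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  zeta <- pmin(pmax((ra - rb) / rho, -1), 1)
  eps <- .pw92_eps(rs, zeta)
  phi <- ((1 + zeta)^(2 / 3) + (1 - zeta)^(2 / 3)) / 2
  gam <- (1 - log(2)) / pi^2
  beta <- 0.066725
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- gamma / (2 * phi * ks * rho)^2
  expo <- exp(-eps / (gam * phi^3))
  Aa <- beta / gam / pmax(expo - 1, 1e-300)
  num <- 1 + Aa * t2
  H <- gam * phi^3 * log1p(beta / gam * t2 * num / (1 + Aa * t2 + Aa^2 * t2^2))
  out[ok] <- rho * (eps + H)
  out
}

#' Exchange-correlation functional specification
#'
#' @param name one of `"hf"` (no xc, full exact exchange), `"lda"`
#'   (Slater exchange + PW92 correlation), `"pbe"`, `"pbe0"`
#'   (25% exact exchange hybrid).
#' @param dispersion `"none"` or `"pairwise_bj"` (see
#'   [dispersion_energy()]).
#' @return an object of class `xc_spec` with fields `name`, `a_hf` (exact
#'   exchange fraction), `fun` (energy density or NULL), and `uses_grad`.
#' @export
xc_spec <- function(name, dispersion = "none") {
  name <- tolower(name)
  spec <- switch(name,
    hf = list(a_hf = 1, fun = NULL, uses_grad = FALSE),
    lda = list(a_hf = 0, uses_grad = FALSE,
               fun = function(ra, rb, gaa, gab, gbb)
                 .slater_x(ra, rb) + .pw92_c(ra, rb)),
    pbe = list(a_hf = 0, uses_grad = TRUE,
               fun = function(ra, rb, gaa, gab, gbb)
                 .pbe_x(ra, rb, gaa, gbb) + .pbe_c(ra, rb, gaa, gab, gbb)),
    pbe0 = list(a_hf = 0.25, uses_grad = TRUE,
                fun = function(ra, rb, gaa, gab, gbb)
                  .pbe_x(ra, rb, gaa, gbb) +
                  .pbe_c(ra, rb, gaa, gab, gbb) / 0.75),
    stop("unknown functional: ", name))
  structure(c(list(name = name, dispersion = dispersion), spec),
            class = "xc_spec")
}

as_xc_spec <- function(x) {
  if (inherits(x, "xc_spec")) x else xc_spec(x)
}

# densities and gradient invariants on the grid for a chunk of points
.grid_density <- function(gr, idx, D) {
  ao <- gr$ao[idx, , drop = FALSE]
  DP <- ao %*% D
  rho <- rowSums(DP * ao)
  gx <- 2 * rowSums(DP * gr$aox[idx, , drop = FALSE])
  gy <- 2 * rowSums(DP * gr$aoy[idx, , drop = FALSE])
  gz <- 2 * rowSums(DP * gr$aoz[idx, , drop = FALSE])
  list(rho = rho, gx = gx, gy = gy, gz = gz)
}

# numerical partial derivatives of the energy density: central differences
# with proportional steps (forward at the clamp boundary)
.fd_partials <- function(fun, ra, rb, gaa, gab, gbb) {
  args <- list(ra = ra, rb = rb, gaa = gaa, gab = gab, gbb = gbb)
  f0 <- fun(ra, rb, gaa, gab, gbb)
  base <- abs(ra) + abs(rb)
  gbase <- abs(gaa) + abs(gbb) + abs(gab)
  out <- vector("list", 5)
  names(out) <- names(args)
  for (k in seq_along(args)) {
    v <- args[[k]]
    scale <- if (k <= 2) base else gbase
    h <- 1e-6 * pmax(scale, 1e-10)
    lo_ok <- if (k == 4) rep(TRUE, length(v)) else (v - h) >= 0
    vp <- args; vp[[k]] <- v + h
    fp <- do.call(fun, vp)
    vm <- args; vm[[k]] <- ifelse(lo_ok, v - h, v)
    fm <- do.call(fun, vm)
    out[[k]] <- (fp - fm) / (h * (1 + lo_ok))
  }
  out
}

#' Evaluate exchange-correlation energy and potentials
#'
#' Integrates the functional on the context's shared quadrature grid and
#' returns the energy together with the AO-basis potential matrices
#' \eqn{V_\sigma = \partial E_{xc}/\partial D_\sigma}.
#'
#' @param ctx an `ao_context`.
#' @param Da,Db symmetric spin density matrices.
#' @param xc an [xc_spec()] (or functional name).
#' @return list with `E`, `Va`, `Vb`.
#' @export
xc_eval <- function(ctx, Da, Db, xc) {
  xc <- as_xc_spec(xc)
  if (is.null(xc$fun)) {
    z <- matrix(0, ctx$n_ao, ctx$n_ao)
    return(list(E = 0, Va = z, Vb = z))
  }
  if (max(abs(Da - t(Da))) > 1e-8 || max(abs(Db - t(Db))) > 1e-8) {
    stop("xc_eval requires symmetric density matrices")
  }
  gr <- context_grid(ctx)
  n <- ctx$n_ao
  npts <- length(gr$weights)
  E <- 0
  Va <- matrix(0, n, n)
  Vb <- matrix(0, n, n)
  chunk <- 8000L
  starts <- seq(1L, npts, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, npts)
    w <- gr$weights[idx]
    da <- .grid_density(gr, idx, Da)
    db <- .grid_density(gr, idx, Db)
    ra <- pmax(da$rho, 0); rb <- pmax(db$rho, 0)
    gaa <- da$gx^2 + da$gy^2 + da$gz^2
    gbb <- db$gx^2 + db$gy^2 + db$gz^2
    gab <- da$gx * db$gx + da$gy * db$gy + da$gz * db$gz
    f0 <- xc$fun(ra, rb, gaa, gab, gbb)
    E <- E + sum(w * f0)
    d <- .fd_partials(xc$fun, ra, rb, gaa, gab, gbb)
    ao <- gr$ao[idx, , drop = FALSE]
    # local (density) part
    Va <- Va + crossprod(ao * (w * d$ra), ao)
    Vb <- Vb + crossprod(ao * (w * d$rb), ao)
    if (xc$uses_grad) {
      aox <- gr$aox[idx, , drop = FALSE]
      aoy <- gr$aoy[idx, , drop = FALSE]
      aoz <- gr$aoz[idx, , drop = FALSE]
      # gradient part: 2 f_gss grad(rho_s) + f_gab grad(rho_s')
      vxa <- w * (2 * d$gaa * da$gx + d$gab * db$gx)
      vya <- w * (2 * d$gaa * da$gy + d$gab * db$gy)
      vza <- w * (2 * d$gaa * da$gz + d$gab * db$gz)
      Ma <- crossprod(ao, vxa * aox + vya * aoy + vza * aoz)
      Va <- Va + Ma + t(Ma)
      vxb <- w * (2 * d$gbb * db$gx + d$gab * da$gx)
      vyb <- w * (2 * d$gbb * db$gy + d$gab * da$gy)
      vzb <- w * (2 * d$gbb * db$gz + d$gab * da$gz)
      Mb <- crossprod(ao, vxb * aox + vyb * aoy + vzb * aoz)
      Vb <- Vb + Mb + t(Mb)
    }
  }
  Va <- (Va + t(Va)) / 2
  Vb <- (Vb + t(Vb)) / 2
  list(E = E, Va = Va, Vb = Vb)
}
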