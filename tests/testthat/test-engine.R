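# Integral engine, basis generation, grids, xc evaluation, dispersion,
# and MP2 against closed-form and brute-force oracles.

test_that("basis generator reproduces the universal 1s three-Gaussian fit", {
  fit <- huzembed:::.fit_shell_group(1L, 3L)
  # classic zeta = 1 least-squares expansion of a 1s Slater function
  expect_equal(sort(fit$exps), sort(c(2.227660584, 0.405771156, 0.109818)),
               tolerance = 2e-3)
  expect_equal(sort(abs(fit$s)), sort(c(0.154328967, 0.535328142, 0.444634542)),
               tolerance = 2e-3)
})

test_that("contractions are normalized and atom AO ranges are contiguous", {
  ctx <- get_ctx("water")
  expect_equal(diag(ctx$S), rep(1, ctx$n_ao), tolerance = 1e-10)
  expect_equal(sort(unlist(ctx$atom_ao_ranges)), seq_len(ctx$n_ao))
  # split-valence basis enlarges the AO set
  ctx2 <- build_context(fixture("water"), "split3g")
  expect_gt(ctx2$n_ao, ctx$n_ao)
})

test_that("context invariants: S spd, V_nn, one-center limits", {
  h <- build_context(fixture("h_atom"))
  expect_equal(h$n_ao, 1L)
  expect_equal(h$S, matrix(1), tolerance = 1e-10)
  expect_equal(h$V_nn, 0)
  # H2 at 1.4 bohr: point-charge repulsion 1/1.4
  r_ang <- 1.4 / huzembed:::.BOHR_PER_ANGSTROM
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(r_ang, 0, 0)))
  ctx <- build_context(m)
  expect_equal(ctx$V_nn, 1 / 1.4, tolerance = 1e-10)
  expect_gt(min(eigen(ctx$S, symmetric = TRUE)$values), 0)
  # far-separated He2: off-diagonal overlap block vanishes
  ctx50 <- build_context(fixture("he_dimer", d = 50))
  expect_lt(max(abs(ctx50$S[1, 2])), 1e-12)
  # unknown element errors
  expect_error(molecule("Xx", matrix(0, 1, 3)), "unknown element")
})

test_that("J and K builders are linear and positive where required", {
  ctx <- get_ctx("water")
  n <- ctx$n_ao
  D1 <- rand_sym(n, 1); D2 <- rand_sym(n, 2)
  a <- 0.3; b <- -1.7
  expect_equal(ctx$J(a * D1 + b * D2), a * ctx$J(D1) + b * ctx$J(D2),
               tolerance = 1e-12)
  expect_equal(ctx$K(a * D1 + b * D2), a * ctx$K(D1) + b * ctx$K(D2),
               tolerance = 1e-12)
  # Tr{D J[D]} >= 0 for PSD D
  set.seed(3)
  B <- matrix(rnorm(n * 3), n, 3)
  Dpsd <- tcrossprod(B)
  expect_gte(sum(Dpsd * ctx$J(Dpsd)), 0)
  # J and K of a symmetric density are symmetric
  expect_equal(ctx$J(D1), t(ctx$J(D1)), tolerance = 1e-12)
  expect_equal(ctx$K(D1), t(ctx$K(D1)), tolerance = 1e-12)
})

test_that("ERI tensor has 8-fold permutational symmetry", {
  ctx <- get_ctx("oh_radical")
  g <- ctx$eri
  set.seed(4)
  n <- dim(g)[1]
  for (rep in 1:25) {
    i <- sample(n, 4, replace = TRUE)
    v <- g[i[1], i[2], i[3], i[4]]
    expect_equal(g[i[2], i[1], i[3], i[4]], v, tolerance = 1e-12)
    expect_equal(g[i[1], i[2], i[4], i[3]], v, tolerance = 1e-12)
    expect_equal(g[i[3], i[4], i[1], i[2]], v, tolerance = 1e-12)
  }
})

test_that("xc evaluation: trivial cases and spin symmetry", {
  ctx <- get_ctx("water")
  n <- ctx$n_ao
  D <- get_uks("water")$Da
  hf <- xc_eval(ctx, D, D, "hf")
  expect_equal(hf$E, 0)
  expect_equal(hf$Va, matrix(0, n, n))
  v <- xc_eval(ctx, D, D, "lda")
  expect_equal(v$Va, v$Vb, tolerance = 1e-12)
  # swapping the spin densities swaps the potentials
  res <- get_uks("oh_radical")
  v1 <- xc_eval(ctx_oh <- get_ctx("oh_radical"), res$Da, res$Db, "lda")
  v2 <- xc_eval(ctx_oh, res$Db, res$Da, "lda")
  expect_equal(v1$Va, v2$Vb, tolerance = 1e-12)
  expect_error(xc_eval(ctx, D + 0.1 * matrix(seq_len(n^2), n, n), D, "lda"),
               "symmetric")
})

test_that("Slater exchange on a one-electron gaussian matches independent
          radial quadrature", {
  # single normalized s gaussian, exponent a: rho(r) = N^2 exp(-2 a r^2)
  a <- 0.8
  m <- fixture("h_atom")
  ctx <- build_context(m, grid_level = 3L)
  # density matrix that puts one electron in an s gaussian is built by
  # projecting onto the single AO; instead evaluate the functional on the
  # SCF density and compare with 1D radial quadrature of the same density
  r1 <- solve_uks(m, ctx, "hf")
  ex_grid <- xc_eval(ctx, r1$Da, r1$Db, "lda")
  # independent oracle: radial integration of the Slater + PW92 energy
  # density of rho(r) expanded in the same contraction
  shell <- ctx$shells
  rho_fun <- function(r) {
    chi <- numeric(length(r))
    for (ip in seq_len(shell$pn[1])) {
      chi <- chi + shell$pcoef[ip] * exp(-shell$pexp[ip] * r^2)
    }
    chi^2 * r1$Da[1, 1]
  }
  cx <- -0.75 * (6 / pi)^(1 / 3)
  integrand <- function(r) {
    ra <- rho_fun(r)
    4 * pi * r^2 * (cx * ra^(4 / 3) + huzembed:::.pw92_c(ra, 0 * ra))
  }
  e_ref <- integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(ex_grid$E, e_ref, tolerance = 2e-4)
})

test_that("xc potentials are consistent derivatives of the energy", {
  ctx <- get_ctx("oh_radical", grid_level = 2L)
  res <- get_uks("oh_radical")
  n <- ctx$n_ao
  for (fun in c("lda", "pbe")) {
    v <- xc_eval(ctx, res$Da, res$Db, fun)
    set.seed(11)
    Delta <- rand_sym(n, 11) * 0.01
    fd <- fd_directional(function(D) xc_eval(ctx, D, res$Db, fun)$E,
                         res$Da, Delta, h = 1e-4)
    expect_equal(fd, sum(v$Va * Delta),
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("dispersion partition rule: subset pairs only", {
  m <- fixture("pentenyl_radical")
  expect_equal(dispersion_energy(m, integer(0)), 0)
  expect_equal(dispersion_energy(m, 3L), 0)
  # full subset equals a direct pair-sum oracle
  full <- dispersion_energy(m)
  xyz <- m$coords * huzembed:::.BOHR_PER_ANGSTROM
  c6 <- huzembed:::.C6_FREE[m$symbols]
  rc <- huzembed:::.RCOV[m$symbols] * huzembed:::.BOHR_PER_ANGSTROM
  acc <- 0
  for (i in 1:(nrow(xyz) - 1)) for (j in (i + 1):nrow(xyz)) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    acc <- acc - sqrt(c6[i] * c6[j]) /
      (r2^3 + (1.6 * (rc[i] + rc[j]) + 0.8)^6)
  }
  expect_equal(full, unname(acc), tolerance = 1e-12)
  expect_lt(full, 0)
  # two-atom molecule: both atoms = full value
  he <- fixture("he_dimer", d = 3)
  expect_equal(dispersion_energy(he, c(1, 2)), dispersion_energy(he))
  # subset sums only internal pairs: complement + subset < full (pairs
  # across the border are dropped)
  sub <- dispersion_energy(m, 1:5)
  comp <- dispersion_energy(m, 6:14)
  expect_gt(sub + comp, full)  # dropped cross terms are negative
})

test_that("MP2 equals a literal four-index-loop oracle and trivial limits", {
  ctx <- get_ctx("h2")
  r <- get_uks("h2")
  e2 <- mp2_from_uks(r, ctx)
  # literal oracle: single occupied, single virtual
  g_iajb <- mo_eri_loop(ctx$eri, r$Ca[, 1], r$Ca[, 2], r$Ca[, 1], r$Ca[, 2])
  e_ref <- g_iajb^2 / (2 * r$eps_a[1] - 2 * r$eps_a[2])
  expect_equal(e2, e_ref, tolerance = 1e-12)
  expect_lt(e2, 0)
  # zero occupied orbitals -> zero correlation
  expect_equal(correlation_energy(ctx, r$Ca[, 0, drop = FALSE],
                                  r$Cb[, 0, drop = FALSE],
                                  ctx$h_core, ctx$h_core), 0)
  # non-orthonormal input is rejected
  expect_error(correlation_energy(ctx, 2 * r$Ca[, 1, drop = FALSE],
                                  r$Cb[, 1, drop = FALSE],
                                  ctx$h_core, ctx$h_core),
               "orthonormal")
})

test_that("MP2 on a many-electron fixture matches the loop oracle", {
  ctx <- get_ctx("oh_radical")
  r <- get_uks("oh_radical")
  e2 <- mp2_from_uks(r, ctx)
  # brute-force spin-orbital MP2 from canonical orbitals
  fk <- build_uks_fock(list(Da = r$Da, Db = r$Db), ctx, "hf")
  na <- r$n_occ[1]; nb <- r$n_occ[2]; n <- ctx$n_ao
  ga <- array(0, c(na, n - na, na, n - na))
  gb <- array(0, c(nb, n - nb, nb, n - nb))
  gab <- array(0, c(na, n - na, nb, n - nb))
  for (i in seq_len(na)) for (a in seq_len(n - na))
    for (j in seq_len(na)) for (b in seq_len(n - na))
      ga[i, a, j, b] <- mo_eri_loop(ctx$eri, r$Ca[, i], r$Ca[, na + a],
                                    r$Ca[, j], r$Ca[, na + b])
  for (i in seq_len(nb)) for (a in seq_len(n - nb))
    for (j in seq_len(nb)) for (b in seq_len(n - nb))
      gb[i, a, j, b] <- mo_eri_loop(ctx$eri, r$Cb[, i], r$Cb[, nb + a],
                                    r$Cb[, j], r$Cb[, nb + b])
  for (i in seq_len(na)) for (a in seq_len(n - na))
    for (j in seq_len(nb)) for (b in seq_len(n - nb))
      gab[i, a, j, b] <- mo_eri_loop(ctx$eri, r$Ca[, i], r$Ca[, na + a],
                                     r$Cb[, j], r$Cb[, nb + b])
  ea <- r$eps_a; eb <- r$eps_b
  acc <- 0
  for (i in seq_len(na)) for (j in seq_len(na)) for (a in seq_len(n - na))
    for (b in seq_len(n - na)) {
      t <- ga[i, a, j, b] - ga[i, b, j, a]
      acc <- acc + 0.25 * t^2 / (ea[i] + ea[j] - ea[na + a] - ea[na + b])
    }
  for (i in seq_len(nb)) for (j in seq_len(nb)) for (a in seq_len(n - nb))
    for (b in seq_len(n - nb)) {
      t <- gb[i, a, j, b] - gb[i, b, j, a]
      acc <- acc + 0.25 * t^2 / (eb[i] + eb[j] - eb[nb + a] - eb[nb + b])
    }
  for (i in seq_len(na)) for (j in seq_len(nb)) for (a in seq_len(n - na))
    for (b in seq_len(n - nb)) {
      acc <- acc + gab[i, a, j, b]^2 /
        (ea[i] + eb[j] - ea[na + a] - eb[nb + b])
    }
  # orbitals enter the oracle from the converged solution, so agreement is
  # limited by the SCF residual, not machine precision
  expect_equal(e2, acc, tolerance = 1e-7)
})
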