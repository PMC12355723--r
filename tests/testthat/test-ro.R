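# Restricted open-shell SCF: ensemble parameters, shell densities, the
# unified Fock operator, and oracle equivalence.

test_that("high-spin ensemble parameters and omega weights", {
  ens <- build_ensemble(3L)
  expect_equal(ens$f, 0.5)
  expect_equal(ens$a, 1)
  expect_equal(ens$b, 2)
  expect_equal(ens$a_bar, 0)
  expect_equal(ens$b_bar, -2)
  expect_equal(ens$c_bar, 2)
  expect_equal(ens$omega(3), c(1, 1, 1, 0.5, 0.5))
  expect_equal(sum(vapply(ens$microstates, `[[`, 0, "c")), 1)
  # closed shell: all weights one
  ens0 <- build_ensemble(1L)
  expect_equal(ens0$omega(4), rep(1, 4))
  # non-high-spin request is rejected
  expect_error(build_ensemble(3L, n_open = 4L), "unsupported")
})

test_that("open-shell self-interaction cancels in the coupling parameters", {
  # one open orbital, f = 1/2, a = 1, b = 2:
  # (1/2)(2f)^2 (a J_mm - (b/2) K_mm) = (1/2)(J_mm - K_mm) = 0
  # since J_mm = K_mm for a single orbital
  ctx <- get_ctx("h_atom")
  C1 <- ctx$X[, 1, drop = FALSE]
  D1 <- tcrossprod(C1)
  ens <- build_ensemble(2L)
  Jmm <- sum(D1 * ctx$J(D1)); Kmm <- sum(D1 * ctx$K(D1))
  expect_equal(0.5 * (2 * ens$f)^2 * (ens$a * Jmm - ens$b / 2 * Kmm), 0,
               tolerance = 1e-12)
})

test_that("shell densities satisfy idempotency, trace, and orthogonality
          invariants", {
  ctx <- get_ctx("ch2_triplet")
  S <- ctx$S
  ens <- build_ensemble(3L)
  ro <- get_ro("ch2_triplet")
  d <- ro$dens
  expect_lt(max(abs(d$Dc %*% S %*% d$Dc - 2 * d$Dc)), 1e-8)
  expect_lt(max(abs(d$Do %*% S %*% d$Do - d$Do)), 1e-8)
  expect_equal(sum(d$Dc * S), 2 * ro$n_closed, tolerance = 1e-8)
  expect_equal(sum(d$Do * S), 2 * ens$f * ro$n_open, tolerance = 1e-8)
  expect_lt(abs(sum((d$Dc %*% S %*% d$Do) * S)), 1e-8)
  # direct-summation oracle on random orthonormal orbitals (2 closed, 2 open)
  n <- ctx$n_ao
  set.seed(41)
  C0 <- ctx$X %*% qr.Q(qr(matrix(rnorm(n * n), n)))
  d2 <- shell_densities(C0, 2L, 2L, ens)
  Dc_ref <- 2 * (tcrossprod(C0[, 1]) + tcrossprod(C0[, 2]))
  Do_ref <- tcrossprod(C0[, 3]) + tcrossprod(C0[, 4])
  expect_equal(d2$Dc, Dc_ref, tolerance = 1e-12)
  expect_equal(d2$Do, Do_ref, tolerance = 1e-12)
  expect_equal(d2$Da, Dc_ref / 2 + Do_ref, tolerance = 1e-12)
  expect_error(shell_densities(C0[, 1:3], 2L, 2L, ens), "exceeds")
  # H atom: single open orbital carries one electron
  hctx <- get_ctx("h_atom")
  dh <- shell_densities(hctx$X, 0L, 1L, build_ensemble(2L))
  expect_equal(sum(dh$Do * hctx$S), 1, tolerance = 1e-12)
})

test_that("ro_energy limits: closed shell, one-electron exactness", {
  # closed-shell He: equals the unrestricted expression with equal spins
  he <- molecule("He", matrix(0, 1, 3))
  ctx <- build_context(he)
  r <- solve_ro(he, ctx, "hf")
  ru <- solve_uks(he, ctx, "hf")
  expect_equal(r$energy, ru$energy, tolerance = 1e-9)
  # H atom: total HF energy equals the bare one-electron energy
  hctx <- get_ctx("h_atom")
  rh <- get_ro("h_atom")
  e1 <- min(eigen(t(hctx$X) %*% hctx$h_core %*% hctx$X,
                  symmetric = TRUE)$values)
  expect_equal(rh$energy, e1, tolerance = 1e-10)
})

test_that("unified Fock: reduction, HF coupling correction, transcription
          oracle", {
  # closed shell: unified operator is the restricted Fock
  ctxw <- get_ctx("water")
  rw <- get_ro("water")
  fk <- build_unified_fock(rw$dens, build_ensemble(1L), ctxw, "hf")
  expect_equal(fk$F_unified, fk$F_c, tolerance = 1e-12)
  # HF high-spin: Q reduces to the exchange of the open density
  ctx <- get_ctx("ch2_triplet")
  ro <- get_ro("ch2_triplet")
  fk2 <- build_unified_fock(ro$dens, build_ensemble(3L), ctx, "hf")
  expect_equal(fk2$Q, ctx$K(ro$dens$Do), tolerance = 1e-12)
  expect_equal(fk2$F_unified, t(fk2$F_unified), tolerance = 1e-10)
  # literal transcription oracle for T and gamma on synthetic matrices
  n <- ctx$n_ao
  S <- ctx$S
  f <- 0.5; cb <- 2
  Rc <- ro$dens$Rc; Ro <- ro$dens$Ro
  Q <- fk2$Q
  G <- fk2$F_c - fk2$F_o - Q / 2
  gamma_ref <- Rc %*% S - diag(n) / cb + (cb / 2) * Ro %*% S
  T_ref <- S %*% Rc %*% Q + Q %*% Rc %*% S +
    f * (S %*% Ro %*% Q + Q %*% Ro %*% S) +
    cb * (t(gamma_ref) %*% G %*% Ro %*% S + S %*% Ro %*% G %*% gamma_ref)
  expect_equal(fk2$gamma, gamma_ref, tolerance = 1e-13)
  expect_equal(fk2$T, (T_ref + t(T_ref)) / 2, tolerance = 1e-12)
})

test_that("solve_ro equals direct-minimization ROHF on small radicals", {
  for (name in c("h_atom", "oh_radical", "ch3_radical", "ch2_triplet")) {
    ctx <- get_ctx(name)
    r <- get_ro(name)
    expect_true(r$converged)
    e_or <- cached(paste0("rohf_oracle_", name),
                   rohf_oracle(fixture(name), ctx))
    expect_equal(r$energy, e_or, tolerance = 1e-8)
    # stationarity of the shell blocks
    expect_lt(r$stationarity, 1e-6)
  }
  # H atom: identical to UHF (one electron)
  expect_equal(get_ro("h_atom")$energy, get_uks("h_atom")$energy,
               tolerance = 1e-10)
})

test_that("restricted solutions are spin-adapted at every multiplicity", {
  for (name in c("oh_radical", "ch3_radical", "ch2_triplet")) {
    r <- get_ro(name)
    s <- (fixture(name)$multiplicity - 1) / 2
    expect_equal(r$s_squared, s * (s + 1), tolerance = 1e-12)
  }
})

test_that("closed-shell RO pathway matches the unrestricted solver", {
  ctx <- get_ctx("water")
  expect_equal(get_ro("water")$energy, get_uks("water")$energy,
               tolerance = 1e-9)
})
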