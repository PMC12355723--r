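# Unrestricted Huzinaga embedding: potential, projector, embedded SCF,
# and the first-order multilevel energy.

test_that("embedding potential vanishes without an environment and drops
          xc for pure HF", {
  ctx <- get_ctx("water")
  r <- get_uks("water")
  D <- list(Da = r$Da, Db = r$Db)
  z <- list(Da = matrix(0, ctx$n_ao, ctx$n_ao),
            Db = matrix(0, ctx$n_ao, ctx$n_ao))
  pot0 <- build_embedding_potential_uks(D, D, ctx, "hf")
  expect_lt(max(abs(pot0$Va)), 1e-10)
  expect_lt(max(abs(pot0$Vb)), 1e-10)
  pot <- build_embedding_potential_uks(D, z, ctx, "hf")
  expect_equal(max(abs(pot$dVxa)), 0)
  expect_equal(pot$Va, pot$dJ - pot$dKa, tolerance = 1e-13)
})

test_that("Huzinaga operator: closed forms and transcription oracle", {
  F1 <- diag(2)
  expect_equal(huzinaga_operator(F1, matrix(0, 2, 2), diag(2)), F1)
  R <- diag(c(1, 0))
  expect_equal(huzinaga_operator(diag(2), R, diag(2)), diag(c(-1, 1)))
  # random instance against a literal formula evaluation
  set.seed(51)
  n <- 4
  F2 <- rand_sym(n, 52)
  B <- qr.Q(qr(matrix(rnorm(n * n), n)))
  S <- B %*% diag(c(2, 1.2, 0.7, 0.4)) %*% t(B)
  v <- matrix(rnorm(n), n)
  R1 <- tcrossprod(v)
  H <- huzinaga_operator(F2, R1, S)
  H_ref <- F2 - F2 %*% R1 %*% S - S %*% R1 %*% F2
  expect_equal(H, (H_ref + t(H_ref)) / 2, tolerance = 1e-13)
  expect_equal(H, t(H), tolerance = 1e-14)
  # eigenvalue inversion: for an environment orbital c, H c = -F-weighted
  # projection, so solutions of the embedded problem stay S-orthogonal;
  # verified operationally in the embedded SCF tests below
})

test_that("embedding potential matches finite differences of the composite
          energy", {
  m <- fixture("he_dimer", d = 2.2)
  ctx <- build_context(m, grid_level = 2L)
  r <- solve_uks(m, ctx, "hf")
  part <- partition_uks(r, ctx, active_atoms = 1L)
  D_AB <- list(Da = r$Da, Db = r$Db)
  D_A <- list(Da = part$a$D_active, Db = part$b$D_active)
  for (xc in c("hf", "pbe")) {
    pot <- build_embedding_potential_uks(D_AB, D_A, ctx, xc)
    # E_12 as a function of the alpha active density at frozen D^B
    DB <- list(Da = D_AB$Da - D_A$Da, Db = D_AB$Db - D_A$Db)
    f <- function(Da_act) {
      uks_energy(list(Da = Da_act + DB$Da, Db = D_A$Db + DB$Db), ctx, xc) -
        uks_energy(list(Da = Da_act, Db = D_A$Db), ctx, xc)
    }
    set.seed(61)
    Delta <- rand_sym(ctx$n_ao, 61) * 0.05
    fd <- fd_directional(f, D_A$Da, Delta, h = 1e-5)
    an <- sum(pot$Va * Delta)
    expect_equal(an, fd, tolerance = 1e-4 * max(abs(fd), 1e-3))
  }
})

test_that("same-level embedding is a fixed point with zero correction", {
  m <- fixture("water_dimer")
  ctx <- cached("ctx_wd", build_context(m, grid_level = 1L))
  res <- pbe_uks(m, "hf", "hf", active_atoms = 1:3, ctx = ctx,
                 control = list(r_tol = 1e-9, e_tol = 1e-11))
  expect_lt(abs(res$correction), 1e-9)
  expect_lt(max(abs(res$embedded$Da - res$partition$a$D_active)), 1e-7)
  expect_lt(abs(res$E_pbe - (res$E_low_AB + res$V_nn)), 1e-6)
  expect_lt(res$orthogonality_residual, 1e-7)
})

test_that("whole-system active region reduces to the high-level
          supersystem", {
  m <- fixture("water")
  ctx <- get_ctx("water")
  res <- pbe_uks(m, "hf", "pbe0", active_atoms = 1:3, ctx = ctx,
                 grid_level = 1L)
  full <- solve_uks(m, ctx, "pbe0")
  expect_equal(res$E_pbe, full$energy, tolerance = 1e-7)
})

test_that("embedded orbital energies match full-system eigenvalues for a
          noninteracting dimer", {
  m <- fixture("he_dimer", d = 50)
  ctx <- cached("ctx_he50", build_context(fixture("he_dimer", d = 50)))
  res <- pbe_uks(m, "hf", "hf", active_atoms = 1L, ctx = ctx)
  full <- solve_uks(m, ctx, "hf")
  emb_occ <- sort(res$embedded$eps_a)[1]
  # occupied eigenvalues of the noninteracting dimer are doubly degenerate;
  # the embedded active orbital reproduces one of them
  expect_equal(emb_occ, full$eps_a[1], tolerance = 1e-6)
})

test_that("open-shell same-level exactness and orthogonality across
          functionals", {
  m <- fixture("propyl_radical")
  act <- c(3, 9, 10)
  for (xc in c("hf", "pbe")) {
    ctx <- cached("ctx_propyl_g1", build_context(m, grid_level = 1L))
    res <- pbe_uks(m, xc, xc, active_atoms = act, ctx = ctx)
    expect_lt(abs(res$E_pbe - (res$E_low_AB + res$V_nn)), 1e-6)
    expect_lt(res$orthogonality_residual, 1e-7)
  }
})

test_that("first-order correction shrinks as the high level approaches the
          low level", {
  # PBE0 mixes exact exchange; moving its fraction toward zero approaches
  # PBE.  The magnitude of the correction must decrease monotonically.
  m <- fixture("oh_radical")
  ctx <- build_context(m, grid_level = 1L)
  r <- solve_uks(m, ctx, "pbe")
  part <- partition_uks(r, ctx, active_atoms = 1L)
  D_AB <- list(Da = r$Da, Db = r$Db)
  D_A <- list(Da = part$a$D_active, Db = part$b$D_active)
  pot <- build_embedding_potential_uks(D_AB, D_A, ctx, "pbe")
  corr <- vapply(c(1, 0.5, 0.1, 0), function(mix) {
    xc_high <- if (mix == 0) xc_spec("pbe") else {
      a <- 0.25 * mix
      structure(list(name = "pbe0mix", a_hf = a, uses_grad = TRUE,
                     dispersion = "none",
                     fun = function(ra, rb, gaa, gab, gbb)
                       huzembed:::.pbe_x(ra, rb, gaa, gbb) +
                       huzembed:::.pbe_c(ra, rb, gaa, gab, gbb) / (1 - a)),
                class = "xc_spec")
    }
    emb <- solve_embedded_uks(part, pot, ctx, xc_high)
    abs(sum((emb$Da - D_A$Da) * pot$Va) + sum((emb$Db - D_A$Db) * pot$Vb))
  }, 0)
  expect_true(all(diff(corr) <= 1e-10))
  expect_lt(corr[4], 1e-9)
})
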