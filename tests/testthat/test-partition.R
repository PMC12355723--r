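# Localization and active/environment partitioning.

test_that("single occupied orbital localizes to itself up to sign", {
  ctx <- get_ctx("h2")
  r <- get_uks("h2")
  C1 <- r$Ca[, 1, drop = FALSE]
  loc <- localize_orbitals(C1, ctx, "spade", active_atoms = 1L)
  expect_equal(abs(loc$W), matrix(1), tolerance = 1e-12)
  expect_equal(abs(loc$L), abs(C1), tolerance = 1e-12)
})

test_that("Boys localization separates far-apart electron pairs", {
  m <- fixture("he_dimer", d = 8)
  ctx <- build_context(m)
  r <- solve_uks(m, ctx, "hf")
  loc <- localize_orbitals(r$Ca[, 1:2, drop = FALSE], ctx, "boys")
  SL <- ctx$S %*% loc$L
  for (i in 1:2) {
    pops <- vapply(1:2, function(a) {
      idx <- ctx$atom_ao_ranges[[a]]
      sum(SL[idx, i] * loc$L[idx, i])
    }, 0)
    expect_gt(max(pops), 0.999)
  }
  # the rotation is unitary and leaves the density invariant
  expect_equal(t(loc$W) %*% loc$W, diag(2), tolerance = 1e-10)
  expect_equal(tcrossprod(loc$L), r$Da, tolerance = 1e-12)
})

test_that("SPADE: descending spectrum, gap split, determinism", {
  m <- fixture("water_dimer")
  ctx <- cached("ctx_wd", build_context(m, grid_level = 1L))
  r <- cached("uks_wd", solve_uks(m, ctx, "hf"))
  C_occ <- r$Ca[, seq_len(r$n_occ[1]), drop = FALSE]
  p <- spade_partition(C_occ, ctx, active_atoms = 1:3)
  expect_true(all(diff(p$sigma) <= 1e-12))
  # one water monomer active: 5 of 10 occupied orbitals
  expect_equal(p$n_active, 5L)
  # identical inputs give identical partitions
  p2 <- spade_partition(C_occ, ctx, active_atoms = 1:3)
  expect_identical(p$active_idx, p2$active_idx)
  expect_equal(p$L, p2$L, tolerance = 0)
  # active = all atoms: empty environment
  pall <- spade_partition(C_occ, ctx, active_atoms = 1:6)
  expect_length(pall$env_idx, 0)
  # far-separated He2 with one active atom: exactly one active orbital
  hectx <- cached("ctx_he50", build_context(fixture("he_dimer", d = 50)))
  rhe <- solve_uks(fixture("he_dimer", d = 50), hectx, "hf")
  phe <- spade_partition(rhe$Ca[, 1:2, drop = FALSE], hectx, 1L)
  expect_equal(phe$n_active, 1L)
})

test_that("Mulliken selection: thresholds and population identities", {
  m <- fixture("water_dimer")
  ctx <- cached("ctx_wd", build_context(m, grid_level = 1L))
  r <- cached("uks_wd", solve_uks(m, ctx, "hf"))
  C_occ <- r$Ca[, seq_len(r$n_occ[1]), drop = FALSE]
  loc <- localize_orbitals(C_occ, ctx, "boys")
  # threshold 0 with every atom active: all orbitals selected
  sel0 <- mulliken_select(loc$L, ctx, 1:6, threshold = 0)
  expect_equal(sel0$n_active, ncol(C_occ))
  sel <- mulliken_select(loc$L, ctx, 1:3, threshold = 0.3)
  expect_equal(sel$n_active, 5L)
  # per-orbital populations over all atoms sum to one
  pop_all <- mulliken_select(loc$L, ctx, 1:6, threshold = 0.3)$populations
  expect_equal(unname(pop_all), rep(1, ncol(C_occ)), tolerance = 1e-10)
  # forced-active indices are respected
  self <- mulliken_select(loc$L, ctx, 1:3, threshold = 2,
                          force_active = 7L)
  expect_true(7L %in% self$active_idx)
})

test_that("subsystem densities: additivity, traces, completeness", {
  m <- fixture("water_dimer")
  ctx <- cached("ctx_wd", build_context(m, grid_level = 1L))
  r <- cached("uks_wd", solve_uks(m, ctx, "hf"))
  part <- partition_uks(r, ctx, active_atoms = 1:3)
  for (sp in c("a", "b")) {
    p <- part[[sp]]
    D_full <- if (sp == "a") r$Da else r$Db
    expect_equal(p$D_active + p$D_env, D_full, tolerance = 1e-10)
    expect_equal(sum(p$D_active * ctx$S), length(p$active_idx),
                 tolerance = 1e-8)
    expect_equal(sum(p$D_env * ctx$S), length(p$env_idx), tolerance = 1e-8)
    expect_setequal(c(p$active_idx, p$env_idx),
                    seq_len(length(p$active_idx) + length(p$env_idx)))
  }
  # localization leaves the supersystem energy unchanged
  Dl <- tcrossprod(part$a$L)
  expect_equal(uks_energy(list(Da = Dl, Db = Dl), ctx, "hf"),
               uks_energy(list(Da = r$Da, Db = r$Db), ctx, "hf"),
               tolerance = 1e-10)
})

test_that("restricted partitions keep open shells active", {
  m <- fixture("propyl_radical")
  ctx <- cached("ctx_propyl", build_context(m, grid_level = 1L))
  ro <- cached("ro_propyl", solve_ro(m, ctx, "hf"))
  part <- partition_roks(ro, ctx, active_atoms = c(3, 9, 10))
  expect_equal(part$n_open, 1L)
  expect_equal(sum(part$Do_A * ctx$S), 1, tolerance = 1e-8)
  # closed-shell additivity at double occupancy
  expect_equal(part$Dc_A + part$Dc_B, ro$dens$Dc, tolerance = 1e-10)
  # the open-shell orbital is localized on the radical carbon
  SL <- ctx$S %*% part$L_open
  pop_active <- sum(SL[unlist(ctx$atom_ao_ranges[c(3, 9, 10)]), 1] *
                      part$L_open[unlist(ctx$atom_ao_ranges[c(3, 9, 10)]), 1])
  expect_gt(pop_active, 0.8)
})

test_that("invalid partition requests fail with guidance", {
  ctx <- get_ctx("h2")
  r <- get_uks("h2")
  expect_error(spade_partition(r$Ca[, 1, drop = FALSE], ctx, integer(0)),
               "nonempty")
  expect_error(localize_orbitals(r$Ca[, 1, drop = FALSE], ctx, "spade"),
               "active_atoms")
})
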