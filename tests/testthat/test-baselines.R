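# Vacuum embedding, ONIOM-ME/EE, link atoms, charge fields, populations.

test_that("link atoms sit exactly 1.08 Angstrom from the active atom on the
          broken bond", {
  m <- fixture("ethane")
  ms <- cap_with_link_atoms(m, c(1, 3, 4, 5), rbind(c(1L, 2L)))
  expect_equal(nrow(ms$link_positions), 1L)
  link <- ms$link_positions[1, ]
  a <- m$coords[1, ]; b <- m$coords[2, ]
  expect_equal(sqrt(sum((link - a)^2)), 1.08, tolerance = 1e-12)
  # collinear with the cut bond
  u <- (b - a) / sqrt(sum((b - a)^2))
  expect_equal(link, a + 1.08 * u, tolerance = 1e-12)
  # geometry reproducible from the rule alone: bond along +x from C1
  # at the origin places the hydrogen at exactly (1.08, 0, 0) + C1
  m2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.53, 0, 0)))
  ms2 <- cap_with_link_atoms(m2, 1L, rbind(c(1L, 2L)), multiplicity = 2L)
  expect_equal(ms2$link_positions[1, ], c(1.08, 0, 0), tolerance = 1e-12)
  # no border pairs: model is the active subset unchanged
  ms0 <- cap_with_link_atoms(fixture("water_dimer"), 1:3)
  expect_equal(ms0$model$symbols, fixture("water_dimer")$symbols[1:3])
  # two cuts produce two link atoms
  mp <- fixture("propyl_radical")
  ms3 <- cap_with_link_atoms(mp, c(2, 7, 8), rbind(c(2L, 1L), c(2L, 3L)),
                             multiplicity = 1L)
  expect_equal(sum(ms3$model$symbols == "H"), 4L)
  # invalid pair is rejected
  expect_error(cap_with_link_atoms(m, c(1, 2), rbind(c(1L, 2L))), "border")
})

test_that("vacuum embedding limits", {
  # whole molecule active: equals the full high-level energy
  m <- fixture("water")
  ms <- cap_with_link_atoms(m, 1:3)
  e <- vacuum_embedding_energy(ms, "hf")
  expect_equal(e, get_uks("water")$energy, tolerance = 1e-8)
  # noncovalent split: equals the monomer energy at the dimer geometry
  dim_ <- fixture("water_dimer")
  msd <- cap_with_link_atoms(dim_, 1:3)
  ed <- vacuum_embedding_energy(msd, "hf")
  mono <- molecule(dim_$symbols[1:3], dim_$coords[1:3, ])
  emono <- solve_uks(mono, build_context(mono), "hf")$energy
  expect_equal(ed, emono, tolerance = 1e-9)
})

test_that("ONIOM telescoping identities", {
  m <- fixture("ethane")
  ms <- cap_with_link_atoms(m, c(1, 3, 4, 5), rbind(c(1L, 2L)),
                            multiplicity = 1L)
  o <- oniom_me(m, ms, "hf", "hf")
  expect_equal(o$energy, o$E_low_AB, tolerance = 1e-12)
  # model = whole molecule: E = E_high(AB)
  msw <- cap_with_link_atoms(m, seq_along(m$z))
  o2 <- oniom_me(m, msw, list(xc = "hf", correlation = "mp2"), "hf")
  ctx <- cached("ctx_ethane", build_context(m))
  r <- cached("uks_ethane", solve_uks(m, ctx, "hf"))
  expect_equal(o2$energy, r$energy + mp2_from_uks(r, ctx),
               tolerance = 1e-8)
  # hand-assembled three-term sum
  e1 <- solve_uks(m, build_context(m), "hf")$energy
  mm <- ms$model
  e2 <- solve_uks(mm, build_context(mm), "hf")$energy
  e3 <- vacuum_embedding_energy(ms, "pbe0", grid_level = 1L)
  o3 <- oniom_me(m, ms, "pbe0", "hf", grid_level = 1L)
  expect_equal(o3$energy, e1 - e2 + e3, tolerance = 1e-10)
})

test_that("charge field: border zeroing and residual redistribution", {
  m <- fixture("ester_radical")
  ms <- cap_with_link_atoms(m, c(5, 9, 10), rbind(c(5L, 3L)),
                            multiplicity = 2L)
  ctx <- cached("ctx_ester", build_context(m, grid_level = 1L))
  scf <- cached("uks_ester", solve_uks(m, ctx, "hf"))
  q <- iao_or_mulliken_charges(scf, ctx, "mulliken")
  expect_equal(sum(q), m$charge, tolerance = 1e-8)
  cf <- charge_field(q, ms)
  # zeroed border atom
  expect_true(all(cf$q[match(cf$zeroed, cf$env_atoms)] == 0))
  # field total equals parent charge minus model charge
  expect_equal(sum(cf$q), m$charge - ms$model$charge, tolerance = 1e-10)
})

test_that("ONIOM-EE reduces to ONIOM-ME as charges vanish and differs
          otherwise", {
  m <- fixture("ester_radical")
  ms <- cap_with_link_atoms(m, c(5, 9, 10), rbind(c(5L, 3L)),
                            multiplicity = 2L)
  ome <- oniom_me(m, ms, "hf", "hf")
  oee0 <- oniom_ee(m, ms, "hf", "hf", charge_scheme = "mulliken",
                   charge_scale = 0)
  expect_equal(oee0$energy, ome$energy, tolerance = 1e-12)
  oee <- oniom_ee(m, ms, "pbe0", "hf", charge_scheme = "mulliken",
                  grid_level = 1L)
  omep <- oniom_me(m, ms, "pbe0", "hf", grid_level = 1L)
  expect_gt(abs(oee$energy - omep$energy), 1e-6)
  # high = low telescopes even with charges present
  oeehl <- oniom_ee(m, ms, "hf", "hf", charge_scheme = "mulliken")
  expect_equal(oeehl$energy, oeehl$E_low_AB, tolerance = 1e-12)
})

test_that("point-charge integrals match the energy shift of a frozen
          density in an external field", {
  m <- fixture("water")
  pc <- list(xyz = rbind(c(5, 0, 0)), q = 1.0)
  ctx0 <- get_ctx("water")
  ctx1 <- build_context(m, point_charges = pc)
  r <- get_uks("water")
  D <- r$Da + r$Db
  # electronic shift: -Tr{D <1/|r-R|>}; nuclear shift: sum Z q / R
  Vpc <- point_charge_matrix(ctx0, pc$xyz, pc$q)
  de_elec <- -sum(D * Vpc)
  de_nuc <- ctx1$V_nn - ctx0$V_nn
  e0 <- uks_energy(list(Da = r$Da, Db = r$Db), ctx0, "hf") + ctx0$V_nn
  e1 <- uks_energy(list(Da = r$Da, Db = r$Db), ctx1, "hf") + ctx1$V_nn
  expect_equal(e1 - e0, de_elec + de_nuc, tolerance = 1e-10)
  # classical limit: far-away unit charge sees the molecular monopole
  # (neutral molecule): interaction ~ dipole/R^2, small but nonzero
  expect_lt(abs(de_elec + de_nuc), 0.05)
})

test_that("population analyses: symmetry, sum rule, electronegativity sign
          pattern", {
  h2ctx <- get_ctx("h2")
  rh2 <- get_uks("h2")
  for (scheme in c("mulliken", "iao")) {
    q <- iao_or_mulliken_charges(rh2, h2ctx, scheme)
    expect_equal(unname(q), c(0, 0), tolerance = 1e-8)
  }
  hf_mol <- molecule(c("H", "F"), rbind(c(0, 0, 0), c(0.92, 0, 0)))
  ctx <- build_context(hf_mol)
  r <- solve_uks(hf_mol, ctx, "hf")
  for (scheme in c("mulliken", "iao")) {
    q <- iao_or_mulliken_charges(r, ctx, scheme)
    expect_gt(q[1], 0)   # hydrogen positive
    expect_lt(q[2], 0)   # fluorine negative
    expect_equal(sum(q), 0, tolerance = 1e-8)
  }
})
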