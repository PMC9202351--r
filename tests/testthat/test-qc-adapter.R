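test_that("monomer spectra from exact diagonalization carry correctly signed transitions", {
  job <- h2_dimer_job(10, n_states = 3L, state_a = 0L)
  sA <- extract_spectrum(job, "A")
  expect_true(all(sA$transitions$energies > 0))   # ground reference: all up
  expect_equal(sA$transitions$reference_index, 0L)

  job1 <- h2_dimer_job(10, n_states = 3L, state_a = 1L)
  sE <- extract_spectrum(job1, "A")
  expect_equal(sum(sE$transitions$energies < 0), 1L)  # one de-excitation
  expect_equal(sum(sE$transitions$energies > 0), 1L)
  # the de-excitation energy is minus the partner's excitation energy
  expect_equal(min(sE$transitions$energies), -min(sA$transitions$energies),
               tolerance = 1e-12)
})

test_that("grid double-sum Coulomb couplings match the analytic integral oracle", {
  job <- h2_dimer_job(10, basis = "sg1", n_states = 2L)
  gA <- molecular_grid(job$coords_bohr[1:2, ], nr = 40, ntheta = 12, nphi = 24)
  gB <- molecular_grid(job$coords_bohr[3:4, ], nr = 40, ntheta = 12, nphi = 24)
  sA <- extract_spectrum(job, "A", grid = gA)
  sB <- extract_spectrum(job, "B", grid = gB)
  Wg <- coulomb_coupling_from_grids(sA, sB)
  Wa <- coulomb_coupling_analytic(sA, sB)
  expect_lt(abs(Wg$w[1, 1] - Wa$w[1, 1]) / abs(Wa$w[1, 1]), 1e-6)
  # all-zero density on one side gives an all-zero matrix
  sB0 <- sB
  sB0$densities <- sB0$densities * 0
  expect_true(all(coulomb_coupling_from_grids(sA, sB0)$w == 0))
})

test_that("far-separated point-like densities recover Coulomb's 1/R law", {
  # two unit 'charges': single-point density grids a distance R apart
  R <- 40
  mk <- function(z) list(densities = matrix(1, 1, 1),
                         grid = list(points = matrix(c(0, 0, z), 1, 3),
                                     weights = 1))
  W <- coulomb_coupling_from_grids(mk(0), mk(R))
  expect_equal(W$w[1, 1], 1 / R)
})

test_that("H2-H2 dispersion from exact spectra decays as R^-6", {
  Rs <- c(10, 15, 20, 25, 30)
  Es <- vapply(Rs, function(R) {
    job <- h2_dimer_job(R, n_states = 3L)
    a <- extract_spectrum(job, "A")
    b <- extract_spectrum(job, "B")
    W <- coulomb_coupling_analytic(a, b)
    dispersion_sos(a$transitions, b$transitions, W)$total
  }, numeric(1))
  expect_true(all(Es < 0))
  expect_lt(abs(loglog_slope(Rs, Es) - (-6)), 0.05)
})

test_that("the single-exciton de-excitation term is negative for an excited H2 partner", {
  # unequal bond lengths: otherwise the de-excitation on A is exactly resonant
  # with the partner's excitation (the degenerate case the theory excludes)
  job <- h2_dimer_job(10, n_states = 2L, state_a = 1L, state_b = 0L,
                      bond_bohr = 1.4, bond_bohr_b = 1.2)
  a <- extract_spectrum(job, "A")
  b <- extract_spectrum(job, "B")
  W <- coulomb_coupling_analytic(a, b)
  eps <- single_exciton_non_cp(a$transitions, b$transitions, W)
  expect_lt(eps, 0)
  # and it equals the (down, up) block of the full breakdown on the same inputs
  b_full <- dispersion_sos(a$transitions, b$transitions, W)
  expect_equal(eps, b_full$part_down_up)
  expect_equal(eps, b_full$non_cp_single_exciton)
})

test_that("counterpoise monomer densities integrate to the electron count", {
  job <- h2_dimer_job(10)
  grid <- molecular_grid(job$coords_bohr, nr = 40, ntheta = 8, nphi = 16)
  dg <- densities_for_revv10(job, "monomerA", "GS", grid = grid)
  expect_lt(abs(sum(dg$weights * dg$rho) - 2), 1e-4)
  # excited-state density integrates to the same electron count
  job1 <- h2_dimer_job(10, state_a = 1L)
  de <- densities_for_revv10(job1, "monomerA", "ES", grid = grid)
  expect_lt(abs(sum(de$weights * de$rho) - 2), 1e-4)
  # far separation: dimer density approaches the sum of CP monomer densities
  # pointwise (the residual is genuine intermonomer correlation, falling off
  # with the coupling as R^-3)
  jf <- h2_dimer_job(150)
  gf <- molecular_grid(jf$coords_bohr, nr = 30, ntheta = 6, nphi = 12)
  dAB <- densities_for_revv10(jf, "dimer", "GS", grid = gf)
  dA <- densities_for_revv10(jf, "monomerA", "GS", grid = gf)
  dB <- densities_for_revv10(jf, "monomerB", "GS", grid = gf)
  expect_lt(max(abs(dAB$rho - dA$rho - dB$rho)), 1e-8)
})

test_that("the supermolecular interaction energy vanishes at 100 angstrom", {
  r_ang <- bohr_to_angstrom(1.4)
  job <- dimer_job(c("H", "H", "H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, r_ang),
                         c(0, 0, 100), c(0, 0, 100 + r_ang)),
                   1:2, 3:4)
  expect_lt(abs(hartree_to_kcal(supermolecular_interaction(job))), 1e-6)
})

test_that("job validation catches bad partitions and state indices", {
  expect_error(dimer_job("H", matrix(0, 1, 3), 1, 1), "disjoint")
  expect_error(dimer_job(c("H", "H"), matrix(0, 2, 3), 1, 2,
                         n_states = 2, state_a = 2), "n_states")
  expect_error(dimer_job(c("C", "H"), matrix(c(0, 0, 0, 0, 0, 1), 2,
                                             byrow = TRUE), 1, 2),
               "H and He")
})
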