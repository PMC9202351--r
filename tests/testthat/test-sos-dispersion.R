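test_that("closed two-level forms are reproduced with the right sign pattern", {
  g1 <- make_two_level_monomer(1.0)
  w <- coupling_matrix(matrix(0.1))
  b <- dispersion_sos(g1, g1, w)
  expect_equal(b$total, -0.005)          # -w^2/(a+b)
  expect_equal(b$part_up_up, -0.005)
  expect_equal(b$part_down_down, 0)
  expect_equal(b$part_up_down, 0)
  expect_equal(b$part_down_up, 0)

  # single exciton: A excited (down -0.3), B ground (up +0.4)
  ae <- make_two_level_monomer(0.3, excited = TRUE)
  bg <- make_two_level_monomer(0.4)
  b2 <- dispersion_sos(ae, bg, coupling_matrix(matrix(0.01)))
  expect_equal(b2$total, -0.001)         # -1e-4 / 0.1
  expect_equal(b2$part_down_up, -0.001)
  expect_equal(b2$non_cp_single_exciton, -0.001)

  # two excitons: both transitions down -> repulsive part
  be <- make_two_level_monomer(0.4, excited = TRUE)
  b3 <- dispersion_sos(ae, be, coupling_matrix(matrix(0.01)))
  expect_equal(b3$part_down_down, 1e-4 / 0.7)
  expect_gt(b3$part_down_down, 0)
})

test_that("ground-state reduction and decomposition closure hold on random dimers", {
  for (seed in c(1, 5, 23, 77)) {
    d <- random_model_dimer(seed)
    b <- dispersion_sos(d$A, d$B, d$W)
    parts <- b$part_up_up + b$part_down_down + b$part_up_down + b$part_down_up
    expect_lt(abs(b$total - parts), 1e-12 * max(abs(b$total), 1e-30))
    expect_lte(b$part_up_up, 0)
    expect_gte(b$part_down_down, 0)
  }
  # both references ground: everything in (up, up), total attractive
  A <- make_random_spectrum(5, 0, seed = 2)
  B <- make_random_spectrum(4, 0, seed = 3)
  b <- dispersion_sos(A, B, dipole_coupling(A, B, 10))
  expect_identical(b$part_down_down, 0)
  expect_identical(b$part_up_down, 0)
  expect_identical(b$part_down_up, 0)
  expect_lte(b$total, 0)
})

test_that("swapping the monomers preserves the total and swaps the mixed parts", {
  d <- random_model_dimer(31)
  b1 <- dispersion_sos(d$A, d$B, d$W)
  b2 <- dispersion_sos(d$B, d$A, coupling_matrix(t(d$W$w)))
  expect_equal(b2$total, b1$total)
  expect_equal(b2$part_up_down, b1$part_down_up)
  expect_equal(b2$part_down_up, b1$part_up_down)
  expect_equal(b2$part_up_up, b1$part_up_up)
  expect_equal(b2$part_down_down, b1$part_down_down)
})

test_that("dispersion from dipole couplings decays exactly as R^-6", {
  d <- random_model_dimer(9)
  tot <- function(R) dispersion_sos(d$A, d$B,
                                    dipole_coupling(d$A, d$B, R))$total
  expect_lt(abs(tot(20) / tot(10) - 2^-6), 1e-10 * 2^-6)
})

test_that("near-resonant transition pairs raise an error naming the pair", {
  A <- transition_set(c(-0.5, 0.3), reference_index = 1L)
  B <- transition_set(c(0.5 + 1e-8, 0.9))
  W <- coupling_matrix(matrix(0.01, 2, 2))
  expect_error(dispersion_sos(A, B, W), "resonance.*dE\\^A_1 \\+ dE\\^B_1")
})

test_that("the single-exciton de-excitation term matches the (down, up) part", {
  job_like <- list(
    A = make_random_spectrum(4, 1, seed = 10),
    B = make_random_spectrum(5, 0, seed = 11)
  )
  W <- dipole_coupling(job_like$A, job_like$B, 12)
  eps <- single_exciton_non_cp(job_like$A, job_like$B, W)
  b <- dispersion_sos(job_like$A, job_like$B, W)
  expect_equal(eps, b$part_down_up)
  expect_equal(eps, b$non_cp_single_exciton)
  # zero coupling row for the de-excitation -> exactly zero
  W0 <- W$w; W0[job_like$A$labels == "down", ] <- 0
  expect_identical(single_exciton_non_cp(job_like$A, job_like$B,
                                         coupling_matrix(W0)), 0)
  expect_error(single_exciton_non_cp(job_like$B, job_like$A,
                                     coupling_matrix(t(W$w))),
               "reference_index")
})
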