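two_level_path <- function(gap1 = 1, gap0 = 1, coupling = 0) {
  # H0 = diag(0, gap0); H1 adds gap change and an off-diagonal mixing
  alpha_path(diag(c(0, gap0)),
             matrix(c(0, coupling, coupling, gap1), 2),
             dipole_op = matrix(c(0, 1, 1, 0), 2))
}

test_that("alpha spectra are exact at the path ends", {
  p <- two_level_path(gap1 = 1, gap0 = 1, coupling = 0.1)
  expect_equal(alpha_spectrum(p, 0)$energies, 1)
  # 2x2 closed form at alpha = 1: gap sqrt(1 + 4*0.1^2)/... = sqrt(1.04)
  expect_equal(alpha_spectrum(p, 1)$energies, sqrt(1.04), tolerance = 1e-12)
})

test_that("reference tracking follows continuity and flags ambiguous crossings", {
  # the endpoint is a near-degenerate pair whose eigenvectors are rotated 45
  # degrees against the H0 basis: both overlaps are ~0.707 and tracking must
  # refuse to pick one
  H0 <- diag(c(0, 1))
  H1 <- matrix(c(0.5, 1e-9, 1e-9, 0.5), 2)
  p <- alpha_path(H0, H1, reference = 0L)
  expect_error(alpha_spectrum(p, 1), "ambiguous")
  # away from the crossing, tracking is unambiguous and ordering-based
  expect_equal(alpha_spectrum(p, 0.5)$reference_index, 0L)
})

test_that("alpha-independent paths collapse the AC integral onto plain SOS", {
  p <- two_level_path(gap1 = 1, gap0 = 1)
  cf <- make_dipole_coupling_fn(10)
  ts <- alpha_spectrum(p, 0)
  sos <- dispersion_sos(ts, ts, cf(ts, ts))$total
  ac <- dispersion_ac2(p, p, cf, n_alpha = 8)
  expect_equal(ac, sos, tolerance = 1e-10)
  expect_equal(dispersion_uncoupled(p, p, cf), ac, tolerance = 1e-10)
})

test_that("alpha quadrature matches a dense-grid integration of the same integrand", {
  pB <- two_level_path(gap1 = 1.2, gap0 = 1)    # a(alpha) = 1 + 0.2 alpha
  pC <- two_level_path(gap1 = 1, gap0 = 1)
  cf <- make_dipole_coupling_fn(10)
  ac <- dispersion_ac2(pB, pC, cf, n_alpha = 8)
  al <- seq(0, 1, length.out = 5001)
  f <- ac_dispersion_integrand(pB, pC, cf, al)
  dense <- sum((f[-1] + f[-length(f)]) / 2 * diff(al))
  expect_lt(abs(ac - dense) / abs(dense), 1e-8)
  # UC freezes the gap at its alpha = 0 value
  expect_equal(dispersion_uncoupled(pB, pC, cf), -(2e-3)^2 / 2,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ac, dispersion_uncoupled(pB, pC, cf))))
})

test_that("zero-overlap consistency: the AC value lands on the fully correlated SOS", {
  pB <- two_level_path(gap1 = 1.2, gap0 = 1, coupling = 0.05)
  pC <- two_level_path(gap1 = 0.8, gap0 = 1, coupling = 0.02)
  cf <- make_dipole_coupling_fn(12)
  ac <- dispersion_ac2(pB, pC, cf, n_alpha = 12)
  tsB <- alpha_spectrum(pB, 1)
  tsC <- alpha_spectrum(pC, 1)
  sos1 <- dispersion_sos(tsB, tsC, cf(tsB, tsC))$total
  # convergence trend: refining the quadrature shrinks the gap to the
  # alpha = 1 second-order value
  ac_coarse <- dispersion_ac2(pB, pC, cf, n_alpha = 4)
  expect_lte(abs(ac - sos1), abs(ac_coarse - sos1) + 1e-15)
  expect_lt(abs(ac - sos1) / abs(sos1), 1e-6)
})

test_that("AC dispersion inherits the R^-6 law from dipole couplings", {
  p <- two_level_path(gap1 = 1.1, gap0 = 1)
  e1 <- dispersion_ac2(p, p, make_dipole_coupling_fn(10), n_alpha = 6)
  e2 <- dispersion_ac2(p, p, make_dipole_coupling_fn(20), n_alpha = 6)
  expect_equal(e2 / e1, 2^-6, tolerance = 1e-9)
})

test_that("alpha-path JSON fixtures round-trip", {
  p <- two_level_path(gap1 = 1.2, gap0 = 1, coupling = 0.03)
  f <- withr::local_tempfile(fileext = ".json")
  write_alpha_path(p, f)
  p2 <- read_alpha_path(f)
  expect_equal(p2$H0, p$H0)
  expect_equal(p2$H1, p$H1)
  expect_equal(p2$dipole_op, p$dipole_op)
  expect_equal(alpha_spectrum(p2, 0.7)$energies,
               alpha_spectrum(p, 0.7)$energies)
})
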