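test_that("local frequency and damping functions obey their scaling laws", {
  # uniform density: gradient term vanishes, omega0 = sqrt(4 pi rho / 3)
  expect_equal(vv10_omega0(0.3, 0), sqrt(4 * pi * 0.3 / 3))
  # doubling C doubles omega_g^2 exactly
  w1 <- vv10_omega0(0.2, 0.5, C = 0.013)^2 - 4 * pi * 0.2 / 3
  w2 <- vv10_omega0(0.2, 0.5, C = 0.026)^2 - 4 * pi * 0.2 / 3
  expect_equal(w2, 2 * w1)
  # kappa: linear in b, sixth-root in rho
  expect_equal(vv10_kappa(0.4, b = 5.68), 2 * vv10_kappa(0.4, b = 2.84))
  expect_equal(vv10_kappa(64 * 0.01) / vv10_kappa(0.01), 2)
  # closed form
  expect_equal(vv10_kappa(0.4, b = 2.84),
               2.84 * (3 * pi / 2) * (0.4 / (9 * pi))^(1 / 6))
  # density floor: skipped, not NaN
  expect_true(is.na(vv10_omega0(0, 0)))
  expect_true(is.na(vv10_kappa(1e-12)))
})

test_that("the nonlocal energy is nonpositive and matches a brute-force pair loop", {
  g <- gaussian_blob_grid(c(0, 0, 0), rho0 = 5, a = 1.5, n = 5)
  e <- vv10_nonlocal_energy(g, chunk = 7L)  # odd chunking must not matter
  expect_lt(e, 0)
  # independent O(N^2) reference: plain double loop over all pairs
  p <- vv10_params()
  w0 <- vv10_omega0(g$rho, g$grad_rho, C = p$C)
  kap <- vv10_kappa(g$rho, b = p$b)
  n <- nrow(g$points)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((g$points[i, ] - g$points[j, ])^2)
    gi <- w0[i] * r2 + kap[i]
    gj <- w0[j] * r2 + kap[j]
    acc <- acc + g$weights[i] * g$rho[i] * g$weights[j] * g$rho[j] *
      (-1.5 / (gi * gj * (gi + gj)))
  }
  expect_equal(e, acc / 2, tolerance = 1e-12)
})

test_that("a single-point grid returns the finite kernel self-term", {
  g1 <- density_grid(matrix(0, 1, 3), 1.0, 0.5, 0)
  k <- vv10_kappa(0.5)
  expect_equal(vv10_nonlocal_energy(g1), 0.5 * 0.25 * (-3 / (4 * k^3)))
  # empty grid: zero with a warning
  g0 <- density_grid(matrix(0, 1, 3), 1.0, 0, 0)
  expect_warning(e0 <- vv10_nonlocal_energy(g0), "density floor")
  expect_identical(e0, 0)
})

test_that("|E_nl| decreases monotonically with the damping parameter b", {
  g <- gaussian_blob_grid(c(0, 0, 0), rho0 = 8, a = 2, n = 6)
  es <- vapply(c(2.0, 2.84, 4.0, 5.9),
               function(b) vv10_nonlocal_energy(g, vv10_params(b = b)),
               numeric(1))
  expect_true(all(diff(abs(es)) < 0))
  expect_true(all(es < 0))
})

test_that("counterpoise interaction energy is exact for vanishing and additive densities", {
  gr <- blob_dimer_grids(R = 20, n = 8)
  # rho_B = 0: exact cancellation to machine precision
  zero <- density_grid(gr$dimer$points, gr$dimer$weights,
                       numeric(nrow(gr$dimer$points)),
                       numeric(nrow(gr$dimer$points)))
  expect_identical(vv10_interaction_energy(gr$monoA, gr$monoA, zero), 0)
  # rho_AB = rho_A + rho_B with disjoint far supports: cross term only, < 0
  e <- vv10_interaction_energy(gr$dimer, gr$monoA, gr$monoB)
  expect_lt(e, 0)
  # algebraic cross-term oracle: sum_{i in A, j in B} q_i Phi_ij q_j
  p <- vv10_params()
  d <- gr$dimer
  w0 <- vv10_omega0(d$rho, d$grad_rho, C = p$C)
  kap <- vv10_kappa(d$rho, b = p$b)
  ia <- which(gr$monoA$rho >= 1e-10)  # same density floor as the engine
  ib <- which(gr$monoB$rho >= 1e-10)
  acc <- 0
  for (i in ia) for (j in ib) {
    r2 <- sum((d$points[i, ] - d$points[j, ])^2)
    gi <- w0[i] * r2 + kap[i]
    gj <- w0[j] * r2 + kap[j]
    acc <- acc + d$weights[i] * d$rho[i] * d$weights[j] * d$rho[j] *
      (-1.5 / (gi * gj * (gi + gj)))
  }
  # the counterpoise difference of ~0.03-hartree totals leaves a ~1e-7 cross
  # term, so agreement is limited by summation roundoff under cancellation
  expect_lt(abs(e - acc) / abs(acc), 1e-7)
  # mismatched grids are rejected
  off <- gr$monoA
  off$points[1, 1] <- off$points[1, 1] + 1e-9
  expect_error(vv10_interaction_energy(gr$dimer, off, gr$monoB), "shared grid")
})

test_that("the far cross term decays with the sixth power of the separation", {
  Rs <- seq(15, 40, by = 5)
  Es <- vapply(Rs, function(R) {
    gr <- blob_dimer_grids(R, n = 10)
    vv10_interaction_energy(gr$dimer, gr$monoA, gr$monoB)
  }, numeric(1))
  expect_lt(abs(loglog_slope(Rs, Es) - (-6)), 0.05)
})

test_that("cube files round-trip and feed the functional", {
  # small uniform box holding a Gaussian blob
  n <- c(9, 9, 9)
  h <- 0.8
  org <- -0.8 * 4
  idx <- expand.grid(k = 1:n[3], j = 1:n[2], i = 1:n[1])
  pts <- cbind(org + (idx$i - 1) * h, org + (idx$j - 1) * h,
               org + (idx$k - 1) * h)
  rho <- 2 * exp(-1.1 * rowSums(pts^2))
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(f, origin = rep(org, 3), steps = diag(h, 3), dims = n,
             values = rho, atoms = data.frame(Z = 1, x = 0, y = 0, z = 0))
  cb <- read_cube(f)
  expect_equal(cb$dims, as.integer(n))
  # cube stores 6 significant digits
  expect_lt(max(abs(as.numeric(cb$values) - rho)), 1e-4)
  dg <- cube_to_density_grid(cb)
  expect_equal(nrow(dg$points), prod(n))
  # voxel weights integrate the density like a Riemann sum
  expect_equal(sum(dg$weights * dg$rho), sum(as.numeric(cb$values)) * h^3,
               tolerance = 1e-12)
  expect_lt(vv10_nonlocal_energy(dg), 0)
})
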