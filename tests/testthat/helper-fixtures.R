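# Seeded model-dimer fixtures used across the suite.

random_model_dimer <- function(seed, separation = 10) {
  set.seed(seed)
  nA <- sample(2:6, 1)
  nB <- sample(2:6, 1)
  IA <- sample(0:(nA - 1), 1)
  IB <- sample(0:(nB - 1), 1)
  A <- make_random_spectrum(nA, IA, seed = seed * 2 + 1)
  B <- make_random_spectrum(nB, IB, seed = seed * 2 + 2)
  list(A = A, B = B, W = dipole_coupling(A, B, separation = separation))
}

# collinear H2...H2 dimer job for the exact-diagonalization backend; distinct
# bond lengths keep the two excitation manifolds off resonance
h2_dimer_job <- function(separation_bohr, basis = "sto-3g", n_states = 3L,
                         state_a = 0L, state_b = 0L, bond_bohr = 1.4,
                         bond_bohr_b = bond_bohr) {
  ra <- bohr_to_angstrom(bond_bohr)
  rb <- bohr_to_angstrom(bond_bohr_b)
  s <- bohr_to_angstrom(separation_bohr)
  dimer_job(c("H", "H", "H", "H"),
            rbind(c(0, 0, 0), c(0, 0, ra), c(0, 0, s), c(0, 0, s + rb)),
            monomer_a = 1:2, monomer_b = 3:4, basis = basis,
            n_states = n_states, state_a = state_a, state_b = state_b)
}

# two Gaussian blobs on one shared (concatenated) grid, as dimer + CP monomers
blob_dimer_grids <- function(R, rho0 = 10, a = 2, n = 10L) {
  gA <- gaussian_blob_grid(c(0, 0, 0), rho0, a, n)
  gB <- gaussian_blob_grid(c(0, 0, R), rho0, a, n)
  pts <- rbind(gA$points, gB$points)
  w <- c(gA$weights, gB$weights)
  zero <- numeric(nrow(gA$points))
  list(
    dimer = density_grid(pts, w, c(gA$rho, gB$rho),
                         c(gA$grad_rho, gB$grad_rho)),
    monoA = density_grid(pts, w, c(gA$rho, zero), c(gA$grad_rho, zero)),
    monoB = density_grid(pts, w, c(zero, gB$rho), c(zero, gB$grad_rho))
  )
}

loglog_slope <- function(R, E) {
  unname(coef(lm(log(abs(E)) ~ log(R)))[2])
}
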