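#' Dimer job specification for the exact-diagonalization backend
#'
#' Describes a dimer of small (hydrogenic) molecules for the built-in s-orbital
#' full-CI engine: geometry, the partition of atoms into monomers A and B, the
#' basis, how many CI roots to keep per monomer, and which root is the
#' unperturbed reference on each side (`state_a = 1`, `state_b = 0` is the
#' single-exciton setup). Monomer quantities are always computed in the *full
#' dimer basis* (partner atoms become ghost centers), the Boys-Bernardi
#' counterpoise convention.
#'
#' @param elements character vector of element symbols (H, He).
#' @param coords n x 3 matrix of coordinates in angstrom (converted to bohr
#'   once, at this boundary).
#' @param monomer_a,monomer_b integer index vectors partitioning the atoms.
#' @param basis `"sto-3g"` or `"sg1"` (one s Gaussian per atom).
#' @param n_states singlet CI roots retained per monomer.
#' @param state_a,state_b reference singlet root (0-based) per monomer.
#' @return Object of class `dimer_job`.
#' @export
dimer_job <- function(elements, coords, monomer_a, monomer_b,
                      basis = "sto-3g", n_states = 3L,
                      state_a = 0L, state_b = 0L) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  elements <- as.character(elements)
  stopifnot(nrow(coords) == length(elements))
  element_z(elements)                 # validate supported elements early
  monomer_a <- as.integer(monomer_a); monomer_b <- as.integer(monomer_b)
  if (length(intersect(monomer_a, monomer_b)) > 0L ||
      !setequal(c(monomer_a, monomer_b), seq_along(elements))) {
    stop("monomer partition must cover all atoms disjointly")
  }
  n_states <- as.integer(n_states)
  if (state_a >= n_states || state_b >= n_states) {
    stop("state indices must be < n_states")
  }
  structure(list(elements = elements, coords_bohr = angstrom_to_bohr(coords),
                 monomer_a = monomer_a, monomer_b = monomer_b, basis = basis,
                 n_states = n_states, state_a = as.integer(state_a),
                 state_b = as.integer(state_b)),
            class = "dimer_job")
}

# full-CI solution for one monomer in the dimer (ghost) basis
monomer_fci <- function(job, monomer = c("A", "B")) {
  monomer <- match.arg(monomer)
  own <- if (monomer == "A") job$monomer_a else job$monomer_b
  shells <- build_shells(job$elements, job$coords_bohr, job$basis)
  charges <- element_z(job$elements)
  charges[-own] <- 0L                  # ghost partner atoms: basis, no charge
  ints <- ao_integrals(shells, charges, job$coords_bohr)
  h <- ints$T + ints$V
  C <- core_orbitals(ints$S, h)
  h_mo <- t(C) %*% h %*% C
  eri_mo <- eri_mo_transform(ints$eri, C)
  ne <- sum(charges)
  if (ne %% 2L != 0L) stop("the adapter handles closed-shell (singlet) monomers")
  real_pos <- job$coords_bohr[own, , drop = FALSE]
  zr <- element_z(job$elements[own])
  e_nuc <- 0
  if (length(own) > 1L) {
    for (i in seq_along(own)[-1L]) for (j in seq_len(i - 1L)) {
      e_nuc <- e_nuc + zr[i] * zr[j] /
        sqrt(sum((real_pos[i, ] - real_pos[j, ])^2))
    }
  }
  fci <- fci_solve(h_mo, eri_mo, ne %/% 2L, ne %/% 2L, e_nuc = e_nuc)
  list(fci = fci, C = C, shells = shells, ints = ints, charges = charges)
}

#' Monomer spectrum and transition densities from exact diagonalization
#'
#' Solves the monomer full-CI problem in the full dimer basis (counterpoise
#' ghosts on the partner), keeps the lowest `n_states` singlet roots, and
#' forms signed transition energies relative to the chosen reference root
#' together with AO-basis transition one-particle density matrices. When a
#' `grid` is supplied, the transition densities are also tabulated on it.
#'
#' @param job a [dimer_job()].
#' @param monomer `"A"` or `"B"`.
#' @param grid optional list with `points` (and `weights`), e.g. from
#'   [molecular_grid()], on which transition densities are tabulated.
#' @param singlet_only keep only S^2 ~ 0 roots (default TRUE).
#' @return Object of class `monomer_spectrum`: `transitions` (a
#'   [transition_set()]), `gammas` (list of AO transition 1-RDMs), `densities`
#'   (N x n_transitions matrix, if `grid` given), `grid`, `state_energies`,
#'   and the backend objects needed by the coupling routines.
#' @export
extract_spectrum <- function(job, monomer = c("A", "B"), grid = NULL,
                             singlet_only = TRUE) {
  monomer <- match.arg(monomer)
  ref_idx <- if (monomer == "A") job$state_a else job$state_b
  mf <- monomer_fci(job, monomer)
  keep <- if (singlet_only) which(mf$fci$s2 < 0.1) else
    seq_along(mf$fci$energies)
  if (length(keep) < job$n_states) {
    stop("not enough singlet roots in this basis for the requested n_states")
  }
  roots <- keep[seq_len(job$n_states)]
  energies <- mf$fci$energies[roots]
  if (ref_idx + 1L > length(roots)) stop("reference root not available")
  ref_root <- roots[ref_idx + 1L]
  dE <- energies - energies[ref_idx + 1L]
  tr_roots <- roots[seq_along(roots) != (ref_idx + 1L)]
  if (any(abs(dE[-(ref_idx + 1L)]) < 1e-10)) stop("degenerate reference state")
  gammas <- lapply(tr_roots, function(rt) {
    g_mo <- fci_transition_1rdm(mf$fci, ref_root, rt)
    mf$C %*% g_mo %*% t(mf$C)
  })
  densities <- NULL
  if (!is.null(grid)) {
    av <- ao_values(mf$shells, grid$points)$vals
    densities <- vapply(gammas, function(g) {
      rowSums((av %*% g) * av)
    }, numeric(nrow(grid$points)))
  }
  ts <- transition_set(dE[seq_along(dE) != (ref_idx + 1L)],
                       reference_index = ref_idx)
  structure(list(transitions = ts, gammas = gammas, densities = densities,
                 grid = grid, state_energies = energies,
                 backend = mf, monomer = monomer),
            class = "monomer_spectrum")
}

#' Coulomb couplings from gridded transition densities
#'
#' Double quadrature sum `w_{mu,nu} = sum_{ij} wA_i rhoA_mu(r_i) rhoB_nu(r_j)
#' wB_j / |r_i - r_j|` over the two monomers' grids. The grids must be
#' disjoint enough that no point pair coincides (separated monomers).
#'
#' @param specA,specB `monomer_spectrum` objects carrying gridded densities.
#' @param chunk points per vectorized block.
#' @return A [coupling_matrix()] with provenance `"grid_densities"`.
#' @seealso [coulomb_coupling_analytic()] for the integral-based oracle.
#' @export
coulomb_coupling_from_grids <- function(specA, specB, chunk = 512L) {
  if (is.null(specA$densities) || is.null(specB$densities)) {
    stop("both spectra must carry gridded transition densities")
  }
  pA <- specA$grid$points; wA <- specA$grid$weights
  pB <- specB$grid$points; wB <- specB$grid$weights
  qA <- specA$densities * wA        # column-wise: wA_i rhoA_mu(i)
  qB <- specB$densities * wB
  nA <- nrow(pA)
  W <- matrix(0, ncol(qA), ncol(qB))
  for (i0 in seq(1L, nA, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nA)
    d2 <- outer(rowSums(pA[ii, , drop = FALSE]^2), rowSums(pB^2), `+`) -
      2 * pA[ii, , drop = FALSE] %*% t(pB)
    d <- sqrt(pmax(d2, 0))
    if (any(d == 0)) stop("coincident grid points between the two monomers")
    W <- W + t(qA[ii, , drop = FALSE]) %*% ((1 / d) %*% qB)
  }
  coupling_matrix(W, provenance = "grid_densities")
}

#' Coulomb couplings from analytic two-electron integrals
#'
#' Exact Coulomb couplings between transition densities by contraction of the
#' AO electron-repulsion integrals:
#' `w_{mu,nu} = sum_{abcd} gammaA_ab gammaB_cd (ab|cd)`. Both monomers share
#' the dimer AO basis (counterpoise), so one ERI tensor serves both sides.
#' This is the integral oracle against which the grid double sum is validated.
#'
#' @inheritParams coulomb_coupling_from_grids
#' @return A [coupling_matrix()] (provenance `"grid_densities"`, as these are
#'   density-based couplings, merely integrated exactly).
#' @export
coulomb_coupling_analytic <- function(specA, specB) {
  eri <- specA$backend$ints$eri
  n <- dim(eri)[1]
  eri2 <- matrix(eri, n * n, n * n)     # (ab),(cd)
  W <- matrix(0, length(specA$gammas), length(specB$gammas))
  for (mu in seq_along(specA$gammas)) {
    ga <- as.numeric(specA$gammas[[mu]])
    for (nu in seq_along(specB$gammas)) {
      gb <- as.numeric(specB$gammas[[nu]])
      W[mu, nu] <- as.numeric(ga %*% eri2 %*% gb)
    }
  }
  coupling_matrix(W, provenance = "grid_densities")
}

#' State densities on a shared dimer grid for the nonlocal functional
#'
#' Tabulates the electron density (and its gradient magnitude) of the dimer or
#' of one counterpoise monomer, in the requested CI root, on one shared
#' dimer-centered molecular quadrature grid — the inputs of
#' [vv10_interaction_energy()]. The dimer calculation requires both monomers'
#' electrons (full-CI on the dimer); monomer targets use ghost partners.
#'
#' @param job a [dimer_job()].
#' @param target `"dimer"`, `"monomerA"` or `"monomerB"`.
#' @param state `"GS"` or `"ES"` (for monomer targets, the monomer's reference
#'   root; the dimer ES root is the singlet root matching the excited monomer).
#' @param grid optional precomputed [molecular_grid()]; built from the dimer
#'   geometry if omitted.
#' @param nr,ntheta,nphi grid sizes when the grid is built here.
#' @return A [density_grid()].
#' @export
densities_for_revv10 <- function(job, target = c("dimer", "monomerA", "monomerB"),
                                 state = c("GS", "ES"), grid = NULL,
                                 nr = 35L, ntheta = 8L, nphi = 16L) {
  target <- match.arg(target)
  state <- match.arg(state)
  if (is.null(grid)) {
    grid <- molecular_grid(job$coords_bohr, nr = nr, ntheta = ntheta, nphi = nphi)
  }
  shells <- build_shells(job$elements, job$coords_bohr, job$basis)
  charges <- element_z(job$elements)
  if (target == "monomerA") charges[-job$monomer_a] <- 0L
  if (target == "monomerB") charges[-job$monomer_b] <- 0L
  ints <- ao_integrals(shells, charges, job$coords_bohr)
  h <- ints$T + ints$V
  C <- core_orbitals(ints$S, h)
  eri_mo <- eri_mo_transform(ints$eri, C)
  ne <- sum(charges)
  fci <- fci_solve(t(C) %*% h %*% C, eri_mo, ne %/% 2L, ne %/% 2L)
  singlets <- which(fci$s2 < 0.1)
  root_pos <- if (state == "GS") 1L else {
    es_idx <- switch(target, dimer = max(job$state_a, job$state_b),
                     monomerA = job$state_a, monomerB = job$state_b)
    es_idx + 1L
  }
  root <- singlets[root_pos]
  g_ao <- C %*% fci_transition_1rdm(fci, root, root) %*% t(C)
  av <- ao_values(shells, grid$points, gradient = TRUE)
  rho <- rowSums((av$vals %*% g_ao) * av$vals)
  gvx <- 2 * rowSums((av$vals %*% g_ao) * av$gx)
  gvy <- 2 * rowSums((av$vals %*% g_ao) * av$gy)
  gvz <- 2 * rowSums((av$vals %*% g_ao) * av$gz)
  density_grid(grid$points, grid$weights, pmax(rho, 0),
               sqrt(gvx^2 + gvy^2 + gvz^2))
}

#' Supermolecular full-CI interaction energy with counterpoise correction
#'
#' `E_int = E(AB) - E(A, ghost B) - E(B, ghost A)`, all terms full CI in the
#' dimer basis. Used as the size-consistency diagnostic: at very large
#' separations the interaction energy must vanish.
#'
#' @param job a [dimer_job()] (ground states).
#' @return Interaction energy in hartree.
#' @export
supermolecular_interaction <- function(job) {
  shells <- build_shells(job$elements, job$coords_bohr, job$basis)
  charges <- element_z(job$elements)
  full_energy <- function(ch) {
    ints <- ao_integrals(shells, ch, job$coords_bohr)
    h <- ints$T + ints$V
    C <- core_orbitals(ints$S, h)
    ne <- sum(ch)
    pos <- job$coords_bohr[ch > 0, , drop = FALSE]
    z <- ch[ch > 0]
    e_nuc <- 0
    if (length(z) > 1L) {
      for (i in seq_along(z)[-1L]) for (j in seq_len(i - 1L)) {
        e_nuc <- e_nuc + z[i] * z[j] / sqrt(sum((pos[i, ] - pos[j, ])^2))
      }
    }
    fci <- fci_solve(t(C) %*% h %*% C, eri_mo_transform(ints$eri, C),
                     ne %/% 2L, ne %/% 2L, e_nuc = e_nuc)
    fci$energies[1L]
  }
  chA <- charges; chA[-job$monomer_a] <- 0L
  chB <- charges; chB[-job$monomer_b] <- 0L
  full_energy(charges) - full_energy(chA) - full_energy(chB)
}
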