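#' Adiabatic-connection path for a model monomer
#'
#' The coupling-constant family `H(alpha) = H0 + alpha (H1 - H0)` links an
#' uncorrelated zeroth-order monomer Hamiltonian `H0` (alpha = 0) to the fully
#' interacting `H1` (alpha = 1). The reference state is defined by *continuity*
#' from the chosen eigenstate of `H0`, not by energy ordering: along the path it
#' is followed by maximum eigenvector overlap.
#'
#' @param H0,H1 symmetric matrices (hartree) of equal dimension.
#' @param dipole_op optional symmetric matrix of the dipole operator along the
#'   intermonomer axis; when supplied, [alpha_spectrum()] attaches transition
#'   dipoles `d_mu = <ref| D |mu>` (placed on the z axis).
#' @param reference index (0-based, by ascending energy of `H0`) of the state
#'   tracked as reference.
#' @return Object of class `alpha_path`.
#' @export
alpha_path <- function(H0, H1, dipole_op = NULL, reference = 0L) {
  H0 <- as.matrix(H0); H1 <- as.matrix(H1)
  if (!isSymmetric(H0, tol = 1e-12) || !isSymmetric(H1, tol = 1e-12)) {
    stop("H0 and H1 must be symmetric")
  }
  if (!all(dim(H0) == dim(H1))) stop("H0 and H1 must have equal dimensions")
  reference <- as.integer(reference)
  if (reference < 0L || reference >= nrow(H0)) stop("reference index out of range")
  if (!is.null(dipole_op)) {
    dipole_op <- as.matrix(dipole_op)
    if (!all(dim(dipole_op) == dim(H0))) stop("dipole_op dimension mismatch")
  }
  structure(list(H0 = H0, H1 = H1, dipole_op = dipole_op, reference = reference),
            class = "alpha_path")
}

alpha_hamiltonian <- function(path, alpha) {
  path$H0 + alpha * (path$H1 - path$H0)
}

#' Monomer spectrum along the adiabatic-connection path
#'
#' Diagonalizes `H(alpha)` and forms the signed transition energies relative to
#' the tracked reference state. Tracking marches alpha from 0 to the target in
#' `track_steps` increments, carrying the reference eigenvector forward by
#' maximum absolute overlap with the previous node; if at any node the two
#' largest overlaps agree within 1e-3 the crossing is ambiguous and an error
#' names the alpha at which it occurs.
#'
#' @param path an [alpha_path()].
#' @param alpha coupling constant in \[0, 1\].
#' @param track_steps number of continuity steps used for reference tracking.
#' @return A [transition_set()]; `reference_index` is the *position* of the
#'   tracked state in the ascending spectrum of `H(alpha)` (so a reference that
#'   stays lowest has index 0), and dipoles are attached when the path carries a
#'   dipole operator.
#' @export
alpha_spectrum <- function(path, alpha, track_steps = 21L) {
  stopifnot(inherits(path, "alpha_path"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  e0 <- eigen(path$H0, symmetric = TRUE)
  ord0 <- order(e0$values)
  vref <- e0$vectors[, ord0[path$reference + 1L]]
  if (alpha > 0) {
    alphas <- seq(0, alpha, length.out = max(2L, as.integer(track_steps)))
    for (a in alphas[-1L]) {
      ea <- eigen(alpha_hamiltonian(path, a), symmetric = TRUE)
      ov <- abs(as.numeric(crossprod(ea$vectors, vref)))
      top <- order(ov, decreasing = TRUE)
      if (length(ov) > 1L && abs(ov[top[1L]] - ov[top[2L]]) < 1e-3) {
        stop(sprintf(
          "reference tracking ambiguous near alpha = %.4f (two overlaps within 1e-3)",
          a
        ))
      }
      vref <- ea$vectors[, top[1L]]
      vals <- ea$values
      vecs <- ea$vectors
      iref <- top[1L]
    }
  } else {
    vals <- e0$values
    vecs <- e0$vectors
    iref <- ord0[path$reference + 1L]
  }
  ord <- order(vals)
  pos_ref <- which(ord == iref)        # position of reference in ascending order
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  dE <- vals - vals[pos_ref]
  keep <- seq_along(vals) != pos_ref
  dip <- NULL
  if (!is.null(path$dipole_op)) {
    d <- as.numeric(crossprod(vecs[, pos_ref], path$dipole_op %*% vecs))
    dip <- cbind(0, 0, d[keep])
  }
  transition_set(dE[keep], dipoles = dip, reference_index = pos_ref - 1L)
}

# second-order dispersion energy at coupling constant alpha
e2_alpha <- function(pathA, pathB, coupling_fn, alpha, resonance_tol = 1e-6) {
  TSa <- alpha_spectrum(pathA, alpha)
  TSb <- alpha_spectrum(pathB, alpha)
  W <- coupling_fn(TSa, TSb)
  b <- dispersion_sos(TSa, TSb, W, resonance_tol = resonance_tol)
  b$total
}

#' Adiabatic-connection dispersion integrand
#'
#' The integrand of the coupling-constant integral used by [dispersion_ac2()]:
#' `f(alpha) = d/dalpha [ alpha^2 E2(alpha) ]`, where `E2(alpha)` is the full
#' four-part second-order dispersion energy (its mixed- and negative-sign terms
#' are the non-Casimir-Polder parts of the AC theory) evaluated from the
#' spectra and couplings of `H(alpha)`. The derivative is taken by central
#' finite differences with step `fd_step` (one-sided at the interval ends).
#'
#' @param pathA,pathB [alpha_path()]s for the monomers.
#' @param coupling_fn function `(transition_set, transition_set) ->`
#'   [coupling_matrix()], e.g. from [make_dipole_coupling_fn()].
#' @param alpha coupling constant(s) in \[0, 1\]; vectorized.
#' @param fd_step finite-difference step for the alpha derivative.
#' @param resonance_tol passed to [dispersion_sos()].
#' @return Integrand value(s) in hartree.
#' @export
ac_dispersion_integrand <- function(pathA, pathB, coupling_fn, alpha,
                                    fd_step = 1e-5, resonance_tol = 1e-6) {
  Ffun <- function(a) a^2 * e2_alpha(pathA, pathB, coupling_fn, a, resonance_tol)
  vapply(alpha, function(a) {
    h <- fd_step
    if (a - h >= 0 && a + h <= 1) {
      (Ffun(a + h) - Ffun(a - h)) / (2 * h)
    } else if (a + 2 * h <= 1) {        # forward second-order at the left end
      (-3 * Ffun(a) + 4 * Ffun(a + h) - Ffun(a + 2 * h)) / (2 * h)
    } else {                             # backward second-order at the right end
      (3 * Ffun(a) - 4 * Ffun(a - h) + Ffun(a - 2 * h)) / (2 * h)
    }
  }, numeric(1))
}

#' Adiabatic-connection second-order dispersion energy
#'
#' Integrates the coupling-constant-dependent second-order dispersion energy
#' along the adiabatic connection: `E_disp^AC = int_0^1 d/dalpha[alpha^2
#' E2(alpha)] dalpha` by Gauss-Legendre quadrature on \[0, 1\]. `E2(alpha)` is
#' built from the alpha-dependent monomer spectra ([alpha_spectrum()]) and the
#' alpha-dependent couplings returned by `coupling_fn`; it includes the
#' de-excitation (non-Casimir-Polder) parts. When `H0 = H1` for both monomers
#' the integrand reduces to `2 alpha E2` and the integral equals the plain
#' sum-over-states value at the `H0` spectra. In the zero-overlap regime of the
#' point-dipole couplings the integral builds up the monomer correlation along
#' the path and lands on the second-order dispersion energy of the fully
#' correlated (alpha = 1) monomers.
#'
#' @inheritParams ac_dispersion_integrand
#' @param n_alpha number of Gauss-Legendre nodes on \[0, 1\] (default 8).
#' @return Dispersion energy in hartree.
#' @export
dispersion_ac2 <- function(pathA, pathB, coupling_fn, n_alpha = 8L,
                           fd_step = 1e-5, resonance_tol = 1e-6) {
  stopifnot(inherits(pathA, "alpha_path"), inherits(pathB, "alpha_path"))
  gl <- pracma::gaussLegendre(as.integer(n_alpha), 0, 1)
  f <- ac_dispersion_integrand(pathA, pathB, coupling_fn, gl$x,
                               fd_step = fd_step, resonance_tol = resonance_tol)
  sum(gl$w * f)
}

#' Uncoupled (UC) dispersion approximation
#'
#' Freezes the monomer description at the uncorrelated alpha = 0 level for the
#' whole path: spectra and couplings are those of `H0`, so the integral
#' collapses to the plain second-order dispersion energy of the zeroth-order
#' monomers, `E2(0)`.
#'
#' @inheritParams ac_dispersion_integrand
#' @return Dispersion energy in hartree.
#' @export
dispersion_uncoupled <- function(pathA, pathB, coupling_fn, resonance_tol = 1e-6) {
  stopifnot(inherits(pathA, "alpha_path"), inherits(pathB, "alpha_path"))
  e2_alpha(pathA, pathB, coupling_fn, 0, resonance_tol = resonance_tol)
}

#' Point-dipole coupling closure for AC paths
#'
#' Convenience factory producing the `coupling_fn` used by [dispersion_ac2()]:
#' point-dipole couplings at fixed separation and axis, rebuilt from the
#' (alpha-dependent) transition dipoles of each spectrum.
#'
#' @inheritParams dipole_coupling
#' @return A function `(A, B) -> coupling_matrix`.
#' @export
make_dipole_coupling_fn <- function(separation, axis = c(0, 0, 1)) {
  force(separation); force(axis)
  function(A, B) dipole_coupling(A, B, separation = separation, axis = axis)
}

#' Alpha-path JSON I/O
#'
#' Serializes dense symmetric model Hamiltonians (and the optional dipole
#' operator) so AC fixtures can be exchanged as plain JSON.
#'
#' @param path an [alpha_path()]; `file` a file path.
#' @return `read_alpha_path()` returns an `alpha_path`.
#' @export
write_alpha_path <- function(path, file) {
  stopifnot(inherits(path, "alpha_path"))
  payload <- list(H0 = path$H0, H1 = path$H1, reference = path$reference)
  if (!is.null(path$dipole_op)) payload$dipole_op <- path$dipole_op
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_alpha_path
#' @export
read_alpha_path <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  alpha_path(p$H0, p$H1,
             dipole_op = if (!is.null(p$dipole_op)) p$dipole_op,
             reference = p$reference)
}
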