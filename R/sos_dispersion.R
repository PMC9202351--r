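#' Sum-over-states dispersion energy with transition-sign partition
#'
#' Direct Rayleigh-Schrodinger second-order evaluation of the dispersion energy
#' of a dimer whose monomers sit in (possibly excited) reference states I and J.
#' Each transition pair (mu, nu) contributes
#' `-w_{mu,nu}^2 / (dE^A_mu + dE^B_nu)`, and the total is partitioned into four
#' parts according to the signs of the two transition energies:
#'
#' * `part_up_up`: both transitions positive — the only part present for
#'   ground-state references; always attractive (<= 0).
#' * `part_down_down`: both negative (one exciton on each monomer); the
#'   denominator is negative, so these terms are *repulsive* (>= 0).
#' * `part_up_down`, `part_down_up`: mixed-sign terms, present whenever one
#'   monomer carries an exciton.
#'
#' A denominator whose magnitude falls below `resonance_tol` signals a
#' (near-)degenerate unperturbed dimer state, where second-order perturbation
#' theory for nondegenerate states breaks down; this raises an error naming the
#' offending pair rather than silently regularizing.
#'
#' @param A,B [transition_set()]s for the two monomers.
#' @param W [coupling_matrix()] of Coulomb couplings w_{mu,nu} (hartree), rows
#'   matching `A`, columns matching `B`.
#' @param resonance_tol smallest admissible |dE^A_mu + dE^B_nu| (hartree).
#' @return An object of class `dispersion_breakdown`: `total`, the four parts,
#'   and `non_cp_single_exciton` (the single-exciton de-excitation term; `NA`
#'   unless I = 1, J = 0).
#' @seealso [dispersion_cp_extended()] for the quadrature route,
#'   [single_exciton_non_cp()] for the I = 1, J = 0 de-excitation term.
#' @examples
#' a <- make_two_level_monomer(1.0)
#' w <- coupling_matrix(matrix(0.1))
#' dispersion_sos(a, a, w)$total  # -0.1^2 / (1 + 1) = -0.005
#' @export
dispersion_sos <- function(A, B, W, resonance_tol = 1e-6) {
  stopifnot(inherits(A, "transition_set"), inherits(B, "transition_set"))
  w <- if (inherits(W, "coupling_matrix")) W$w else as.matrix(W)
  if (nrow(w) != length(A$energies) || ncol(w) != length(B$energies)) {
    stop("coupling matrix dimensions do not match the transition sets")
  }
  dA <- A$energies
  dB <- B$energies
  den <- outer(dA, dB, `+`)
  bad <- which(abs(den) < resonance_tol, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "resonance: |dE^A_%d + dE^B_%d| = %.3e hartree below tolerance %.1e (nondegenerate reference assumption violated)",
      bad[1L, 1L], bad[1L, 2L], abs(den[bad[1L, 1L], bad[1L, 2L]]), resonance_tol
    ))
  }
  terms <- -(w^2) / den
  upA <- dA > 0
  upB <- dB > 0
  part <- function(ia, ib) sum(terms[ia, ib, drop = FALSE])
  res <- list(
    total = sum(terms),
    part_up_up = part(upA, upB),
    part_down_down = part(!upA, !upB),
    part_up_down = part(upA, !upB),
    part_down_up = part(!upA, upB),
    non_cp_single_exciton = NA_real_
  )
  if (A$reference_index == 1L && B$reference_index == 0L) {
    res$non_cp_single_exciton <- res$part_down_up
  }
  structure(res, class = "dispersion_breakdown")
}

#' @export
print.dispersion_breakdown <- function(x, ...) {
  cat("<dispersion_breakdown> (hartree / kcal mol^-1)\n")
  row <- function(nm, v) {
    if (is.na(v)) return(invisible())
    cat(sprintf("  %-22s % .10e  /  % .6f\n", nm, v, hartree_to_kcal(v)))
  }
  row("total", x$total)
  row("part_up_up", x$part_up_up)
  row("part_down_down", x$part_down_down)
  row("part_up_down", x$part_up_down)
  row("part_down_up", x$part_down_up)
  row("non_cp_single_exciton", x$non_cp_single_exciton)
  invisible(x)
}

#' Single-exciton non-Casimir-Polder dispersion term
#'
#' For the lowest localized exciton on monomer A (reference I = 1) interacting
#' with a ground-state partner (J = 0), the only de-excitation terms are those
#' with mu < I = 1 and nu > J = 0. Their sum is negative and equals the
#' (down, up) part of the full breakdown.
#'
#' @inheritParams dispersion_sos
#' @return The de-excitation contribution in hartree.
#' @export
single_exciton_non_cp <- function(A, B, W, resonance_tol = 1e-6) {
  if (A$reference_index != 1L || B$reference_index != 0L) {
    stop("single-exciton term requires A.reference_index = 1 and B.reference_index = 0")
  }
  dispersion_sos(A, B, W, resonance_tol = resonance_tol)$part_down_up
}
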