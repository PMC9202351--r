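#' Coulomb coupling matrix between two transition manifolds
#'
#' `coupling_matrix` wraps the real Coulomb couplings w_{mu,nu} (hartree)
#' between transition mu of monomer A and transition nu of monomer B, together
#' with a provenance tag saying whether they came from the point-dipole model or
#' from gridded transition densities.
#'
#' @param w numeric matrix of couplings (rows: A transitions, cols: B).
#' @param provenance `"dipole_model"` or `"grid_densities"`.
#' @return An object of class `coupling_matrix`.
#' @export
coupling_matrix <- function(w, provenance = c("dipole_model", "grid_densities")) {
  provenance <- match.arg(provenance)
  w <- as.matrix(w)
  if (!is.numeric(w) || any(!is.finite(w))) stop("couplings must be finite numbers")
  structure(list(w = w, provenance = provenance), class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %d x %d (%s)\n", nrow(x$w), ncol(x$w), x$provenance))
  print(x$w)
  invisible(x)
}

#' Point-dipole Coulomb couplings
#'
#' Couplings in the zero-overlap (multipole) regime:
#' `w_{mu,nu} = [d_mu . d_nu - 3 (d_mu . n)(d_nu . n)] / R^3`
#' with `n` the unit intermonomer axis and `R` the separation in bohr. Every
#' entry scales exactly as R^-3, so second-order dispersion built from these
#' couplings decays exactly as R^-6.
#'
#' @param A,B [transition_set()]s carrying transition dipoles.
#' @param separation intermonomer distance R > 0 (bohr).
#' @param axis 3-vector along the intermonomer axis (normalized internally).
#' @return A [coupling_matrix()] with provenance `"dipole_model"`.
#' @examples
#' a <- make_two_level_monomer(1.0, dipole = c(0, 0, 1))
#' dipole_coupling(a, a, separation = 10)$w  # -2e-3 for collinear unit dipoles
#' @export
dipole_coupling <- function(A, B, separation, axis = c(0, 0, 1)) {
  stopifnot(inherits(A, "transition_set"), inherits(B, "transition_set"))
  if (!is.numeric(separation) || length(separation) != 1L || separation <= 0) {
    stop("separation must be a positive distance in bohr")
  }
  if (is.null(A$dipoles) || is.null(B$dipoles)) {
    stop("both transition sets must carry transition dipoles")
  }
  n_hat <- axis / sqrt(sum(axis^2))
  dA <- A$dipoles
  dB <- B$dipoles
  # dipole-dipole tensor: d_mu^T (1 - 3 n n^T) d_nu / R^3
  w <- (dA %*% t(dB) - 3 * (dA %*% n_hat) %*% t(dB %*% n_hat)) / separation^3
  coupling_matrix(w, provenance = "dipole_model")
}

#' Coupling-matrix CSV I/O
#'
#' Writes/reads the coupling matrix as CSV with a header row and first column of
#' transition labels (`up`/`down` tags combined with the transition number).
#'
#' @param x a `coupling_matrix`; `A,B` the transition sets it couples (used for
#'   labels when writing).
#' @param path file path.
#' @return `read_coupling_matrix()` returns a `coupling_matrix`.
#' @export
write_coupling_matrix <- function(x, path, A = NULL, B = NULL) {
  stopifnot(inherits(x, "coupling_matrix"))
  w <- x$w
  rn <- if (!is.null(A)) paste0("A", seq_len(nrow(w)), ".", A$labels) else
    paste0("A", seq_len(nrow(w)))
  cn <- if (!is.null(B)) paste0("B", seq_len(ncol(w)), ".", B$labels) else
    paste0("B", seq_len(ncol(w)))
  df <- data.frame(transition = rn, w, check.names = FALSE)
  names(df)[-1L] <- cn
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coupling_matrix
#' @export
read_coupling_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  coupling_matrix(as.matrix(df[, -1L, drop = FALSE]))
}
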