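#' Transition set of a monomer
#'
#' A `transition_set` describes one monomer's excitation manifold relative to a
#' chosen (possibly excited) reference state I. Each transition mu != I carries a
#' *signed* transition energy dE_mu = E_mu - E_I in hartree: positive for
#' up-transitions (mu above the reference) and negative for down-transitions
#' (de-excitations, mu below an excited reference). A nondegenerate reference is
#' assumed, so no transition energy may be exactly zero.
#'
#' @param energies numeric vector of signed transition energies (hartree), one
#'   per state mu != I.
#' @param dipoles optional n x 3 matrix of transition dipole vectors (atomic
#'   units), rows aligned with `energies`.
#' @param reference_index integer label I of the reference state (0-based state
#'   counting, so a ground-state reference is 0).
#' @return An object of class `transition_set` with fields `reference_index`,
#'   `energies`, `labels` (`"up"`/`"down"`) and `dipoles`.
#' @seealso [make_two_level_monomer()], [make_random_spectrum()],
#'   [dipole_coupling()]
#' @export
transition_set <- function(energies, dipoles = NULL, reference_index = 0L) {
  energies <- as.numeric(energies)
  if (length(energies) < 1L) stop("a transition set needs at least one transition")
  if (any(!is.finite(energies))) stop("transition energies must be finite")
  if (any(energies == 0)) {
    stop("degenerate reference: transition energy exactly zero")
  }
  if (!is.null(dipoles)) {
    dipoles <- matrix(as.numeric(dipoles), ncol = 3L)
    if (nrow(dipoles) != length(energies)) {
      stop("need one 3-vector transition dipole per transition")
    }
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 0L) stop("reference_index must be >= 0")
  structure(
    list(
      reference_index = reference_index,
      energies = energies,
      labels = ifelse(energies > 0, "up", "down"),
      dipoles = dipoles
    ),
    class = "transition_set"
  )
}

#' @export
print.transition_set <- function(x, ...) {
  n_down <- sum(x$labels == "down")
  cat(sprintf(
    "<transition_set> reference state I = %d, %d transition(s) (%d up, %d down)\n",
    x$reference_index, length(x$energies), length(x$energies) - n_down, n_down
  ))
  cat("  dE (hartree):", paste(sprintf("%+.6g", x$energies), collapse = ", "), "\n")
  if (!is.null(x$dipoles)) cat("  transition dipoles: present\n")
  invisible(x)
}

#' Two-level model monomer
#'
#' Builds the simplest monomer: two states separated by `gap`. With
#' `excited = FALSE` the reference is the lower state and the set holds one
#' up-transition (+gap); with `excited = TRUE` the reference is the upper state
#' and the single transition is a de-excitation (-gap).
#'
#' @param gap positive energy gap between the two states (hartree).
#' @param dipole 3-vector transition dipole (atomic units).
#' @param excited logical; is the reference the upper state?
#' @return A [transition_set()] with a single transition.
#' @examples
#' make_two_level_monomer(1.0)                  # one up-transition at +1
#' make_two_level_monomer(0.3, excited = TRUE)  # one down-transition at -0.3
#' @export
make_two_level_monomer <- function(gap, dipole = c(0, 0, 1), excited = FALSE) {
  if (!is.numeric(gap) || length(gap) != 1L || !is.finite(gap) || gap <= 0) {
    stop("degenerate reference: gap must be a positive energy")
  }
  transition_set(
    energies = if (excited) -gap else +gap,
    dipoles = matrix(dipole, nrow = 1L),
    reference_index = if (excited) 1L else 0L
  )
}

#' Seeded random model spectrum
#'
#' Draws a reproducible ladder of state energies with strictly positive gaps
#' (uniform on [0.1, 1.0] hartree, which keeps all model dimers safely away from
#' accidental resonances) and random unit-scale transition dipoles, then forms
#' signed transition energies relative to state `reference_index`. By
#' construction, a reference index I yields exactly I down-transitions.
#'
#' @param n_states number of model states (>= 2).
#' @param reference_index reference state I, `0 <= I < n_states`.
#' @param seed integer seed; identical inputs give bitwise-identical output.
#' @param dipole_scale standard deviation of the random dipole components.
#' @return A [transition_set()] with `n_states - 1` transitions.
#' @export
make_random_spectrum <- function(n_states, reference_index = 0L, seed = 1L,
                                 dipole_scale = 1.0) {
  n_states <- as.integer(n_states)
  reference_index <- as.integer(reference_index)
  if (n_states < 2L) stop("need at least two states")
  if (reference_index < 0L || reference_index >= n_states) {
    stop("reference_index must satisfy 0 <= I < n_states")
  }
  set.seed(as.integer(seed))
  gaps <- runif(n_states - 1L, min = 0.1, max = 1.0)
  state_energies <- cumsum(c(0, gaps))
  dE <- state_energies - state_energies[reference_index + 1L]
  keep <- seq_len(n_states) != (reference_index + 1L)
  dip <- matrix(rnorm(3L * (n_states - 1L), sd = dipole_scale), ncol = 3L)
  transition_set(dE[keep], dipoles = dip, reference_index = reference_index)
}

#' Write / read a monomer spectrum as JSON
#'
#' Serializes a [transition_set()] as
#' `{reference_index, energies[], labels[], dipoles[][3]}` plus an optional
#' `seed` header recording how the spectrum was generated.
#'
#' @param x a `transition_set`.
#' @param path file path.
#' @param seed optional integer recorded in the file header.
#' @return `write_transition_set()` returns `path` invisibly;
#'   `read_transition_set()` returns a `transition_set`.
#' @export
write_transition_set <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "transition_set"))
  payload <- list(
    reference_index = x$reference_index,
    energies = x$energies,
    labels = x$labels
  )
  if (!is.null(x$dipoles)) payload$dipoles <- x$dipoles
  if (!is.null(seed)) payload$seed <- as.integer(seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_set
#' @export
read_transition_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  dip <- if (!is.null(payload$dipoles)) matrix(payload$dipoles, ncol = 3L)
  transition_set(payload$energies, dipoles = dip,
                 reference_index = payload$reference_index)
}
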