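#' Unit conversions
#'
#' The package works in atomic units (hartree for energies, bohr for lengths)
#' throughout; kcal/mol is used only when reporting. 1 hartree = 627.5095
#' kcal/mol; 1 bohr = 0.52917721092 angstrom.
#'
#' @param x numeric vector of energies (hartree or kcal/mol) or lengths.
#' @return Converted numeric vector.
#' @examples
#' hartree_to_kcal(1)      # 627.5095
#' kcal_to_hartree(627.5095)
#' @export
hartree_to_kcal <- function(x) x * 627.5095

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / 627.5095

#' @rdname hartree_to_kcal
#' @export
angstrom_to_bohr <- function(x) x / 0.52917721092

#' @rdname hartree_to_kcal
#' @export
bohr_to_angstrom <- function(x) x * 0.52917721092
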