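#' SAPT component table
#'
#' A thin wrapper around a data.frame of named interaction-energy components
#' (kcal/mol by convention) for a set of dimers, with a mandatory units tag.
#' Missing cells stay `NA` — they are never silently treated as zero.
#'
#' @param df data.frame of components; first column should identify the dimer.
#' @param units unit string, e.g. `"kcal/mol"`.
#' @return Object of classes `component_table` and `data.frame`.
#' @export
component_table <- function(df, units = "kcal/mol") {
  stopifnot(is.data.frame(df))
  if (is.null(units) || !nzchar(units)) stop("a units tag is mandatory")
  attr(df, "units") <- units
  class(df) <- c("component_table", class(df))
  df
}

#' Component-table CSV I/O
#'
#' CSV with a leading `# units: <units>` comment line followed by a regular
#' header; reading a file without the units line is an error.
#'
#' @param x a [component_table()].
#' @param path file path.
#' @return `read_component_table()` returns a `component_table`.
#' @export
write_component_table <- function(x, path) {
  con <- base::file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", attr(x, "units")), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*units:\\s*(.+)$", first))[[1L]]
  if (length(m) < 2L) stop("component table must start with a '# units: ...' line")
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  component_table(df, units = trimws(m[2L]))
}

missing_stop <- function(..., what) {
  vals <- c(...)
  if (any(is.na(vals)) || any(!is.finite(vals))) {
    stop(sprintf("missing component in %s (explicit NA, not zero)", what))
  }
  invisible(vals)
}

#' Total dispersion component
#'
#' `E_DISP = E_disp^(2) + E_exch-disp^(2)`: the second-order dispersion energy
#' damped by its exchange counterpart — the quantity a dispersion correction
#' to a dispersion-free supermolecular method must supply.
#'
#' @param e_disp2 second-order dispersion energy.
#' @param e_exch_disp2 second-order exchange-dispersion energy.
#' @return Their sum (same units as inputs).
#' @examples
#' e_disp_total(-2.88, 0.33)  # -2.55
#' @export
e_disp_total <- function(e_disp2, e_exch_disp2) {
  missing_stop(e_disp2, e_exch_disp2, what = "e_disp_total")
  e_disp2 + e_exch_disp2
}

#' Dispersion-corrected CAS interaction energy
#'
#' `CAS+DISP = E_int^CAS + E_DISP`: the supermolecular CASSCF interaction
#' energy (which misses dispersion entirely) plus the perturbation-theory
#' dispersion-plus-exchange-dispersion correction.
#'
#' @param e_int_cas supermolecular CAS interaction energy.
#' @param e_disp_total output of [e_disp_total()].
#' @return Corrected interaction energy.
#' @export
cas_plus_disp <- function(e_int_cas, e_disp_total) {
  missing_stop(e_int_cas, e_disp_total, what = "cas_plus_disp")
  e_int_cas + e_disp_total
}

#' Second-order SAPT interaction energy
#'
#' Plain sum of the six components through second order in the interaction
#' operator: electrostatics, first-order exchange, induction,
#' exchange-induction, dispersion and exchange-dispersion. Higher-order
#' corrections (delta_HF / delta_CAS) and the de-excitation dispersion term
#' are reported separately, never folded in silently.
#'
#' @param e_elst1,e_exch1,e_ind2,e_exch_ind2,e_disp2,e_exch_disp2 the six
#'   components (consistent units).
#' @return The SAPT interaction energy.
#' @examples
#' sapt_total(-1.85, 2.82, -1.23, 0.65, -2.88, 0.33)  # -2.16
#' @export
sapt_total <- function(e_elst1, e_exch1, e_ind2, e_exch_ind2, e_disp2,
                       e_exch_disp2) {
  missing_stop(e_elst1, e_exch1, e_ind2, e_exch_ind2, e_disp2, e_exch_disp2,
               what = "sapt_total")
  e_elst1 + e_exch1 + e_ind2 + e_exch_ind2 + e_disp2 + e_exch_disp2
}

#' Excited-state analogue of the delta_HF induction correction
#'
#' Beyond-second-order induction effects are routinely estimated for ground
#' states from a supermolecular Hartree-Fock calculation (delta_HF). No such
#' supermolecular reference exists for an exciton-bearing dimer, so the shift
#' is assumed proportional to the change of the *second-order* induction on
#' excitation:
#' `delta_CAS = delta_HF^GS * (E_ind + E_exch-ind)_ES / (E_ind + E_exch-ind)_GS`.
#' Whether the scaling ratio should include the exchange-induction term is a
#' genuinely open choice; the default includes it (`ratio_terms = "sum"`),
#' `"ind_only"` uses bare induction.
#'
#' @param delta_hf_gs ground-state delta_HF correction.
#' @param ind_gs,exch_ind_gs ground-state second-order induction and
#'   exchange-induction.
#' @param ind_es,exch_ind_es the same for the excited complex.
#' @param ratio_terms `"sum"` (default) or `"ind_only"`.
#' @return The delta_CAS correction.
#' @examples
#' delta_cas(-0.50, -2.00, 0, -1.00, 0)  # -0.25
#' @export
delta_cas <- function(delta_hf_gs, ind_gs, exch_ind_gs, ind_es, exch_ind_es,
                      ratio_terms = c("sum", "ind_only")) {
  ratio_terms <- match.arg(ratio_terms)
  missing_stop(delta_hf_gs, ind_gs, exch_ind_gs, ind_es, exch_ind_es,
               what = "delta_cas")
  den <- if (ratio_terms == "sum") ind_gs + exch_ind_gs else ind_gs
  num <- if (ratio_terms == "sum") ind_es + exch_ind_es else ind_es
  if (den == 0) stop("ground-state induction sum is zero; refusing to extrapolate")
  delta_hf_gs * num / den
}

#' Mean unsigned error and mean absolute percentage error
#'
#' `MUE = mean |v - r|`; `MA%E = 100 * mean |v - r| / |r|`. Computed at full
#' precision; rounding belongs to display only.
#'
#' @param values numeric vector of method predictions.
#' @param references numeric vector of reference values (no zeros).
#' @return Named list `mue`, `mape`.
#' @export
error_metrics <- function(values, references) {
  if (length(values) != length(references)) {
    stop("values and references must have equal length")
  }
  missing_stop(values, references, what = "error_metrics")
  if (any(references == 0)) stop("zero reference value: MA%E undefined")
  d <- abs(values - references)
  list(mue = mean(d), mape = 100 * mean(d / abs(references)))
}

#' Benchmark tables for eight S66 exciton complexes
#'
#' Precomputed interaction-energy data (kcal/mol) for eight S66 dimers whose
#' excited states carry a localized pi-pi* (benzene, pyridine) or n-pi*
#' (peptide = N-methyl-acetamide) exciton, from SAPT(CAS)/aug-cc-pVTZ-level
#' calculations with ERPA response, shipped as plain-text component tables:
#'
#' * `"sapt_components_excited"`: the six SAPT(CAS) components, their sum and
#'   the de-excitation dispersion term `eps_disp_1to0` for the excited dimers.
#' * `"correlation_interaction_excited"`: E_DISP and the AC0 / lrAC0 / reVV10 /
#'   LRD correlation interaction-energy contributions.
#' * `"interaction_energies_ground"` / `"interaction_energies_excited"`:
#'   total interaction energies for eight CASSCF-based methods plus the
#'   coupled-cluster reference column.
#' * `"printed_error_summaries"`: the error statistics printed alongside those
#'   method columns (for consistency checks against [error_metrics()]).
#'
#' @param name one of the table names above.
#' @return A [component_table()] (a data.frame with a units attribute).
#' @export
benchmark_table <- function(name = c("sapt_components_excited",
                                     "correlation_interaction_excited",
                                     "interaction_energies_ground",
                                     "interaction_energies_excited",
                                     "printed_error_summaries")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "excidisp",
                      mustWork = TRUE)
  read_component_table(path)
}

#' Per-dimer assembly report
#'
#' Convenience driver for a component table in the layout of
#' [benchmark_table()]`("sapt_components_excited")`: computes E_DISP, the SAPT
#' sum and (when CAS interaction energies are provided) CAS+DISP for every
#' row, carrying the de-excitation term as its own ledger line.
#'
#' @param comps a `component_table` with columns `dimer`, `e_elst1`, `e_exch1`,
#'   `e_ind2`, `e_exch_ind2`, `e_disp2`, `e_exch_disp2` and optionally
#'   `eps_disp_1to0`.
#' @param e_int_cas optional vector of CAS interaction energies, aligned with
#'   the rows.
#' @return A `component_table` with columns `e_disp_total`, `e_int_sapt`, and
#'   optionally `cas_plus_disp`.
#' @export
assemble_report <- function(comps, e_int_cas = NULL) {
  need <- c("dimer", "e_elst1", "e_exch1", "e_ind2", "e_exch_ind2",
            "e_disp2", "e_exch_disp2")
  if (!all(need %in% names(comps))) {
    stop("component table lacks required columns: ",
         paste(setdiff(need, names(comps)), collapse = ", "))
  }
  out <- data.frame(
    dimer = comps$dimer,
    e_disp_total = e_disp_total(comps$e_disp2, comps$e_exch_disp2),
    e_int_sapt = sapt_total(comps$e_elst1, comps$e_exch1, comps$e_ind2,
                            comps$e_exch_ind2, comps$e_disp2,
                            comps$e_exch_disp2)
  )
  if ("eps_disp_1to0" %in% names(comps)) {
    out$eps_disp_1to0 <- comps$eps_disp_1to0
  }
  if (!is.null(e_int_cas)) {
    out$cas_plus_disp <- cas_plus_disp(e_int_cas, out$e_disp_total)
  }
  component_table(out, units = attr(comps, "units"))
}
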