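# excidisp

Dispersion energies for van der Waals complexes with **localized excitons** —
dimers in which one (or both) monomers sits in an electronically excited
reference state.

## The problem

For two ground-state molecules the London dispersion energy is the classic
second-order sum over states,

```
E_disp^(2) = - sum_{mu != I, nu != J}  w_{mu,nu}^2 / (dE^A_mu + dE^B_nu),
```

where `w_{mu,nu}` is the Coulomb coupling between transition densities and the
transition energies `dE` are all positive. Equivalently it is the
Casimir-Polder integral of the product of the monomers' density-response
functions over imaginary frequency — always attractive.

When a monomer's reference state is an *excited* state, its manifold contains
**negative transition energies** (de-excitations, `mu < I`). The
sum-over-states expression then splits into four parts by the signs of
`(dE^A_mu, dE^B_nu)`:

* `(up, up)` — the Casimir-Polder part, always attractive;
* `(down, down)` — present only when *both* monomers carry excitons; its
  denominators are negative, so it is **repulsive**;
* `(up, down)` and `(down, up)` — mixed terms; for the common single-exciton
  case (`I = 1`, `J = 0`) the only extra term is `(down, up)` and it is
  negative.

The blocks touching a negative transition cannot be pushed through the
imaginary-frequency identity (it requires positive denominators); they are the
**non-Casimir-Polder terms**. `excidisp` computes all of this with several
mutually validating engines:

| engine | function | idea |
|---|---|---|
| sum over states | `dispersion_sos()` | exact closed form + four-way sign partition |
| extended Casimir-Polder | `dispersion_cp_extended()` | quadrature for `(up,up)`, closed form for the rest |
| adiabatic connection | `dispersion_ac2()` | integrate the coupling-constant-dependent `E^(2),alpha` of explicit model Hamiltonians; `dispersion_uncoupled()` is the alpha = 0 (UC) limit |
| reVV10 | `vv10_nonlocal_energy()`, `vv10_interaction_energy()` | VV10 nonlocal correlation functional with dispersion-trained parameters `C = 0.013`, `b = 2.84`, counterpoise-corrected on a shared grid |
| SAPT assembly | `sapt_total()`, `e_disp_total()`, `cas_plus_disp()`, `delta_cas()`, `error_metrics()` | compose interaction energies from component tables; benchmark error statistics |
| exact-diagonalization backend | `dimer_job()`, `extract_spectrum()`, `coulomb_coupling_from_grids()`, `densities_for_revv10()` | s-orbital Gaussian-basis full CI for hydrogenic systems: exact spectra, transition densities, density grids, counterpoise ghosts |

Everything internal is in atomic units; `hartree_to_kcal()` converts at the
reporting boundary (1 hartree = 627.5095 kcal/mol).

## Worked example

A monomer in its first excited state (gap 0.3 hartree, so one de-excitation at
-0.3) next to a ground-state partner (gap 0.4), coupled as collinear unit
point dipoles 10 bohr apart:

```r
library(excidisp)
A <- make_two_level_monomer(0.3, dipole = c(0, 0, 1), excited = TRUE)
B <- make_two_level_monomer(0.4, dipole = c(0, 0, 1))
W <- dipole_coupling(A, B, separation = 10)   # w = -2/R^3 = -2e-3 hartree
dispersion_sos(A, B, W)
#> <dispersion_breakdown> (hartree / kcal mol^-1)
#>   total                  -4.0000000000e-05  /  -0.025100
#>   part_up_up              0.0000000000e+00  /   0.000000
#>   part_down_down          0.0000000000e+00  /   0.000000
#>   part_up_down            0.0000000000e+00  /   0.000000
#>   part_down_up           -4.0000000000e-05  /  -0.025100
#>   non_cp_single_exciton  -4.0000000000e-05  /  -0.025100
```

The whole dispersion energy here is the non-Casimir-Polder `(down, up)` term,
`-w^2/(-0.3 + 0.4) = -4e-5` hartree: attractive, as it must be for a single
localized exciton. The extended Casimir-Polder engine reproduces it exactly
(`dispersion_cp_extended(A, B, W)$total` differs by 0 at convergence).

Benchmark-table assembly works the same way at the kcal/mol boundary:

```r
es <- benchmark_table("interaction_energies_excited")
em <- error_metrics(es$cas_disp, es$reference)
sprintf("CAS+DISP excited: MUE %.2f kcal/mol, MA%%E %.1f%%", em$mue, em$mape)
#> "CAS+DISP excited: MUE 0.24 kcal/mol, MA%E 5.9%"
```

A thin CLI over the same functions lives at `inst/cli/excidisp.R`
(subcommands `sos`, `cp`, `ac`, `revv10`, `assemble`).

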