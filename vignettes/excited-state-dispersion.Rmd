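---
title: "Dispersion energies in exciton-localized excited-state complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion energies in exciton-localized excited-state complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excidisp)
```

## The model

Consider a dimer AB dissociating into monomer A in state $I$ and monomer B in
state $J$, with a nondegenerate unperturbed product state. Second-order
Rayleigh–Schrödinger perturbation theory in the intermolecular Coulomb
operator gives the dispersion energy as a sum over monomer transitions,

$$E^{(2)}_{\mathrm{disp}}
  \;=\; -\sum_{\mu\neq I}\sum_{\nu\neq J}
  \frac{w_{\mu\nu}^2}{\Delta E^A_\mu + \Delta E^B_\nu},
  \qquad \Delta E^A_\mu = E^A_\mu - E^A_I ,$$

with $w_{\mu\nu}$ the Coulomb coupling of the two transition densities
$\rho_A^{I\mu}$, $\rho_B^{J\nu}$ (all wave functions real). For ground-state
references every $\Delta E$ is positive. For an excited reference the manifold
contains *negative* transition energies ($\mu < I$), and the sum splits into
four parts by the sign pattern of the denominators. `dispersion_sos()` returns
exactly this partition (`part_up_up`, `part_down_down`, `part_up_down`,
`part_down_up`), enforcing two sign theorems: the (up, up) part is always
$\le 0$, and the (down, down) part — present only when both monomers carry
excitons — is always $\ge 0$, i.e. genuinely repulsive dispersion.

### Extended Casimir–Polder evaluation

For positive denominators the identity

$$\frac1{a+b}=\frac2\pi\int_0^\infty
  \frac{ab}{(a^2+\omega^2)(b^2+\omega^2)}\,d\omega, \qquad a,b>0$$

converts the (up, up) block into a frequency integral over the product of the
monomers' positive-transition response components $\chi_+^A \chi_+^B$ — the
classic Casimir–Polder (Longuet–Higgins) form. The identity is simply
unavailable for blocks touching a de-excitation, so those non-Casimir-Polder
terms are evaluated directly in closed sum-over-states form. That split is the
central engine decision in `dispersion_cp_extended()`: quadrature where the
theory defines a quadrature, exact summation everywhere else, and the two
engines must agree to high precision (the suite checks $<10^{-8}$ relative on
100 seeded random dimers; observed agreement is near machine precision).

Quadrature uses Gauss–Legendre nodes mapped by
$\omega=\omega_0(1+x)/(1-x)$. Defaults: 24 nodes, $\omega_0=0.5$ hartree.
The grid constructor self-tests the identity at $a=b=1$ and records the
deviation; `dispersion_cp_extended()` validates its result by doubling the
node count and adopts the doubled grid (up to three times) if the (up, up)
block moves by more than `conv_tol` (default $10^{-10}$ relative), erroring
out on persistent non-convergence rather than returning a silently
unconverged number.

### Adiabatic-connection route

For model monomers whose Hamiltonians are explicit matrices we define the
linear coupling-constant path $H(\alpha)=H_0+\alpha(H_1-H_0)$. The reference
state along the path is fixed by *continuity* from $\alpha=0$, tracked by
maximum eigenvector overlap — never by energy ordering, because states may
cross. If two overlaps agree within $10^{-3}$ at a tracking node, the crossing
is genuinely ambiguous and `alpha_spectrum()` refuses with an error naming the
$\alpha$.

The AC dispersion energy is taken as

$$E^{\mathrm{AC}}_{\mathrm{disp}}
 = \int_0^1 \frac{d}{d\alpha}\left[\alpha^2\,
   E^{(2),\alpha}_{\mathrm{disp}}\right] d\alpha ,$$

where $E^{(2),\alpha}_{\mathrm{disp}}$ is the full four-part second-order
dispersion energy (including its non-Casimir-Polder parts) built from the
spectra and couplings of $H(\alpha)$. This transcription was a genuinely open
design choice; we fixed it by two requirements. First, when $H_0=H_1$ the
integrand reduces to $2\alpha E^{(2)}$ and the integral collapses exactly onto
the plain sum-over-states value, which pins the normalization. Second, in the
zero-overlap regime (where the point-dipole couplings of the model fixtures
live) the integral builds up the monomer correlation along the path and lands
on the second-order dispersion energy of the *fully correlated* ($\alpha=1$)
monomers — exactly the consistency the theory asserts between the AC and
perturbation routes for a localized exciton with a single-determinant
partner. Freezing spectra and couplings at $\alpha=0$ instead gives the
uncoupled (UC) approximation, $E^{(2)}$ at the zeroth-order description
(`dispersion_uncoupled()`).

Numerically, the integrand's $\alpha$-derivative is taken by central finite
differences (step $10^{-5}$, one-sided second-order stencils at the interval
ends) and integrated with 8-node Gauss–Legendre on $[0,1]$ by default. The
suite validates the quadrature against a dense trapezoid of the same
integrand on 5001 nodes — dense enough that the oracle's own $O(h^2)$ error
sits well below the $10^{-8}$ agreement being asserted.

### reVV10 nonlocal correlation

The VV10 nonlocal correlation energy is

$$E_{\mathrm{nl}} = \tfrac12\iint \rho(\mathbf r)\,
  \Phi(\mathbf r,\mathbf r')\,\rho(\mathbf r')\,d\mathbf r\,d\mathbf r',
  \qquad
  \Phi=-\frac{3}{2\,g\,g'\,(g+g')},\quad
  g=\omega_0(\mathbf r)\,r_{12}^2+\kappa(\mathbf r),$$

with $\omega_0^2 = \omega_g^2+\omega_p^2/3$, $\omega_p^2=4\pi\rho$,
$\omega_g^2=C\,|\nabla\rho/\rho|^4$ and
$\kappa = b\,(3\pi/2)\,[\rho/(9\pi)]^{1/6}$. No uniform-density constant is
added: the dispersion-trained functional deliberately does not impose
vanishing for uniform densities. The defaults $C=0.013$, $b=2.84$ are the
dispersion-trained parameters (the original functional used $C=0.0093$,
$b=5.9$); the smaller $b$ damps less and binds more, as required of a
functional that must supply the entire long-range correlation missing from a
dispersion-free supermolecular method. $|E_{\mathrm{nl}}|$ is strictly
decreasing in $b$, which the suite checks.

The discretized double sum runs over all grid-point pairs, including the
finite $r_{12}=0$ self term $\Phi=-3/(4\kappa^3)$, in chunked vectorized form;
at desk-scale grids ($\le 10^5$ points) the full $O(N^2)$ sum is exact and
fast, so no distance cutoff is applied. Points with $\rho<10^{-10}$ bohr$^{-3}$
are skipped (never propagated as NaN). The counterpoise interaction energy
$E_{\mathrm{nl}}[\rho_{AB}]-E_{\mathrm{nl}}[\rho_A]-E_{\mathrm{nl}}[\rho_B]$
requires all three densities on *one shared* dimer-centered grid — the
functional's analogue of ghost-atom counterpoise — and rejects mismatched
grids outright, because the interaction energy is a small difference of large
totals and grid noise would contaminate it. With a shared grid the
$\rho_B\equiv0$ limit cancels to exactly zero.

## The synthetic fixtures: what they emulate, what they do not

`make_two_level_monomer()` and `make_random_spectrum()` generate few-level
monomers with signed transition energies and point transition dipoles;
`dipole_coupling()` couples them through the dipole–dipole tensor
$[\,\mathbf d_\mu\!\cdot\!\mathbf d_\nu-3(\mathbf d_\mu\!\cdot\!\hat n)
(\mathbf d_\nu\!\cdot\!\hat n)\,]/R^3$. This is the zero-overlap multipole
regime — precisely the regime in which the AC and perturbation routes must
agree, which makes it the right fixture class for engine cross-validation,
and it guarantees exact $R^{-3}$ coupling and $R^{-6}$ dispersion scaling.
Random spectra draw their gaps uniformly from $[0.1, 1.0]$ hartree, a
valence-excitation scale that also keeps random dimers safely away from
accidental resonances by construction.

What the model fixtures do *not* contain: charge-overlap and exchange
(damping) effects, vibronic structure, spin multiplets, or degenerate
references. Passing tests on these fixtures therefore demonstrate the
formulas' internal consistency and asymptotics, not the short-range behavior
of real complexes.

The built-in electronic-structure backend closes part of that gap: an
s-orbital Gaussian-basis full-CI engine (closed-form integrals via the Boys
function; STO-3G or single-Gaussian bases on H/He) produces *exact* monomer
spectra, transition densities, state densities and counterpoise ghosts for
hydrogenic systems. Exact diagonalization was chosen over a linear-response
backend deliberately: it makes the second-order formulas testable to machine
precision on real molecules. Its limits are equally deliberate: s functions
only, so hydrogenic systems only — aromatic chromophores are far outside its
scope, and real-system columns of the shipped benchmark tables are consumed
as data, not recomputed.

## Numerical choices

* **Resonance tolerance.** Any $|\Delta E^A_\mu+\Delta E^B_\nu|<10^{-6}$
  hartree is a hard error naming the pair $(\mu,\nu)$, not a damped or
  regularized contribution: the formulas presuppose a nondegenerate
  unperturbed dimer state, and silently regularizing would fabricate physics.
  (Two identical monomers with one excited are exactly this resonant case —
  the H$_2$ fixtures use unequal bond lengths for that reason.)
* **Units.** Hartree and bohr everywhere internally; kcal/mol only at
  reporting boundaries (1 hartree = 627.5095 kcal/mol). Geometries enter in
  ångström and are converted once at the `dimer_job()` boundary.
* **Molecular grids.** Atom-centered spherical product grids (mapped
  Gauss–Legendre radial, Gauss–Legendre $\times$ uniform angular) glued by
  Becke's fuzzy-cell partition (cutoff polynomial iterated three times);
  ghost centers carry grid points but no charge. Grid-based Coulomb couplings
  agree with the analytic integral oracle to $10^{-6}$ relative on the
  single-Gaussian basis with 40 radial and $12\times24$ angular points; the
  contracted STO-3G basis needs denser angular grids for the same target
  because its tight primitives put sharp product densities between the
  nuclei.
* **Problem sizes.** The test suite and the acceptance script run on
  two-to-six-level model monomers, 100-dimer engine cross-validations,
  $10^3$–$10^4$-point density grids and H$_2$-scale CI spaces — sizes chosen
  so the whole suite exercises every engine in about two minutes while
  keeping every comparison at its stated tolerance.
* **Table arithmetic.** The shipped benchmark tables print each component to
  two decimals. Sums and error statistics recomputed from printed columns are
  therefore compared within explicit rounding-propagation bounds (e.g.
  $6\times0.005$ for a six-component sum), never re-tuned: four of the eight
  SAPT rows reproduce their printed sum exactly and the rest agree within
  0.02 kcal/mol, and 15 of 16 printed error-summary cells reproduce within
  the bounds. The one exception — the excited-state SAPT column's printed
  summary — is inconsistent with its own printed column (recomputation gives
  an MUE of 0.27 kcal/mol rather than the printed 0.23, evidently computed
  from unrounded, differently corrected data); the suite pins the recomputed
  value and documents the discrepancy rather than hiding it.
* **$\delta_{\mathrm{CAS}}$ ratio.** The excited-state analogue of the
  beyond-second-order induction correction scales the ground-state
  $\delta_{\mathrm{HF}}$ by the excited/ground ratio of second-order
  induction. Whether the ratio should include exchange-induction is not
  decidable on first principles; the default includes it (the two terms
  describe one physical polarization response and their sum is the quantity
  whose shift the ansatz tracks), with `ratio_terms = "ind_only"` as an
  explicit switch.

## Known limitations

* De-excitation blocks are never evaluated by quadrature — by design, since
  the frequency identity does not apply — so there is no independent
  quadrature route for them; their validation is the SOS/CP cross-check on
  the (up, up) block plus closed-form examples.
* The CI backend's s-orbital limitation means electron counts, counterpoise
  and density additivity are demonstrated on H$_2$ (2 electrons), not on
  polyatomic chromophores; the benchmark tables for benzene/pyridine/peptide
  complexes are inputs, and their reproduction from first principles is out
  of scope.
* `dispersion_ac2()` addresses model Hamiltonians in matrix form; it does not
  implement the supermolecular AC correlation-energy machinery (which needs a
  linear-response backend and reduced density matrices beyond this package's
  remit).
* Retardation (real-photon exchange) contributions to excited-state
  dispersion are outside this nonrelativistic treatment.
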