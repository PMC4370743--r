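---
title: "The tightly bound ion model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tightly bound ion model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA backbones carry one negative elementary charge per phosphate, so folding
into compact tertiary structure works against a large Coulomb self-repulsion
that must be paid off by counterions. Monovalent salt (Na+) screens this
repulsion in a smooth, mean-field way that the Poisson-Boltzmann (PB)
equation describes well. Divalent Mg2+ is different: near the RNA surface it
reaches local densities at which ion-ion Coulomb coupling is several kBT, so
the binding events at different sites are correlated and the ion cloud
fluctuates between discrete arrangements. Mean-field theories average these
arrangements away and systematically underestimate the Mg2+ effect.

`tbion` treats the two regimes separately:

* **Tightly bound ions.** A thin layer around the molecular surface (the
  tightly bound region) is partitioned into one cell per phosphate. Mg2+
  ions inside the layer are treated as discrete particles: a *binding mode*
  assigns 0 or 1 ion to each cell, and the ensemble over modes is summed
  explicitly, which is what captures correlation and fluctuation.
* **Diffusive ions.** Na+, Cl-, and Mg2+ outside the layer form a mean-field
  atmosphere described by the full nonlinear PB equation, solved with the
  RNA charges plus any tightly bound ions as fixed sources.

## Energies

For one placement of the tightly bound ions, the energy of the charges in
the tightly bound region is a Generalized Born (GB) decomposition:

* `u_ele`: direct Coulomb sum `sum_{m<n} q_m q_n / (eps_in r_mn)` at the
  interior dielectric (default `eps_in = 12`);
* `u_pol`: the cross reaction-field term
  `(1/eps_w - 1/eps_in) sum_{m<n} q_m q_n / f_GB` with the Still kernel
  `f_GB = sqrt(r^2 + B_m B_n exp(-r^2/(4 B_m B_n)))`;
* `u_self`: the Born self term `(1/eps_w - 1/eps_in) sum_x q_x^2/2 (1/B_x -
  1/B0_x)`.

Effective Born radii `B` come from the Coulomb-field approximation: `1/B =
1/a - (1/4pi) * integral dV/r^4` over the low-dielectric volume outside the
charge's own sphere, evaluated by grid quadrature on the same smoothed
atom-sphere union that defines the PB dielectric boundary.

The diffusive contribution of a PB field `psi` (and `psi_prime`, the pure
Poisson solution of the identical fixed-charge problem) is

* enthalpy `dU_d = 1/2 integral sum_a c_a z_a (psi + psi') dV` and
* entropy `-T dS_d = integral sum_a [c_a ln(c_a/c0_a) - c_a + c0_a] dV`,

with `c_a = c0_a exp(-z_a psi)` on ion-accessible nodes and zero elsewhere.
The bracketed entropy integrand is pointwise non-negative, so `-T dS_d >= 0`
always; excluded volume (the Stern shell and the molecular interior)
contributes `c0` per species.

### The reference state

The self term needs a reference radius `B0`. For a bound Mg2+ ion we use its
hydrated radius, so an isolated ion has zero self energy and burial costs
desolvation. For a phosphate the package uses the phosphate's Born radius in
its *own isolated nucleotide* (the integral restricted to own-residue
atoms). Two reasons:

1. It makes `dG_tot` the electrostatic free energy of *assembling* the
   structure from separated, solvated nucleotides — the quantity that
   per-nucleotide length scaling (`scale_intermediate`) implicitly assumes,
   and the natural zero for folding thermodynamics. Referencing a bare
   sphere instead would fold the large, structure-independent solvation
   energy of the phosphate-in-its-nucleotide into every total.
2. Since `B` and `B0` come from the same integrator, the leading quadrature
   bias of the r^-4 integral cancels in `1/B - 1/B0`.

The printed no-subtraction form (`1/2 (1/eps_w - 1/eps_in) q_p^2/B_p`)
remains available as `u_self(..., reference = "uniform")` for analysis of
the raw Born term.

### Mode weights

A mode with bound cells `i in M` has weight

```
w_M = prod_{i in M} [ c0_Mg * v_i ] * < exp(-E/kBT) >
```

where `c0_Mg` is the bulk Mg2+ number density, `v_i` the cell volume, and
the average runs over uniform placements of the ions inside their cells
(the exponential, partition-function average — not the arithmetic mean of
energies). This fugacity form is the dimensionless reduction of the
configurational integral over the tightly bound ions, and it is unit-tested
against a brute-force two-cell enumeration. Then

```
dG_M   = -kBT ln w_M
dG_tot = -kBT ln sum_M exp(-dG_M/kBT)
P_M    = exp(-(dG_M - dG_tot)/kBT)
```

The reported components are the `P_M`-weighted placement averages `dE_ele`,
`dG_pol`, `dG_self`, and the entropic remainder `dG_s = dG_tot - (dE_ele +
dG_pol + dG_self)`, which absorbs the diffusive-ion terms and the
positional/combinatorial entropy of the tightly bound ions.

### Double counting at the layer boundary

Because Mg2+ inside the tightly bound layer is already represented by the
discrete modes, the diffusive Mg2+ is excluded from that layer in the PB
solve (its Stern exclusion is hydrated radius + `t_shell`). Without this,
the mean-field Mg2+ populating the same shell is counted twice and the
charge-neutrality sum `2 sum_i f_Mg(i) + N f_Na` overshoots the backbone
charge.

## Numerics

* **PB discretization.** 7-point finite differences; dielectric on links by
  harmonic mean; boundary smoothed over one grid cell. The nonlinear
  Boltzmann source is handled by outer damped-Newton linearization with
  red-black SOR sweeps inside (`omega = 1.9`); convergence when the largest
  potential change over a Newton iterate is below `tol = 1e-6` kBT/e.
  Exponents in the Boltzmann factors are capped at |z psi| = 40 — this only
  matters inside Stern regions that are ion-inaccessible anyway.
* **Focusing.** Two levels: a coarse grid (3x the fine spacing) padded by
  max(4 Debye lengths, 15 A) with screened-Coulomb Dirichlet values, then a
  fine grid (default 0.8 A, 10 A padding) with boundary values interpolated
  from the coarse solution. Four Debye lengths keep the truncated far-field
  share of the diffusive integrals below about 2%. `psi_prime` uses the
  same ladder with plain-Coulomb boundary values and the mobile terms off.
  Volume integrals are spliced: the fine grid integrates its own box, the
  coarse grid the remainder.
* **Born quadrature.** Default 0.6 A grid; voxels closer than `a + 2h` to
  the charge are subsampled 3x3x3 against the r^-4 singularity. Verified
  against the isolated-sphere and buried-sphere closed forms and a 0.08 A
  brute-force two-sphere integral (2%).
* **Cells and placements.** The tightly bound region is the shell between
  the Mg2+ contact surface and `t_shell = 3 A` beyond it, partitioned by
  nearest phosphate on the working grid; ion placements are uniform over
  cell voxels with intra-voxel jitter. Default 20 placements per mode;
  energies are combined with the exponential average, so the estimator is
  consistent with the configurational integral.
* **Mode sets.** Full enumeration when `sum_k C(N,k)` fits the budget;
  otherwise guided sampling: the empty mode and all single-ion modes are
  always evaluated, multi-ion modes are built by extending the
  lowest-energy modes with the best-ranked cells (plus a seeded random
  remainder). A sweep over concentrations reuses one seed (common random
  numbers) so that the monotone fugacity dependence is not masked by
  sampling noise. Ties for the most probable mode break toward fewer ions,
  then lexicographic cell order.
* **Caching.** PB evaluations are cached by bound-ion fingerprint; the
  phosphate-only GB configuration and the empty-mode field are computed
  once per run.

## The helix generator

`generate_aform_helix()` builds an idealized A-form duplex from fibre-type
parameters: rise 2.81 A/bp, twist 32.7 deg/bp, phosphates 9.4 A from the
axis. Each residue carries seven pseudo-atoms (P, O5', C4', C1', N9, C5,
C2) tracing backbone and base so that the sphere union forms a realistic
low-dielectric body; the second strand is the exact dyad image of the
first, phased so the strands sit 110 degrees apart at equal height, which
reproduces the A-form narrow/deep major groove (closest cross-strand P-P
about 8.7 A) and wide/shallow minor groove. The generator emulates the
charge geometry and dielectric body of double-stranded RNA; it does not
emulate sequence-dependent structure, terminal fraying, non-helical
elements, or atomic-level surface texture. Tests that pass on this fixture
therefore validate the electrostatic engine on helix-like geometry; they do
not by themselves establish accuracy for irregular tertiary folds.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `eps_in` | 12 | - | RNA interior dielectric |
| `eps_w` | from T | - | water dielectric, cubic polynomial in Celsius |
| `radii` | Bondi-style | A | dielectric boundary (H 1.2, C 1.7, N 1.55, O 1.52, P 1.8) |
| `ion_radius` | Na 3.5, Mg 4.5, Cl 3.5 | A | hydrated radii: Stern exclusion and ion `B0` |
| `t_shell` | 3.0 | A | tightly bound layer thickness beyond Mg2+ contact |
| `spacing` | 0.8 | A | fine PB grid |
| `pad_coarse` | 4 Debye lengths | A | far-field truncation |
| `n_samples` | 20 | - | placements per mode |
| `mode_budget` | 200 | - | modes before sampling replaces enumeration |

The zero-Mg2+ free energy of the 24-nt helix fixture at 0.1 M Na+, 37 C is
the calibration anchor for these defaults: the settings above reproduce the
reference value of 30.30 kcal/mol within a few percent (the acceptance
suite computes the number; the reference implementation's exact grid,
radius and shell settings are not published, hence the tolerance band).

## Problem sizes used by the test-suite

The shipped tests run on deliberately small systems so the whole suite
stays fast: one- and two-sphere toys for the solver and GB limits, a 2-cell
toy for the brute-force partition-function oracle, a 3-bp helix for the
concentration sweep, and the 12-bp helix (single PB evaluation) for the
calibration anchor. Production-scale runs (tens of nucleotides with Mg2+
mode sampling) use the same code paths with larger budgets.

## Known limitations

* One ion per cell; very high [Mg2+] regimes where multiple correlated ions
  share a cell are outside the model.
* Na+ is never tightly bound (weakly correlated by assumption); systems
  whose monovalent ions condense strongly (e.g. very low dielectric
  solvents) are out of scope.
* The layer thickness `t_shell` stands in for a correlation-strength
  criterion; results should be reported together with its value.
* No ion dehydration, chelation, or site-specific (inner-sphere) binding:
  the most probable mode is an electrostatic statement, not a predicted
  crystallographic site.
* Unit charges on P atoms only; no partial-charge model.
* Monte-Carlo position averaging and guided mode sampling make Mg2+ results
  stochastic at fixed seed quality; the acceptance checks use seeded runs
  and tolerance bands accordingly.
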