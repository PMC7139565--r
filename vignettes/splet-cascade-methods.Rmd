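---
title: "Methods: cumulative SPLET thermochemistry for multi-phenol antioxidants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative SPLET thermochemistry for multi-phenol antioxidants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spletcascade)
```

## The model

A phenolic antioxidant neutralizes a free radical by surrendering the H of
an O–H group. The three candidate mechanisms differ only in the order of
proton and electron loss — HAT (both at once), SET-PT (electron first),
SPLET (proton first) — and each step is scored by an enthalpy difference
between solvated species:

- BDE = H(PhO•) + H(H•) − H(PhOH)
- IP = H(PhOH•⁺) + H(e⁻) − H(PhOH), PDE = H(PhO•) + H(H⁺) − H(PhOH•⁺)
- PA = H(PhO⁻) + H(H⁺) − H(PhOH), ETE = H(PhO•) + H(e⁻) − H(PhO⁻)

Entropy is neglected throughout (−TΔS is small for these proton/electron
transfers in solution), so preference arguments are made from enthalpy
alone. The package never computes quantum-chemical enthalpies; it consumes
them — as a *ledger* mapping each protonation/oxidation microstate of a
compound to one enthalpy (kJ/mol internally; Hartree accepted at the I/O
boundary, 1 Hartree = 2625.4996 kJ/mol). Lookups of microstates that were
never computed raise an error naming the state; nothing is imputed.

For a compound with several phenolic sites, each site is one of
protonated (`OH`), phenoxide (`O-`) or phenoxy radical (`O*`), plus a
molecule-level radical-cation flag on the neutral parent. The formal
charge is derived, never stored. A three-site compound therefore has 3³
site microstates plus the radical cation.

### Reference enthalpies and scale conventions

`reference_enthalpies()` bundles the enthalpies assigned to the small
species, with methanol defaults H(H•) = +5, H(H⁺) = −1071,
H(e⁻) = −77 kJ/mol, and −303 kJ/mol for the reduction of the DPPH radical
by an electron. These are stored constants — computing solvation
enthalpies of the proton or electron from first principles requires
explicit quantum mechanics on the solvent and is out of scope.

The constants enter the definitions *directly* as H(H•), H(H⁺), H(e⁻).
Two consequences deserve care:

1. The cycle identity IP + PDE = PA + ETE = BDE + (H(H⁺) + H(e⁻) − H(H•))
   holds *exactly* for any ledger, whatever the constants, because all
   routes connect the same two species. `descriptor_set()` documentation
   treats this as the module's internal oracle; the test suite asserts it
   to 1e−6 kJ/mol on every generated ledger.
2. If the ledger holds absolute quantum-chemistry enthalpies, BDE computed
   with H(H•) = +5 sits on a different absolute scale than a BDE computed
   with the full quantum enthalpy of the hydrogen atom (≈ −0.5 Hartree
   plus thermal terms). Users matching absolute scales should supply
   `h_atom` as (gas-phase QM enthalpy of H•) + 5, and may add
   `gas_phase_proton_enthalpy()` ((5/2)RT, the complete enthalpy of an
   ideal-gas proton: 6.197 kJ/mol at 298.15 K) to the proton constant.
   Every relative comparison within one mechanism, and the whole SPLET
   cascade, is unaffected by this choice because the constants cancel in
   differences and orderings.

## The cumulative cascade

`run_cascade()` drives every site of a compound from `OH` to `O*`:

1. From the current species state, compute the PA of **each** remaining
   protonated site (deprotonation enthalpy *from that state*, not from the
   parent).
2. Deprotonate the site with the lowest PA; break exact ties by site-label
   order, so traces are reproducible.
3. Remove the electron from that phenoxide immediately (raw ETE), add the
   partner-radical reduction enthalpy for the net step, and continue until
   all sites are radicals.

Recomputing PA from the current state matters: rings that already reacted
shift the enthalpies of the remaining ones, which is the observed
"PA drifts down, ETE drifts up" pattern in dendritic tri-phenols and the
reason the cascade total ΔH_cum can exceed the naive per-site sum ΔH_tot
(`dh_tot()`). Each step completes both sub-steps before the next site is
chosen; there is no pool of partially deprotonated intermediates.

Two totals are always reported: `dh_cum_net` (electron transfers coupled
to the partner radical) and `dh_cum_raw` (antioxidant species only), which
differ by exactly n_steps × radical_reduction. `dh_cum_raw` telescopes to
H(all-radical) − H(parent) + n·(H(H⁺) + H(e⁻)) — Hess's law — so it is
invariant under the visiting order. The suite brute-forces all n!
orderings of 2- and 3-site ledgers and checks agreement to 1e−9 kJ/mol,
and checks that the greedy first step is the cheapest first step among all
orderings. A fixed ordering (`ordering = c("Y", "X", ...)`) is supported
both for replaying literature paths with minimal (path-only) ledgers and
for sensitivity checks.

`ledger_from_step_values()` inverts a published trace: given per-step PA
and ETE it reconstructs species enthalpies along the path, and places each
off-path phenoxide `margin` kJ/mol per rank above the chosen step's PA.
The margin (default 1 kJ/mol) only pins the greedy order; no step value or
total depends on it. This is how the bundled `benchmark_ledgers()` turn
printed step tables back into executable ledgers.

### Fragments and starting materials

`fragment_comparison()` scores a set of independent mono-phenolic
fragments (weighted by integer multiplicities) against the compound's
cumulative totals. Fragments are scored at their parent state — they have
one site, so cumulative and naive totals coincide — and the comparison
reports the compound-minus-fragments differences for PA, ETE and ΔH.

## Mechanism preference

No formal decision rule exists in the literature for "preferred
mechanism"; the rule here is an explicit design choice, recorded in every
verdict. Uncoupled route *totals* are identical up to the constant above,
so totals cannot discriminate. `compare_mechanisms()` therefore scores
each route by its **rate-limiting (maximum) step enthalpy** — the step
structure is exactly what distinguishes the routes (SET-PT's large first
step, SPLET's small first step). Per-site routes (HAT, SPLET) are scored
at their most favorable site. With `coupled = TRUE` the partner-radical
reduction enthalpy is added to whichever step hands the electron to the
radical — SPLET step 2 and, symmetrically, SET-PT step 1; HAT transfers
the hydrogen atom directly and receives no coupling. The uncoupled
variant is always computable for comparison. Exact ties resolve in the
fixed documented order HAT, SET-PT, SPLET. With descriptor sets drawn
from the synthetic generator's default (dendritic-phenol-like) regime and
DPPH coupling, the verdict is SPLET — computed, not asserted, in the test
suite.

The global IP is one value per compound (electron loss is a molecular
property). The global PDE is reported as the minimum per-site PDE — the
most favorable deprotonation of the radical cation — since which ring the
cation loses its proton from is not observable from a ledger; per-site
values remain available via `pde()`.

## Activity correlation

`activity_records()` joins cumulative cascade quantities (PA_cum, net
ETE_cum, ΔH_cum) with experimental DPPH IC50 values, which are **input
data** from the assay — the package never estimates them.
`pearson_r()` validates (n ≥ 3, finite, nonzero variance) and delegates to
the standard product-moment estimator; `fisher_ci()` is the closed-form
Fisher-Z interval tanh(atanh r ± z\*/√(n−3)) with the two-sided normal
quantile (1.95996 at 95%) — the standard construction, chosen because it
reproduces published interval bounds for these data to the printed
precision. `delta_series()` gives the differences-vs-reference view
(reference row maps to zeros; the operation is idempotent). No regression
model of IC50 on enthalpy is fitted, and no significance testing beyond
the interval is attempted.

## The synthetic generator

`generate_ledger()` produces a complete ledger (all 3ⁿ microstates plus
the radical cation) from a `synthetic_spec()`:

H(state) = base + Σᵢ costᵢ(stateᵢ) + Σᵢ<ⱼ εᵢⱼ·[both i,j non-protonated] + noise

with the `O-`/`O*` costs inverted from requested parent-state PA/ETE
targets under the chosen reference enthalpies. Design choices:

- **Defaults are the study conditions**: three sites, parent-state PA 150
  and raw ETE 355 kJ/mol (the first-step values of an unsubstituted
  tri-phenolic dendrimer in methanol), IP 470 kJ/mol (mid-range for
  *ortho*-substituted phenols in polar solvents under these conventions),
  parent enthalpy −1000 kJ/mol (an arbitrary offset; only differences
  matter, and descriptor invariance under uniform shift is tested).
- **Substituent electronics as offsets**: an electron-donating group is
  δETE < 0 with a mild δPA > 0; electron-withdrawing mirrored. The
  generator property that donors beat acceptors on the coupled total
  whenever |δETE| > |δPA| is asserted in the tests.
- **Ring–ring interaction** is a pairwise penalty εᵢⱼ applied when both
  sites are non-protonated — the simplest structure that yields
  ΔH_cum > ΔH_tot and a monotone step drift. The gap has the closed form
  ΔH_cum(raw) − ΔH_tot = Σᵢ<ⱼ εᵢⱼ, which the tests verify. Because ε does
  not distinguish phenoxide from radical, the drift appears in PA only;
  real compounds also drift in ETE, so the generator reproduces the
  *existence* of cooperativity, not its detailed shape.
- **Noise is Gaussian on species enthalpies** (where a quantum-chemistry
  workflow's variability lives — conformers, convergence), not on
  descriptors. A descriptor recovery error is then a difference of two
  species noises, sd √2·noise_sd; with noise_sd = 2 kJ/mol the RMSE of
  `recover_offsets()` over 100 seeds is checked against the 1–4 kJ/mol
  band implied by that closed form.
- **Seeded always**: there is no unseeded path, and the generator
  restores the caller's RNG state.

What passing tests on synthetic ledgers do *not* show: that any real
compound's enthalpies follow the additive-plus-pairwise form, that noise
in DFT thermochemistry is Gaussian or independent across microstates, or
anything about conformers, intramolecular H-bonding, or solvents other
than the one encoded in the reference constants.

## Numerical choices

- Enthalpies are stored and summed at full double precision; rounding to
  integer kJ/mol (half away from zero, `round_half_up()`) happens only at
  report time, matching how such tables are printed. Published integer
  step values sum consistently either way.
- Ledger keys are canonical state codes (sites sorted by label,
  `X:O-;X':OH;Y:OH`, `+cation` suffix), so lookups are deterministic and
  duplicate detection is exact.
- Tolerances: cycle closure 1e−6 kJ/mol (pure algebra; anything larger
  indicates a corrupted ledger), path invariance 1e−9 kJ/mol relative to
  totals of order 10³.
- Degenerate inputs fail loudly: ledgers without the parent state, duplicate
  states, unknown site labels, non-positive IC50, zero-variance series,
  |r| = 1 in the Fisher transform, n < 4 intervals.

## Problem sizes

The test suite and acceptance script run on 1–4-site ledgers (27 + 1
microstates at three sites), full permutation enumeration up to 3! orders,
and 100-seed Monte-Carlo for noise calibration — a few seconds in total,
while still exercising every code path end to end.

## Known limitations

- Enthalpy-only: no free-energy corrections, no kinetics — a mechanism
  verdict is thermodynamic, and "electron transfer is fast" type kinetic
  arguments are outside the model.
- Solvent dependence enters only through the reference constants; swapping
  solvents means supplying a new `reference_enthalpies()` and a ledger
  computed in that solvent.
- The radical-cation species is tied to the neutral parent, so SET-PT is
  modeled for the first scavenging event only; the cascade is a SPLET
  construct.
- Site equivalence (X/X′ averaging) is declared metadata, never inferred
  from enthalpy closeness — a deliberate refusal to guess thresholds.
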