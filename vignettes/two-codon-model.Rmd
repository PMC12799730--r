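---
title: "The two-codon translation model: methods and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-codon translation model: methods and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocodon)
```

## The model and its assumptions

The package models translation of a homogeneous pool of `N` transcripts, each
`L` codons long, by `R_tot` ribosomes. Codons come in exactly two classes —
*optimal*, read by the preferred tRNA (total `T1_tot`), and *non-optimal*,
read by the non-preferred tRNA (`T2_tot`) — and a transcript is characterized
entirely by its fraction of optimal codons, `f_op`. Seven counts evolve:
charged and uncharged tRNAs of each species (`T_c1`, `T_u1`, `T_c2`, `T_u2`),
free ribosomes (`R_f`), and ribosomes bound to each codon class (`R_b1`,
`R_b2`).

The reactions are mass-action:

* **Charging.** Uncharged tRNA is re-aminoacylated at rate
  `k_charge * T_ui`, with one shared `k_charge` for both species — the model
  deliberately collapses all synthetase kinetics into a single constant.
* **Initiation.** Free ribosomes bind at `k_bind_eff * N * R_f`; each
  transcript carries one binding site. A newly bound ribosome sits on an
  optimal codon with probability `f_op`, consistent with the
  composition-only description of movement.
* **Elongation.** A ribosome on class *i* advances at `k_speed * T_ci`
  (class-wide flux `k_speed * R_bi * T_ci`), consuming one charged tRNA of
  that class per step. After a step the ribosome terminates with probability
  `1/L`, otherwise it lands on an optimal codon with probability `f_op`.
  Termination frees the ribosome and releases one protein, so the protein
  expression rate is the off-rate
  `P_r = k_speed * (R_b1*T_c1 + R_b2*T_c2) / L`.

Three assumptions do the heavy lifting. First, the **mean-field** treatment
of ribosome position: only the codon *composition* matters, not the
arrangement of codons along the transcript (the codon-resolved simulator
exists to test exactly this). Second, **no steric interference** between
ribosomes by default. Third, totals are conserved — no transcription, mRNA
decay, ribosome drop-off, or tRNA synthesis.

The bound-ribosome kinetics deserve one explicit note. A reduced description
of ribosome movement between codon classes can be written with the exchange
fluxes alone (`R_b2*T_c2*f_op` against `R_b1*T_c1*(1 - f_op)`); that form
conserves `R_b1 + R_b2` separately and is inconsistent with a free-ribosome
pool that exchanges with the bound pool through initiation and termination.
`ode_rhs()` therefore uses the full accounting: each bound class gains
`k_bind_eff*N*R_f` split by composition, loses `k_speed*R_bi*T_ci / L` to
termination, and exchanges the remaining `(1 - 1/L)` share of the elongation
flux by composition. Total ribosome and per-species tRNA derivatives sum to
zero identically, and at the stationary point the initiation/termination
terms cancel so the exchange balance
`R_b1*T_c1*(1 - f_op) = R_b2*T_c2*f_op` is recovered exactly. All
steady-state results are identical under either bookkeeping; time courses
and the stochastic simulators require the full one.

## Parameters, units, and the calibrated baseline

| Field | Units | Reference value | Meaning |
|---|---|---|---|
| `T1_tot`, `T2_tot` | molecules | 2500 total, split 50:50 / 70:30 / 90:10 | tRNA pools |
| `R_tot` | molecules | 500 | ribosomes |
| `N` | molecules | 100 | transcripts = binding sites |
| `L` | codons | 300 | transcript length |
| `k_charge` | s⁻¹ | 3–300 explored | charging constant |
| `k_speed` | per charged tRNA per bound ribosome s⁻¹ | 0.02 | elongation constant |
| `k_bind_eff` | per molecule pair s⁻¹ | calibrated | effective binding constant |
| `f_op` | — | 0–1 | optimal-codon fraction |

Two unit conventions matter. `k_speed` multiplies `R_b * T_c`, so it is a
second-order constant; the biologically meaningful translation speed in
codons/s is `k_speed * T_c` (≈ 22 codons/s at the calibrated baseline).
Measured ribosome binding constants are molar (`2.5e6 M⁻¹s⁻¹` is the
reference value); the mass-action term needs a per-molecule constant, and
`molar_to_effective_bind()` divides by Avogadro's number times a
user-chosen reaction volume. The packaged baseline does **not** assume a
volume: `calibrate_rates()` fixes `(k_charge, k_bind_eff)` so that the
symmetric system reproduces two empirical anchors for exponentially growing
bacteria, 88% charged tRNA and 88% active ribosomes. That calibration is
computed at first use (not hard-coded) and yields `k_charge ≈ 32.3 /s` and
`k_bind_eff ≈ 5.38e-3` — numerically close to the molar constant in a
typical scaled-down cytoplasmic volume of order `1e-15` L, which is a useful
sanity check rather than an input. The resulting steady state also shows
0.49 ribosomes per 100 nt and 22 codons/s per active ribosome, inside the
measured 0.3–0.6 and 13–22 ranges. We report the per-active-ribosome speed
exactly as defined by `steady_summary()` (flux divided by bound ribosomes)
and make no attempt to force it to any particular tabulated value, since
averaging conventions (per-active vs per-total, time vs ensemble) differ
between sources.

```{r calibration}
p <- load_reference_params("baseline")
c(k_charge = p$k_charge, k_bind_eff = p$k_bind_eff)
glance(steady_state(p))
```

## Numerical design

**Steady state.** Writing `x_i = R_bi * T_ci`, the exchange balance forces
`x1 = f_op * S`, `x2 = (1 - f_op) * S` for the total flux `S`; the charging
balances give `T_ci = Ti_tot - x_i k_speed / k_charge`, leaving one scalar
equation in `S` that is strictly decreasing on `[0, S_max)` (where `S_max`
is the flux that would exhaust a charged pool). The root is therefore unique
and bracketed; `uniroot()` locates it and a safeguarded Newton iteration
polishes it to machine precision. This one-dimensional reduction has no
starting-point sensitivity at all, which is why it was chosen over a damped
multivariate Newton on the four unknowns. Three of the four balances and all
conservation laws hold *exactly by construction*; the reported residuals
(`steady_residuals()`) scale each equation by its natural flux scale (e.g.
`k_bind_eff*N*R_tot` for initiation) so the check stays meaningful when a
species is driven to a vanishing count. Default residual tolerance:
`1e-10` relative, configurable. The uncharged pools are computed as
`x_i k_speed / k_charge` directly rather than by subtraction, avoiding
cancellation at fast charging.

**Boundaries and limits.** `f_op` exactly 0 or 1 collapses the system to a
quadratic in the active flux (`one_codon_steady()`, solved with the
numerically stable root form); `steady_state()` dispatches there
automatically. A tRNA species with zero molecules requires that its codon
class be absent (validation error otherwise). `infinite_charging_rate()`
gives the fully-charged limit, where the per-ribosome speed is the
`f_op`-weighted harmonic mean of `k_speed*Ti_tot`.

**Locating the expression maximum.** `find_fop_max()` scans a grid (default
step 0.01) and refines the bracketing interval by golden section (default
final width `1e-3`), comparing the refined point against the bracket
endpoints so a maximum at `f_op = 1` is reported as exactly 1. Grid ties
break toward the smaller `f_op`. When the whole curve is flat to within
`1e-9` relative — equal tRNA pools in the fast-charging limit — the maximum
is genuinely undefined and is reported as `NA` with `flat = TRUE` rather
than an arbitrary argmax. Note that at `k_charge = 300 /s` the symmetric
system still shows a ~1% bow in `P_r(f_op)` (the insensitivity is exact only
as `k_charge` diverges; the curve is always symmetric under
`f_op -> 1 - f_op`). If a steady state fails inside the refinement bracket,
the coarse-grid argmax is returned flagged `refined = FALSE`.

**Stochastic simulators.** Both SSAs are direct-method Gillespie in Rcpp —
one uniform pair per event, no tau-leaping — because they serve as exactness
oracles for the deterministic solver. All draws come from R's RNG;
replicate *i* is seeded `seed + i - 1`, so runs are bit-reproducible. The
mean-field SSA treats termination per elongation event with probability
`1/L` (a geometric approximation of transcript length). The codon-resolved
SSA tracks every ribosome's transcript and codon position on explicit
sequences and terminates positionally when a ribosome steps past codon `L`;
because the elongation propensity depends only on the codon class under the
ribosome, ribosomes are sampled uniformly within class. Optional steric
exclusion (footprint in codons) is implemented by thinning — a blocked
ribosome drawn for elongation is a null event — which preserves exactness;
it defaults off to match the mean-field assumptions. Stationary estimates
use a burn-in of half the simulated time by default and report
across-replicate standard errors.

**Growth-rate conversion.** `growth_rate()` solves
`r = kC (b e^{-lysis_time * r} - 1)` with `b = p / virion_size`. The right
side decreases and the left increases in `r`, so the root is unique; the
bracket `[-kC, max(kC(b-1), 0) + 1]` (exact at `p = 0`) is expanded
geometrically if needed and the `uniroot()` result is Newton-polished to a
residual below `1e-12`. Burst sizes of exactly 0 or 1 return `-kC` and 0
without iteration. The general `kC` is implemented, but only `kC = 1/min`
has any external anchor; other values are exercised by round-trip residuals
only.

## What the synthetic conditions do and do not show

The packaged reference sets *are* the study conditions: 2500 tRNAs (split
50:50, 70:30 or 90:10), 500 ribosomes, 100 transcripts of 300 codons,
`k_speed = 0.02`, `k_charge` swept over 3–300 /s, all species counts scaled
down orders of magnitude from a real cell. The scaling law is what makes
this legitimate for the *deterministic* quantities: multiplying the tRNA
pools by `alpha` while dividing `k_charge` and `k_speed` by `alpha` leaves
`P_r` exactly invariant (`scaling_deviation()` verifies this to solver
precision, and the SSA means agree within Monte-Carlo error). Random
transcripts from `generate_transcript()` place codon classes independently
(exact-count or Bernoulli); real coding sequences have autocorrelated codon
usage, 61 codons, wobble pairing, and amino-acid constraints, none of which
are represented. Agreement between the codon-resolved and mean-field
simulators here therefore shows the *mean-field reduction* is sound for
composition-dominated questions — including mixed transcript pools, which
match the homogeneous surrogate at the codon-mass-weighted `effective_fop()`
within Monte-Carlo error in our tests at equal lengths — not that real
genomes are two-codon systems. Widely different transcript lengths in a
mixture remain an untested regime for the surrogate; the codon-resolved
simulator is the tool to quantify it. Ribosome exclusion is off by default;
at the reference densities (~0.5 ribosomes per 100 nt, ~15 codons apart)
occasional queueing exists but is rare enough that the mean-field
comparison passes, and the `footprint` option exists to probe it.

Test problem sizes were chosen to keep the default suite fast while leaving
Monte-Carlo error well below the effects being checked: SSA consistency
tests run 4–5 replicates of 400–800 s; the full stochastic-vs-numeric
cross-validation runs 10 replicates of 5000 s with a 2500 s burn-in and
checks every species mean and the protein rate within three standard
errors.

## Known limitations

* Exactly two codon classes and two tRNA species; no sequence-level biology.
* No transcription, mRNA decay, ribosome drop-off, or synthetase saturation;
  `k_charge` is shared by both species.
* The mean-field `f_op^max` analysis is deterministic; stochastic effects on
  the *location* of the maximum (as opposed to the rate) are not studied.
* The growth-rate conversion assumes only capsid abundance changes between
  conditions — lysis time and adsorption are fixed inputs, and the model is
  silent on any feedback from growth rate back onto expression.
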