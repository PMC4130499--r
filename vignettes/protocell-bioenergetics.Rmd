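---
title: "Modelling chemiosmotic free energy in protocells on natural proton gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemiosmotic free energy in protocells on natural proton gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomotive)
```

## The model

`protomotive` simulates a spherical protocell (radius 1 µm by default)
sitting at the interface between two clamped fluids: a relatively
acidic ocean-like fluid (pH 7, Na⁺ 0.4 M, K⁺ 0.01 M, Cl⁻
charge-balancing) on one hemisphere and an alkaline fluid (pH 10, same
salt background) on the other. The two exteriors never change — they
stand for large reservoirs replenished by flow — while the interior
evolves under the summed fluxes of five ions (H⁺, OH⁻, Na⁺, K⁺, Cl⁻)
across the lipid phase and through up to four membrane proteins.
The central reported quantity is the electrochemical free energy of
inward ion transfer across the acid face,

$$\Delta G_i \;=\; z_i F \Delta\psi + RT\,
  \ln\frac{[i]_\mathrm{in}}{[i]_\mathrm{acid}},$$

printed as $-\Delta G$ (kJ/mol): the driving force a membrane protein
on the acid face can harvest. With a 3-pH-unit chemical gradient and no
potential, $-\Delta G_\mathrm{H} = 2.303\,RT \times 3 = 17.1$ kJ/mol at
298 K; 20 kJ/mol of purely electrical driving force corresponds to
$\Delta\psi \approx 207$ mV.

### Passive fluxes and the membrane potential

Sodium, potassium and chloride cross the bilayer as bare ions. Their
fluxes follow the Goldman–Hodgkin–Katz (constant-field) flux equation,
evaluated separately on each face with that face's external
concentration, and they jointly set the membrane potential through the
GHK voltage equation. Because one potential spans a cell with two
different exteriors, each ion's "external" concentration in the
voltage equation is the face-area-weighted mean of its two face
values; for GHK fluxes this pooling is exactly the potential at which
the summed passive current over both faces vanishes, so it is the
quasi-static (zero-capacitance) closure, not merely a convenience.

Protons and hydroxide are treated differently, and deliberately so.
In mixed-amphiphile membranes the dominant H⁺ translocation mechanism
is fatty-acid flip-flop: the ion crosses as part of a transiently
neutral carrier species, not as a bare charge drifting in the membrane
field. We therefore model the lipid-phase H⁺ and OH⁻ fluxes with the
linear diffusion law $J = P A ([S]_\mathrm{ext} - [S]_\mathrm{int})$
per face, and exclude both from the constant-field voltage equation.
Two observations motivated this choice over giving H⁺/OH⁻ the bare-ion
GHK treatment. First, with OH⁻ as a GHK anion at the H⁺ permeability,
the thousand-fold OH⁻ asymmetry between the faces dominates the pooled
voltage and pins $\Delta\psi$ near −0.1 V in every scenario. Second,
that potential creates a spurious attractor in which the Na⁺/H⁺
antiporter runs backwards — the cell loads itself with sodium and
acidifies below the acid fluid — which contradicts the behaviour the
antiporter scenarios are built to probe. The carrier treatment removes
both artefacts, and it reproduces the concentration-kinetic mechanism
behind the gradient-placement asymmetry discussed below. The exported
`ghk_flux()` and `ghk_voltage()` are general-purpose and are used by
the simulator for the bare ions.

The default permeabilities encode the field's measured hierarchy: OH⁻
equal to H⁺ (no separate measurement is adopted), and Na⁺, K⁺, Cl⁻ six
orders of magnitude below H⁺, the flip-flop-driven gap between proton
and sodium leakage in fatty-acid membranes. The H⁺ permeability itself
is the main experimental axis, swept from 10⁻⁶ cm/s (modern
phospholipid, proton-tight) to 10⁻² cm/s (very leaky fatty-acid
vesicle).

### Water equilibrium

After every step the interior H⁺/OH⁻ pair is re-equilibrated to the
water ion product $K_w = 10^{-14}$ (mol/L)² (25 °C throughout;
temperature dependence is out of scope). Neutralization removes equal
amounts of H⁺ and OH⁻, so the *proton excess* $d = [\mathrm{H}^+] -
[\mathrm{OH}^-]$ is conserved by the projection and the pair is the
closed-form root of $(d + s)/2$ with $s = \sqrt{d^2 + 4K_w}$ — taken
in the cancellation-free arrangement (larger species from the
quadratic, smaller from $K_w$ divided by it), which keeps the ion
product exact to ≤10⁻¹² relative even for molar-scale totals.

### Membrane proteins

All proteins sit on the acid face only, where the proton gradient
points inward; their kinetic constants live in a single documented
table, `protein_constants()`, and every run manifest records the
resolved values.

* **ATP synthase** (`atpase`). Fully promiscuous for H⁺ and Na⁺.
  Total ion flux is capped at $N \cdot k_\mathrm{cat} \cdot \epsilon
  \cdot 3.3$ ions/s ($N$ = surface fraction × acid-face area /
  64 nm² footprint; $k_\mathrm{cat}$ = 500 ATP/s, mid-range of
  reported bacterial F₁F₀ turnover; $\epsilon$ = 0.1, see below;
  3.3 ions per ATP), throttled by a hyperbolic Michaelis–Menten
  saturation in the driving force, $|\Delta G| / (|\Delta G| + K)$
  with $K = 2$ kJ/mol so the factor passes 0.9 slightly beyond
  20 kJ/mol — the gradient scale equivalent to a ~200 mV potential.
  The flux partitions between the two ions in proportion to their
  favourable driving forces; an ion with an unfavourable gradient gets
  nothing, and the saturation uses the partition-weighted mean drive.
  Only the synthesis direction is modelled.
* **Ech** (`ech`), the energy-converting hydrogenase, shares the
  ATPase contract with double the per-unit ion rate and a slightly
  smaller footprint (50 nm²), so its per-area proton conductance is
  ~2.6× the ATPase's.
* **Sodium–proton antiporter** (`spap`). Strict electroneutral 1:1
  exchange: the H⁺ and Na⁺ flows are equal and opposite at every
  instant, so no net charge moves and the membrane potential drops
  out of its driving force thermodynamically (accordingly no
  potential-dependent speed factor is applied; the direction follows
  the sign of $\Delta G_\mathrm{H} - \Delta G_\mathrm{Na}$, chemical
  terms only, and the magnitude uses the same hyperbolic saturation).
  Turnover is 10⁵ exchanges/s — sodium–proton antiporters are among
  the fastest transporters known (E. coli NhaA approaches 10⁵ s⁻¹) —
  and this speed matters: drawing the 0.4 M external-level sodium pool
  (~10⁹ ions in a 1 µm cell) down to its equilibrium in minutes
  rather than days requires it.
* **Pump** (`pump`). A generic H₂-powered extruder of H⁺ or Na⁺:
  $J_\mathrm{out} = N k \epsilon \cdot \frac{[\mathrm{H_2}]}
  {[\mathrm{H_2}]+K_\mathrm{H2}} \cdot e^{-\max(\Delta G_\mathrm{opp},0)/K_p}$,
  with $K_\mathrm{H2} = 10^{-4}$ M (the default 10⁻³ M H₂ keeps it
  near-saturated — H₂ is an enabling substrate, not a studied
  variable) and $K_p = 10$ kJ/mol. The exponential back-pressure
  term makes pumping easier against an alkaline exterior and harder
  against an acidic one, and — unlike a hyperbolic tail — stalls the
  pump at a finite opposing gradient, so the pumped ion has a
  reachable steady state and the adaptive integrator is not forced to
  chase a concentration decaying to zero.

The efficiency scale $\epsilon = 0.1$ runs every protein at 10% of its
modern turnover, the package's standing assumption about primordial
enzymes; 0.5 and 1.0 are exercised by the turnover-comparison
scenario, which shows the qualitative behaviour is insensitive to it.

### The reported $-\Delta G$

The per-ion components $-\Delta G_\mathrm{H}$ and
$-\Delta G_\mathrm{Na}$ are always emitted. The single reported
$-\Delta G$ combines them with the same weights as the ATPase ion
preference (proportional to the favourable drives, all weight on one
ion when only it is favourable, the larger component when neither is).
This combination rule is a package design choice — some single number
has to stand for a two-ion driving force — and any analysis that cares
about one ion should read the per-ion columns.

### Integration and steady state

The balance is integrated by explicit forward Euler with an adaptive
step, matching the model's per-time-step construction: sum the fluxes,
advance the amounts, re-equilibrate water, recompute the potential.
The step is halved (and the step retried) whenever a concentration
would go negative or move by more than 1% — for the equilibrated
H⁺/OH⁻ pool the 1% cap is enforced on the conserved proton-excess
coordinate, since the pool's two species are one state variable — and
doubled again when changes fall below a quarter of the cap, up to the
passive-exchange stability limit $0.5 V / (P_\mathrm{max} A)$. Twenty
consecutive failed halvings abort with a state dump; no scenario in
the package approaches this. The compiled core (Rcpp) is mirrored by
a pure-R reference stepper, `step_state()`, and the test suite holds
the two to step-by-step agreement, so the fast path is continuously
validated against the readable one. An audit mode checks, per step,
that the change in every internal amount equals flux × dt to ≤10⁻⁹
relative (in practice ~10⁻¹³, i.e. rounding).

A run stops at `t_end` or as soon as the reported $-\Delta G$ has
drifted by less than `steady_tol` (10⁻⁴ kJ/mol/s) across every record
in a trailing `steady_window` (10 s). The plateau criterion is ours —
the trajectories show plateaus but no published rule. Cells without an
antiporter plateau within a second of simulated time; antiporter and
pump scenarios need hundreds to ~2000 s because the sodium pool is
large, which is why those presets carry longer horizons (`t_end` 1500
to 2400 s) and a wider window (60 s). Na⁺, K⁺ and Cl⁻ also drift on a
multi-hour timescale set by their tiny permeabilities; the reported
steady states are the minutes-scale quasi-steady plateaus the
experiment concerns, not the day-scale Donnan end state.

The initial interior is neutral water (pH 7) carrying the acid-side
ocean salt composition, so an antiporter cell starts with no sodium
gradient — which is what produces the characteristic transient: the
antiporter first collapses $-\Delta G$ by importing protons against
the nascent sodium gradient, then rebuilds it over minutes as the
sodium pool drains.

## What the scenario presets emulate — and what they do not

The preset registry (`list_scenarios()`) is the package's synthetic
experiment generator: every figure-level condition is a named,
fully-resolved configuration (sweeps over permeability, gradient
placement and size, protein surface fractions, pumped ion, efficiency,
stoichiometry, and seeded external-pH fluctuations). The fluctuation
process — a bounded Gaussian random walk, 1 s steps, σ = 0.25 pH,
±1.5 pH bounds, or a deterministic sinusoid — is our construction;
only its seconds timescale is anchored.

Behaviour the model reproduces, and the test suite asserts: free
energy is monotone in lipid H⁺ permeability, with proton-tight
membranes (≤10⁻⁵ cm/s) collapsing to under 10% of the open-system
reference; equal 3-unit gradients weaken as they acidify (7:10 > 6:9 >
5:8), because a more acidic acid face multiplies H⁺ influx while the
matching alkaline face supplies less OH⁻ for neutralization; protein
crowding (10–50% coverage) collapses even leaky cells; pumping across
a leaky membrane without an antiporter is futile, while with an
antiporter a 5% pump yields a monotone gain as the membrane tightens;
and without any gradient, pumped leaky cells stay below the
15 kJ/mol viability threshold.

Two quantitative headlines of the motivating analysis are *not*
reproduced, and the package reports them honestly rather than tuning
toward them. In this formulation, once hydroxide reaches its pooled
steady the per-proton driving force is capped at
$RT \ln([\mathrm{H}^+]_\mathrm{acid}[\mathrm{OH}^-]_\mathrm{pooled}/K_w)$
(≈15.4 kJ/mol for 7:10, against 17.1 for the open system), and a
passive 1:1 antiporter can only equilibrate the sodium ratio to the
proton ratio — it cannot push the combined driving force above that
passive ceiling, and the cation depletion it causes adds a small
positive-potential penalty. The steady values therefore land ~25%
below the ~20 kJ/mol headline, and adding the antiporter changes
$-\Delta G$ by about −11% rather than +60%. Free energy *above* the
passive ceiling appears in this package only where something injects
it: the H₂-powered pump.

Passing tests show internal consistency of this model, not fidelity to
real vent protocells: there are no activity coefficients or
ionic-strength corrections, no buffers or carbonate chemistry, no
capacitive charging (the potential is always the instantaneous
zero-current value), no spatial structure inside the cell or boundary
layers outside it, a fixed 25 °C, and protein kinetics reduced to
capped, saturating flux laws with literature-scale constants.

## Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| radius, embedding | 1 µm, 50/50 faces | half-embedded sphere |
| dt (initial/max) | 10⁻³ s, stability-capped | explicit Euler |
| step-change cap | 1% per step | positivity + accuracy |
| steady rule | <10⁻⁴ kJ/mol/s over 10 s | plateau detection |
| ATPase | 500 ATP/s, 64 nm², 3.3 ions/ATP | cited F₁F₀ range |
| Ech | 2× ATPase per-unit rate, 50 nm² | conduit analogy |
| SPAP | 10⁵ /s, 25 nm² | NhaA-class speed |
| pump | 10³ /s, K_H2 10⁻⁴ M, K_p 10 kJ/mol | stalling extruder |
| saturation K | 2 kJ/mol | ≥0.9 at 20 kJ/mol |
| efficiency | 0.1 | primordial enzymes |

Problem sizes used by the shipped tests and the acceptance script:
single trajectories of 10⁴–10⁷ Euler steps (seconds of CPU), sweeps of
5–30 cells, fluctuation runs of 40–600 s simulated time.

## A worked run

```{r example, eval = FALSE}
cfg <- protocell_config(atpase = 0.01, spap = 0.05, perm_H_cm_s = 1e-3,
                        t_end = 2400, steady_window = 60)
run <- run_protocell(cfg)
run
#> <protocell_run> steady at t = 338.5 s (17768069 steps)
#>   -dG reported = 13.63 kJ/mol (H: 13.63, Na: 13.63)
#>   dpsi = 17.2 mV, internal pH = 9.68

open_system_reference(cfg)$minus_dG_reported
#> [1] 17.11446
```

The antiporter has pulled internal Na⁺ three orders of magnitude below
the ocean (equilibrating its ratio to the proton ratio), the interior
is nearly as alkaline as the vent fluid, and both ions offer the same
~13.6 kJ/mol — the promiscuous ATPase can run on either.
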