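---
title: "A Cellular Potts model of wound healing with senescent-cell dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Cellular Potts model of wound healing with senescent-cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`woundcpm` simulates the proliferative and remodelling phases of dermal
wound repair on a two-dimensional lattice. It couples three layers:

1. **Cell dynamics** — a Cellular Potts model (CPM). Each cell is a set of
   lattice pixels carrying a shared integer identifier; medium is 0. The
   configuration evolves by stochastic pixel-copy attempts: a random target
   pixel and a random second-order (8-neighbour) source are drawn, and the
   copy is accepted with the Boltzmann factor `min(1, exp(-dH/Tm))`, where
   `dH` is the change in the effective energy

   `H = sum_cells [ lambda_v (v - V_t)^2 + lambda_s (s - S_t)^2 ]
      + sum_neighbour_pairs J(tau, tau') + H_chemotaxis`

   with volume `v`, surface `s` (4-neighbour boundary faces), their targets,
   the symmetric contact-energy matrix `J` over cell types (including
   medium), and a chemotaxis term `-lambda_chem (c(target) - c(source))`
   applied to the extending cell. One Monte Carlo step (MCS) is
   `width x height` copy attempts.

2. **Chemical fields** — four reaction-diffusion species (PDGF, CSF1, MMP,
   inflammatory SASP) obeying `dc/dt = D lap(c) - delta c + S`, advanced one
   MCS at a time by forward-Euler finite differences with a 5-point
   Laplacian and zero-flux boundaries. Species diffuse freely across cell
   bodies; there is no intracellular chemistry.

3. **The biological state machine** — threshold-gated rules evaluated every
   100 MCS (about 45 min of model time). Fibroblasts activate when PDGF at
   their centre of mass exceeds `PDGFf`, then secrete CSF1 (only while
   touching a macrophage), deposit extracellular matrix (ECM), and may
   differentiate into myofibroblasts (probability `PMF`, requiring ECM
   contact above `ECMthr` and residence in the wound). Macrophages polarise
   by the local inflammation level (M1 secretes MMP, M2 secretes PDGF), grow
   on CSF1, and die of growth-factor withdrawal below `CSF1thr`.
   Myofibroblasts secrete PDGF autocrinely, take up MMP locally (a TIMP
   abstraction), and resolve by tension-release apoptosis (ECM contact below
   `ECMthr`), inflammation apoptosis (INF above `INFthr`), or senescence.

## Units

One pixel is 3 um; a typical cell is 8x8 pixels (200 um^2); the reference
domain is 200x200 pixels = 600 um x 600 um. The temperature `Tm = 8.5` was
calibrated so a single unhindered cell moves at ~0.1 pixel/MCS; referencing
the peak fibroblast migration speed of 40 um/h, one MCS is
`0.3 um * 3600 / 40 = 27 s`, hence 3200 MCS per day. Field concentrations
are in arbitrary units; only ratios of secretion rates, decay constants and
thresholds are meaningful.

## The senescence programme

Primary (CCN1-mediated) senescence converts a myofibroblast with ECM
contact above `ECMthr`, with probability `PSNC`, once the onset time `TSEN`
has passed. `TSEN` is expressed in units of 1000 MCS (7.5 h); the baseline
value 12 corresponds to 3.75 days, placing induction in the mid stage of
healing. We read the time constraint as an *onset* (senescence permitted
for `t >= TSEN`): delaying `TSEN` to 15 days must delay the senescent-cell
rise to the late stage, which is only consistent with an onset semantics.

A senescent myofibroblast runs a two-phase secretory programme: a
*fibrogenic* SASP (PDGF secretion + ECM deposition) for `TNIS = 3` days,
then a *fibrolytic* SASP (CSF1 + inflammatory SASP + MMP). Secondary
senescence spreads by two routes evaluated before inflammation apoptosis:

- *juxtacrine*: contact with a fibrogenic-phase senescent cell and PDGF
  above `SNCthr`;
- *paracrine*: contact with a fibrolytic-phase (or pre-existing
  inflammatory) senescent cell and INF above `INFthr`.

The ordering matters: paracrine induction and inflammation apoptosis share
the INF threshold, so evaluating apoptosis first would make the paracrine
route unreachable. Senescent cells are cleared by macrophage contact
(phagocytosis) or, under inflammation, by other immune mechanisms; the two
routes carry the same hazard (`clear_phago = clear_inf = 0.1` per 1000-MCS
step), reflecting their "equal chance" in the conceptual model. Making
phagocytosis certain per evaluation instead removes every senescent cell
within hours of induction in a macrophage-rich wound and abolishes the
fibrolytic phase entirely, so a hazard semantics is used.

## Probability time base

`PSNC`, `PMF`, `mu` and the clearance probabilities are expressed per
1000-MCS step — the same unit as `TSEN` — and converted to per-evaluation
hazards at the 100-MCS cadence via `p_eval = 1 - (1-p)^(1/10)`. Interpreting
`PSNC = 0.15` per 45-minute evaluation instead would senesce essentially
every myofibroblast within a day of onset, incompatible with a senescent
population that rises at day ~4 and peaks near day ~7; the per-1000-MCS
base yields day-scale kinetics and is consistent with the unit in which the
onset parameter is quoted.

## ECM representation

ECM is made of small CPM cells: the initial dermis is tiled with 4x4 ECM
cells (finer than the 8x8 cellular grain so MMP degradation acts at
sub-cell resolution), and deposition creates 2x2 seeds with a stiff volume
constraint on medium pixels adjacent to the producing cell. When a
producing cell has no free medium face, its deposition budget instead
thickens an adjacent ECM cell inside the wound (raising its target volume
up to twice the base), which lets granulation tissue mature after the
provisional matrix has covered the wound front. ECM cells are removed when
MMP at their centre of mass exceeds `MMPthr` (strict inequality);
myofibroblasts reduce MMP at their own centre of mass by `MMPthr` each
evaluation (TIMP abstraction).

## Numerical choices

- **Stability.** The explicit field stepper requires `D dt <= 0.25` *and*
  the von Neumann bound `8 D dt + delta dt <= 2`; the second is not implied
  by the first — at `D dt = 0.25` a nonzero decay pushes the checkerboard
  mode's amplification factor below -1 and the clipped scheme slowly gains
  mass. Defaults (`D = 0.2`, `dt = 1`) satisfy both with margin.
- **Growth pressure.** Monod growth raises a cell's target volume, but only
  to a small margin (4 pixels) above its realised volume. Without the cap,
  a crowded cell accumulates an unbounded volume deficit and crushes its
  neighbours — deposited ECM in particular — which is neither biological
  nor numerically stable.
- **Bookkeeping.** The Metropolis kernel maintains volume, surface,
  medium-surface and centre-of-mass sums incrementally; after every rule
  evaluation (removals, divisions, depositions) the bookkeeping is rebuilt
  from the lattice, so drift cannot accumulate across intervals. The
  incremental energy is cross-checked against a brute-force Hamiltonian in
  the test suite on exhaustively enumerated small lattices.
- **Determinism.** All randomness derives from R's RNG: the compiled kernel
  is seeded from it per call (internally an xorshift64* generator), and all
  rule draws are fixed-length vectors in a fixed order, so a run is a pure
  function of `(configuration, seed)`. Replicate k of a scenario uses
  `seed + k - 1`.
- **Ties and boundaries.** Contact inhibition freezes growth at
  `Rs <= TCI`; ECM survives MMP exactly at `MMPthr`; activation,
  polarisation and all other gates use strict inequalities. Cell division
  retries a random axis up to 10 times before skipping. The lattice
  boundary is fixed (no wrap); out-of-bounds sources are never proposed and
  domain-edge faces are not counted as surface.

## Scenario presets and classification

Five presets reproduce the study conditions: `healthy`
(`PSNC = 0.15`, `TSEN = 12`), `chronic_high_psnc` (`PSNC = 0.75`),
`fibrotic_no_snc` (`PSNC = 0`), `fibrotic_delayed` (`TSEN` = 15 days), and
`chronic_preexisting` (inflammatory senescent cells seeded in the wound at
t = 0, one per ~250 wound pixels, all other parameters unchanged). Outcomes
are classified against a healthy reference trajectory over the final six
days: *fibrotic* if mean ECM is at least 1.3x the reference (excessive
matrix deposition), *chronic* if it is at most 0.8x (insufficient matrix),
otherwise *healthy*. The inflammatory SASP ratio is reported as evidence —
chronic wounds accumulate inflammatory and fibrolytic factors — but at
reduced lattice sizes late-stage inflammation is episodic (driven by a
handful of fibrolytic cells), so it is not used as a gate. For robustness
the reference should be the pointwise median of several healthy replicates
(`median_reference()`): at 100x100, roughly one healthy replicate in three
degrades its matrix late in remodelling, and a median reference keeps one
such replicate from distorting every comparison. These thresholds are the
package's operationalisation of end states that were classified by
inspection in the source study; they were validated against the five
presets.

## The synthetic initial state

`build_initial_state()` constructs a dermis of 8x8 fibroblasts and 4x4 ECM
tiles (50:50 by block) around a central square wound covering 40% of the
domain, initially occupied by 8x8 M2 macrophages on 15% of wound blocks;
all fields start at zero. Because CSF1 only appears after activated
fibroblasts reach the macrophages, the CSF1-withdrawal apoptosis rule is
given a 4-day grace period; otherwise every macrophage would die at the
first evaluation of an initial state that is, by construction, free of
growth factors. This generator emulates the geometry and composition of a
wounded dermal patch at the end of the inflammatory phase; it does not
emulate re-epithelialisation, 3D tissue architecture, explicit growth
factor kinetics of real wounds, or inter-individual variability — passing
the scenario checks therefore demonstrates internal consistency of the
model mechanisms, not predictive accuracy for clinical wounds.

## Problem sizes

The reference geometry is 200x200 pixels. The package's regression and
acceptance checks run the same model on reduced lattices with the full
18-day time axis: 100x100 for the baseline-trajectory, scenario and sweep
checks (the smallest size at which the healthy trajectory is
replicate-stable; at 80x80 and below, single-seed extinction events
dominate), 64x64 for mechanical properties where trajectory shape is
irrelevant, and 40x40 over 1.5 days for calibration parameter-recovery, with
particle swarm optimisation at 2 swarms x 10 particles x 30 iterations.
Each candidate evaluation in the swarm uses one fixed evaluation seed
(common random numbers) so particles compare positions rather than noise
realisations; the recovery target is the replicate-noise fitness floor
measured at the true parameters.

## Known limitations

- The early granulation overshoot of matrix density — a transient ECM peak
  followed by a ~0.7-fold relaxation around day 3 — is not reproduced at
  the reduced scale: deposition and macrophage-derived degradation
  equilibrate smoothly instead of overshooting. Stronger macrophage MMP
  secretion produces the overshoot only at the price of destroying the
  dermis during remodelling.
- Paracrine secondary senescence is rare under baseline conditions
  (single-digit counts at 100x100); it becomes the dominant route in the
  chronic scenarios, as expected, but its healthy-baseline kinetics are at
  the edge of resolution at reduced scale.
- Myofibroblast de-differentiation is mentioned as a possible fate in the
  source biology but has no stated rule; it is available behind the
  `dedifferentiation` flag (off by default) and untested.
- `mu` removal applies to activated fibroblasts and macrophages only, not
  to myofibroblasts, whose losses are governed by their explicit fates.

## A short run

```{r}
library(woundcpm)
cfg <- scenario_config("healthy", lattice = c(100L, 100L), days = 18)
res <- run_simulation(cfg, seed = 1)
tail(res$timeseries[, c("time_days", "fibroblasts", "myofibroblasts",
                        "macrophages", "senescent", "ecm_volume",
                        "wound_closure")])
write_outputs(res, "healthy_run", snapshot = TRUE)
```
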