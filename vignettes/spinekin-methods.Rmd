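---
title: "The spinekin model: stochastic CaMKII activation in a spine head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spinekin model: stochastic CaMKII activation in a spine head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinekin)
```

## What the model computes

`spinekin` simulates the first ~20 s of CaMKII activation in a median-sized
dendritic spine head (0.016 fL) driven by a two-epoch presynaptic burst
stimulus. The chemistry couples four processes:

1. **Ca²⁺ entry and clearance.** Glutamate release events that coincide with
   a back-propagating action potential open NMDAR channels; each opening
   injects a pulse of Ca²⁺ ions into the spine pool. Ca²⁺ is removed by an
   effective saturable pump (below).
2. **Calmodulin.** CaM carries two Ca²⁺ sites on each lobe, giving nine
   occupancy species from apo-CaM (CaM0) to fully loaded CaM4. Site kinetics
   depend on the binding context: free CaM, CaM bound to an unphosphorylated
   CaMKII subunit (the low-affinity "la" site), or CaM trapped on a
   phosphorylated subunit (the high-affinity "ha" site).
3. **The CaMKII holoenzyme.** Sixty dodecamers (720 subunits, two
   six-membered rings each) bind CaM species at their cam sites.
   Autophosphorylation of Thr286 is directional within a ring: the
   clockwise ("right-hand") neighbor acts as kinase, and fires at
   0.96 s⁻¹ when the substrate holds CaM4 (0.1 s⁻¹ for any other bound CaM
   species), provided the kinase is itself active (CaM-bound or already
   phosphorylated). After phosphorylation the CaM site converts from la to
   ha ("CaM-trapping") at a rate equal to the la off-rate of the bound
   species; the trapped CaM4 off-rate is 9×10⁻⁵ s⁻¹ instead of 6.6 s⁻¹.
4. **PP1.** Protein phosphatase 1 (12 molecules at the 1.25 µM baseline)
   dephosphorylates pThr286 by explicit binding and catalysis whose ensemble
   behavior is Michaelis–Menten with kcat = 11.5 s⁻¹ and KM = 11 µM. An
   optional *competition* rule (the steric CaM-block hypothesis) forbids PP1
   binding while the CaM site is occupied.

The engine is a Gillespie direct method over class-aggregated channels
(`engine = "exact"`), or a hybrid mode that tau-leaps the fast free-CaM pool
channels while keeping all molecule-level events and the Ca²⁺ birth/death
pair exact. Both are bit-reproducible per seed; the hybrid mode is the
production default for ensembles and agrees with the exact engine within
Monte-Carlo error on a reduced system (tested).

## Rate-table construction and detailed balance

Only a handful of constants for this system are measured directly:
the free-CaM lobe kinetics (C-lobe sites: kon 6.8×10⁶ M⁻¹s⁻¹ with koff 68
and 10 s⁻¹; N-lobe sites: kon 1.08×10⁸ with koff 4150 and 800 s⁻¹), apo-CaM
binding to CaMKII (kon 3.8×10³ M⁻¹s⁻¹, KD ≈ 1.45 mM), the initial CaM4
interaction (KD = 65 nM, koff = 6.6 s⁻¹) and the trapped CaM4 off-rate
(9×10⁻⁵ s⁻¹). Every other rate is *derived* so that each closed
thermodynamic cycle (load Ca²⁺ then bind CaMKII, versus bind CaMKII then
load Ca²⁺) has zero net free-energy change:

- a uniform per-site factor $g = (K_D^{CaM0,la}/K_D^{CaM4,la})^{1/4} \approx
  12.2$ by which CaMKII binding increases each site's Ca²⁺ affinity in the
  la context;
- a factor $h$ (`ha_ca_lock_factor`, default 1000) for the trapped context:
  the trapped conformation effectively locks the Ca²⁺ sites. Detailed
  balance then *forces* partially loaded species to leave the trapped site
  faster the more Ca²⁺ they are missing, and releases apo-CaM essentially
  instantly — trapping requires Ca²⁺. A key property of this construction is
  that once $h$ is large the escape rate of a trapped subunit at resting
  Ca²⁺ saturates at a ceiling fixed by the cycle thermodynamics alone
  (≈ 1/60 s⁻¹ at 100 nM), so the exact value of $h$ is immaterial;
- geometric interpolation of the CaM–CaMKII association rate between the
  CaM0 and CaM4 anchors with the number of bound ions, with off-rates set by
  koff = kon·KD.

`validate_thermodynamics()` checks all 24 cycles of the shipped table
(residuals < 10⁻⁹) and flags any perturbed edge. `cam_rate_table()` returns
the full derived table; `derive_ha_offrates()` the trapped off-rates, which
are independently reproduced in the test suite by a brute-force
cycle-product solver.

```{r}
head(cam_rate_table(spinekin_params())$binding, 4)
```

## The synthetic stimulus

The presynaptic drive is 2 epochs × 5 bursts (5 Hz) × 5 APs (50 Hz) — 50 APs
total, epoch 1 starting at 1 s and epoch 2 at 5 s (the figure timing of the
study; its Methods also mention a 2 s separation, an ambiguity we resolve in
favor of the figures). Vesicle release uses 7 docked sites with a compound
initial release probability of 0.2, a two-parameter facilitation stand-in,
and depression through docked-site depletion with 0.2 s⁻¹ redocking. A
release opens the 15 NMDARs with probability `p_open` each only when a bAP
(10 ms after each AP) falls within a 20 ms coincidence window — the temporal
abstraction of Mg²⁺-block relief. Voltage, glutamate diffusion and NMDAR
state kinetics are deliberately not modeled; their net effect is carried by
`p_open` and `n_ca_per_opening`.

## Effective Ca²⁺ handling, and what was calibrated

The full Ca²⁺ machinery of the source models (pumps, exchangers, calbindin,
immobile buffers, diffusion to the dendrite) is replaced by one effective
mechanism with two regimes:

- **clearance** is a Michaelis pump far into saturation
  (`ca_clear_KM` = 0.02 µM): stimulus loads drain at a near-constant
  capacity, reproducing the seconds-long inter-epoch persistence of
  Ca²⁺/CaM activity that explicit buffers would provide, while the
  birth–death balance pins resting Ca²⁺ tightly at 100 nM (the stationary
  *mean* is solved numerically, since a saturating removal rate would
  otherwise bias it upward);
- **CaM exchange** with the dendritic reservoir (an infinite bath at 30 µM
  total CaM, baseline-equilibrated) relaxes the free spine pool at
  `k_cam_exchange` = 8 s⁻¹, an estimate of diffusional exchange through the
  spine neck.

Four constants cannot be taken from measurements because they absorb the
omitted machinery: `p_open` (0.6), `n_ca_per_opening` (90 ions),
`pulse_tau` (5 ms) and `tau_ca_clear` (4 ms, which sets the pump capacity
through `ca_clear_KM`). They were calibrated **once**, jointly, against two
printed reference values of the study system — the no-competition model at
1.25 µM PP1 reaching a peak of ~200 phosphorylated subunits, and ~90
phosphorylated subunits remaining at 5 s — and are flagged
`calibrated, not measured` in `param_provenance()`. The two anchors cannot
be matched simultaneously to high precision in this reduced model: with a
peak near 200, near-pure Michaelis–Menten decay forces the 5 s value toward
~70 rather than 90 (even the printed pair implies ongoing inter-epoch
rephosphorylation that a well-mixed model only partly reproduces). The
calibration minimizes the joint relative error.

## Known limitations

- **No spatial transport.** Compartments are well-mixed; the PSD capsule
  (0.002915 fL) only partitions counts of confined species (CaMKII always,
  PP1 in the `camkii_and_pp1` variant) while Ca²⁺ and CaM are shared
  spine-wide pools. The small enhancement of autophosphorylation from
  Ca²⁺/NMDAR proximity in the PSD is deliberately not captured.
- **High-phosphatase decay is slightly fast.** At 2.5 µM PP1 the epoch-1
  decay constant comes out near 0.5 s versus the published 0.74 s: at high
  phosphatase the decay is essentially pure Michaelis–Menten, and the
  ~1.5-fold slow-down that diffusion-limited enzyme encounter contributes in
  a particle-based spatial model has no counterpart in a well-mixed engine
  with KM fixed at the measured 11 µM. The sweep ordering and the other
  concentrations are reproduced.
- **The 55-constant Ca²⁺/CaM table is reconstructed**, not transcribed: the
  detailed-balance construction above reproduces the measured anchors and
  the qualitative structure of the source model's table, but individual
  intermediate-species rates may differ from the deposited model.
- The facilitation stand-in (two parameters) is not the 37-parameter
  presynaptic model; only its mean release counts and depression trend are
  comparable.
- Thr306 is carried in the state but never phosphorylated;
  inter-holoenzyme autophosphorylation, β-subunits and CaM buffers such as
  neurogranin are out of scope.

## Design choices on open points

- *Post-dephosphorylation fate of a trapped site*: reverts to la (the
  alternative, persistence, is not supported by the structural picture in
  which the extended conformation depends on pThr286); any still-bound CaM
  immediately adopts la off-rates.
- *Empty cam site on a phosphorylated subunit*: sits in ha when trapping is
  on, so rebinding is trapped — the high-affinity state is a property of the
  phosphorylated subunit, not of the binding event.
- *A phosphorylated kinase-side neighbor is fully active* regardless of its
  own CaM load; the substrate's CaM species alone selects the fast or slow
  rate.
- *PP1 kon/koff split*: KM fixes only (koff+kcat)/kon; the default sets
  koff = kcat. Because the quasi-steady Michaelis–Menten velocity is
  invariant to this split, decay constants are insensitive to it (the
  `pp1_koff_policy` options `zero` and `factor` expose the alternatives).
- *Fit windows*: epoch-1 decays are fit on 4–5 s, epoch-2 on 7.7–8.7 s, and
  the slow trapping-plus-competition condition on 8.7–21 s of extended runs;
  windows follow the time anchors marked in the study's figures and are
  configurable in `make_table1()`. Decay constants are fit on the
  ensemble-mean trace; for short windows the floor term is disabled
  (amplitude and decay constant only) because a three-parameter fit is
  degenerate when the window is much shorter than the decay time.

## Problem sizes

Production ensembles here use 10–40 seeds per condition (the original study
used 50), 11 s of simulated time for standard runs and 21 s for the slow
trapping-plus-competition decays, recorded every 10 ms. A single 21 s
hybrid trajectory of the full system runs in roughly a second on one CPU.

## A worked condition

```{r, eval = FALSE}
p <- spinekin_params(trapping = TRUE, competition = TRUE)
ens <- run_ensemble(p, seeds = 1:12, t_end = 21)
tr <- ensemble_trace(ens, "pT286")
fit_exponential_tau(tr$time, tr$mean, c(8.7, 21), floor = FALSE)
```

The trace rises over both epochs to roughly twice the no-competition peak
(bound CaM shields pThr286 from PP1 while trapped), then decays with a time
constant of tens of seconds set by the thermodynamics of trapped-CaM escape
at resting Ca²⁺ — the central quantitative prediction this package
reproduces.
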