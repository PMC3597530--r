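---
title: "Modeling Gq-coupled signaling in spiny dendrites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Gq-coupled signaling in spiny dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Striatal medium spiny projection neurons express two opposing forms of
long-term plasticity that both require intracellular calcium and
diacylglycerol (DAG): long-term depression, mediated by the retrograde
endocannabinoid 2-arachidonoylglycerol (2AG), and long-term potentiation,
which requires conventional protein kinase C (PKC). GqSpine implements a
mesoscopic stochastic reaction–diffusion model of the postsynaptic
signaling network that lets both pathways compete for the same calcium and
DAG, and asks whether the *temporal pattern* of synaptic input — theta-burst
versus 20 Hz stimulation at identical total input — selects between them,
and how spatially specific each signal is along a spiny dendrite.

## The signaling network

The network couples:

* **Calcium handling** — influx (injection events standing in for NMDA
  receptor and voltage-gated channel flux), the buffers calbindin and
  calmodulin (two-site lobes binding calcium pairs), a high-affinity PMCA
  pump, a low-affinity NCX exchanger, and a membrane leak returning
  extracellular calcium.
* **The Gq cycle** — glutamate (or the group-I mGluR agonist DHPG) binds
  mGluR; the bound receptor catalytically converts Gαβγ into GαqGTP, which
  is hydrolyzed intrinsically and, much faster, by PLCβ acting as a GAP.
* **PLCβ coincidence detection** — PLC must bind calcium to hydrolyze PIP2
  into DAG + IP3; GαqGTP binding raises the catalytic rate tenfold, so DAG
  production reports the *product* of calcium and receptor drive.
* **The 2AG branch** — calcium-bound DAG lipase converts DAG to 2AG
  (Michaelis–Menten through an explicit DAG·Ca·DAGL complex), with
  first-order 2AG degradation.
* **The PKC branch** — PKC binds calcium first, then membrane DAG, giving
  active PKC; the calcium step is low-affinity and fast to reverse, which
  makes active PKC formation sensitive to coincident calcium and DAG.
* **Housekeeping** — DAG kinase clearing DAG to phosphatidic acid, IP3
  degradation and PIP2 regeneration by PI kinase, agonist uptake.

All reactions are elementary mass-action channels expanded from a
row grammar (`reactionTable()`, `expandReactionRow()`); second-order rate
constants are in nM⁻¹s⁻¹ and converted per subvolume to per-molecule-pair
rates. Rows written `A + 2*Ca` fire as a single second-order channel
(propensity ∝ N_A·N_Ca) consuming two calcium ions per firing: this keeps
the printed nM⁻¹s⁻¹ units meaningful and reproduces the initial
calmodulin occupancies, whereas a termolecular reading would not. The
network carries 15 conserved moieties (total calmodulin 8.06 µM, total
PKC 15 µM, total calcium counting every bound form with multiplicity,
enzyme pools, and so on), each validated against every channel's
stoichiometry at construction time and asserted exactly along stochastic
trajectories.

Two printed-table idiosyncrasies are resolved as follows: the DAG-kinase
row lists only phosphatidic acid as its catalytic product, and is
implemented with the kinase recycled (`DagK.DAG => DagK + PA`), as in
every other enzyme row; the DAG-release rows carry a single rate in the
forward column and are implemented as irreversible first-order release.
The four calmodulin rows' C/N-site labels are treated as comments; the
printed per-row rates are used as printed.

## Membrane pools (the open parameters)

The published tables give cytosolic initial concentrations but not the
surface densities of the membrane-bound species. These are therefore
**model configuration**, expressed as whole-cell-equivalent concentrations
and converted to picomol/m² surface densities over each species'
localization regions (`surfaceDensity()` reports the implied density).
The shipped defaults were chosen once, to satisfy the stated constraints
and produce the documented qualitative dose–response behavior, and are
not revisited per experiment:

| pool | value (µM) | rationale |
|------|-----------|-----------|
| DAG lipase | 1.7 | stated total pool (the saturation diagnostic approaches it) |
| PLCβ | 1.0 | sets tonic DAG production at rest to the hundreds-of-nM range |
| PIP2 | 20 | substrate reservoir; large enough that theta-burst drive is not substrate-limited |
| mGluR | 4.0 | with Gαβγ, sets the GαqGTP response to 25 µM DHPG |
| Gαβγ | 8.0 | as above; GAP activity of PLC makes GαqGTP short-lived, so a sizable pool is needed for tens-of-nM GαqGTP |
| PI kinase, DAG kinase | 1.0 each | DAG/IP3 turnover on the seconds scale |
| PMCA | 12, NCX 7 | clearance of a train's calcium load within a few seconds; NCX restricted to dendrite submembrane + spine neck |
| Leak | analytic | `calibrateLeak()` balances pump efflux at 51 nM free calcium |

The exogenous fast buffer used in the 20 Hz control condition (10 µM)
uses literature-typical fast-buffer kinetics (kon 0.4 nM⁻¹s⁻¹, Kd
200 nM).

## Morphology and mesh

The single-spine morphology is a 2 µm dendrite (1 µm wide, 0.6 µm deep)
discretized laterally into a 14 × 7 grid of columns (lateral size
2/14 ≈ 0.143 µm so the grid tiles exactly) with a single layer spanning
the full depth — diffusion in the dendrite is two-dimensional. The
printed subvolume depth of 0.4 µm conflicts with the 0.6 µm dendrite
depth; the mesh uses one full-depth layer (depth is a config parameter)
since lateral 2-D diffusion is the stated intent. The outer ring of
columns is the submembrane region hosting membrane-bound molecules. The
spine is a stack of 0.1 µm cylindrical slices (1-D diffusion): a 0.2 µm
diameter, 0.3 µm neck, a 0.6 µm diameter head, and the distal head slice
labeled PSD, where synaptic input arrives. The multi-spine morphology is
a 20 µm dendrite with 13 spines placed randomly (no shared attachment
columns, reproducible under a placement seed); spine counts in the source
figures vary between 12 and 13, so the count is a config value defaulting
to 13 to match the spatial-specificity analyses.

Initial placement distributes cytosolic species in proportion to volume
and membrane species in proportion to membrane area over their
localization regions, using stochastic rounding so expectations are
exact. Spine-head membrane slices do carry membrane species (the 2AG
machinery operates in spines); this is exposed through the localization
sets.

## Stochastic engine

The engine advances a (species × subvolume) integer count table with a
fixed-step spatial tau-leap: per step and subvolume each channel fires
Poisson(a·dt) times, with firings clipped so no reactant goes negative
(clips are counted and reported on the `Trajectory`); diffusible species
then jump to adjacent subvolumes with per-molecule probability
1 − exp(−D·G_i·dt), split multinomially over neighbors, where
G_i = Σ A/(V_i d) is the subvolume's jump geometry. Fast diffusers in
small subvolumes automatically receive substeps so the per-substep leave
probability stays below ~0.25. Detailed balance holds across unequal
volumes (rate_ij V_i = rate_ji V_j), diffusion conserves counts exactly,
and a two-box system equilibrates to a 50/50 split.

The reference step is 2.5 µs. Randomness comes from an explicitly
seeded xoshiro256++ stream per run — trajectories are bitwise
reproducible for a given seed and independent of R's global RNG.
Large-mean Poisson (λ > 30) and large-N binomial draws use clamped
normal approximations, which leave leap means exact where they engage;
small-count draws are exact inversion/Bernoulli sampling. A well-mixed
deterministic oracle (`solveReferenceOde()`, stiff LSODA on the same
channel list) validates ensemble means on fixture networks: exponential
decay, reversible binding at the calbindin rates (Kd 700 nM),
an explicit-complex enzyme, two-box diffusion, and exact conservation of
every moiety on the full network (`validateEngine()`).

## Stimulation protocols

Every synaptic pulse is a 3 ms calcium injection into the stimulated PSD
plus a calcium injection into the dendritic submembrane (voltage-gated
channels) and release of mGluR ligand into the PSD. Theta-burst: 4
pulses at 50 Hz per burst, bursts every 95 ms, 10 per train, trains every
15 s (onset to onset), 10 trains. 20 Hz: trains of 20 pulses at 20 Hz
with a 9 s gap, 20 trains. Both deliver 400 pulses and identical calcium
and glutamate totals (guarded by an assertion in the plasticity suite).
The depolarization (DSI) protocol applies DHPG as a sustained whole-bath
clamp of the agonist species at t = 0 and injects calcium into spine and
dendrite from t = 2 s — constant-rate for 0.1 s, exponentially decaying
(τ = 2 s) for 1 s and 5 s depolarizations to mimic channel inactivation.
The spine/dendrite split of depolarization calcium is membrane-area
proportional (28% spine).

Per-pulse and depolarization amplitudes are not printed anywhere; they
were fixed once by calibration against configured transient targets
(`calibrateInjection()` implements the monotone secant search): 1000
calcium ions per pulse into the PSD and 4000 into the dendrite, giving a
single-pulse spine transient in the 100–300 nM range and train-scale
spine transients in the micromolar range; the DSI injection starts at
1.2 × 10⁵ ions/s, which produces a ~1 µM spine plateau for the 5 s
depolarization. 1000 glutamate molecules accompany each pulse.

## Readouts

Concentrations are counts divided by Avogadro's number and the
appropriate (group) volume. Regional series are volume-weighted across
the subvolumes of a region (or a spine's head + PSD); ensembles over
seeds report pointwise mean, SD and SEM. Peak statistics are computed on
the trial-mean series after 1 s boxcar smoothing to suppress
single-sample Poisson spikes. The DHPG *enhancement ratio* is the
window-mean 2AG with agonist divided by the window-mean without; the
*plasticity index* is mean active PKC divided by mean 2AG over the
stimulation-plus-response window, with index > 2 read as LTP-like and
index ≈ 1 as LTD-like. The averaging window runs from the first stimulus
to a configurable tail after the last pulse (60 s at full scale; 10–20 s
in desk-scale runs) — the sources do not state a window, and this one
covers the slow PKC transient. Both time-mean and smoothed-peak
statistics are reported wherever a "mean" could be read either way.

## Study conditions at desk scale

The reference conditions (2.5 µs step, 0.143 µm lateral mesh, 400-pulse
protocols, 3 seeds) are available throughout via `scaled = FALSE`, but
the shipped suites default to a desk-scale mode chosen once and used
consistently: a coarser mesh (0.4 µm lateral columns, 0.15 µm spine
slices; 25 × 2 columns for the 20 µm dendrite), a 50 µs step (80 µs for
the spatial and robustness suites), and truncated protocols with matched
totals — one theta train (40 pulses) versus two 20 Hz trains (40 pulses),
or two versus four. At these settings the discrimination and specificity
statistics are stable across seeds while each suite completes in minutes.
The desk-scale step keeps all per-event probabilities well below one
(fast unbinding at 1000 s⁻¹ gives per-step probability 0.05–0.08) and the
diffusion substepping bounds jump probabilities; fixture accuracy checks
run at finer steps where closed forms are asserted.

## What the suites show (and what they do not)

* `runDsiSuite()` reproduces the dose–response validation: 2AG rises
  with depolarization duration; DHPG enhances 2AG monotonically for
  0.1 s and 1 s depolarizations but hardly at all for 5 s, because
  calcium alone then drives DAG-bound DAG lipase to ≈ 90% of its 1.7 µM
  pool — enzyme saturation, the model's explanation for the ceiling.
  As in the source model, the 0.1 s condition is enhanced *more* than
  1 s, a known qualitative deviation from slice experiments attributed
  to presynaptic CB1 response properties that are outside this model.
* `runPlasticitySuite()` shows temporal-pattern discrimination: at
  identical input totals, theta burst drives peak active PKC more than
  four times (and mean more than two times) above 20 Hz, while 2AG is
  similar for both; adding 10 µM fast buffer leaves 20 Hz 2AG unchanged.
  The mechanism is the chain of local supralinearities — buffer
  saturation in the small spine during 50 Hz bursts, PLCβ's
  calcium×GαqGTP product sensitivity, and PKC's calcium-then-DAG
  requirement — against the saturating, and therefore
  pattern-insensitive, DAG-lipase route to 2AG.
* `runSpatialSuite()` shows spine-level spatial specificity of the
  index: with spine 1 stimulated, theta burst raises the PKC:2AG index
  above 2 only there, while 2AG spreads to neighbors (it is fast-
  diffusing); under 20 Hz no spine exceeds 2.
* `runRobustnessSuite()` re-runs the comparison under the documented
  parameter variations (2AG decay, mGluR desensitization ±, DAG-lipase
  affinities for calcium and DAG ±, GαqGTP hydrolysis, PSD relocation,
  spine-matched PLC/PIP2/mGluR/DAGL densities) and checks only the rank
  order index(theta) > index(20 Hz). "Affinity 50%" variations scale the
  forward binding rate; the spine-matching variations rescale spine
  placement weights so local spine concentrations match the dendritic
  submembrane (adding molecules in the "Dgl" variant, redistributing in
  the "PLC" variant).

The synthetic stimulus generator emulates event *timing* and molecule
*totals*, not channel gating or membrane potential; no synaptic weight
change, presynaptic CB1 dynamics, or electrophysiology is modeled, so
passing suites support the signaling-level claims only. Several
quantitative features (absolute 2AG/PKC concentrations, enhancement
magnitudes) depend on the configured membrane pools and injection
amplitudes documented above; the suites therefore assert patterns —
monotonicity, saturation, ratios, rank order — rather than absolute
levels, except where a pool total (1.7 µM DAG lipase) pins the scale.

## Numerical choices and limitations

* Negativity policy: firings are clipped to available reactants per
  channel per step; clip counts are reported (`@corrections`). At the
  default steps clips are a small fraction of events and concentrated in
  high-flux calcium channels during injections.
* The multinomial neighbor split ignores multi-hop moves within a step;
  substepping bounds the associated error.
* Clamp events overwrite counts after reactions each step: a clamped
  species is a boundary condition, and its moieties are exempt from
  conservation while clamped.
* Placement stochastic rounding makes tiny-pool species (free calcium is
  only ~40 ions in the whole single-spine mesh) integer-noisy at t = 0;
  resting-state checks therefore average over 10 s.
* Mesoscopic subvolumes assume well-mixedness below the mesh scale;
  nanodomain coupling of channels to enzymes is outside the model.
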