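---
title: "Methods: population-of-models simulation of atrial fibrillation inducibility"
author: "afpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-of-models simulation of AF inducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`afpop` implements a four-stage in-silico pharmacology pipeline for atrial
fibrillation (AF):

1. **Population of models.** Nine electrophysiological quantities of a
   chronic-AF remodeled human atrial myocyte model — the fast Na⁺
   conductance (g~Na~), the Na⁺/K⁺ pump (I~NaK~), the inward rectifier
   (g~K1~), the L-type Ca²⁺ conductance (g~CaL~), the ultrarapid K⁺
   conductance (g~Kur~), the Ca²⁺-activated K⁺ current (I~KCa~), the
   extracellular Na⁺ and K⁺ concentrations, and the tissue diffusion
   coefficient D — are varied by −50 % to +100 % (multipliers in
   [0.5, 2]) with Latin-hypercube sampling. Each candidate is paced for 15
   beats at 1 Hz on an 8 × 256-node strip and accepted into the population
   iff all six action-potential biomarkers (APD~20~, APD~50~, APD~90~, APA,
   RMP, V~20~) at the three probe cells 500/620/748 fall within a
   per-biomarker constraint box.
2. **Tissue simulation.** Each accepted profile is simulated on 2D
   monodomain sheets of a normal (16 cm²) and a dilated (20.25 cm²) atrium
   under four conditions (basal, flecainide, verapamil, isoproterenol)
   with an S1–S2 cross-field induction protocol.
3. **Reentry analysis.** Hilbert-transform phase maps, topological-charge
   phase-singularity (SP) detection, nearest-neighbour rotor tracking with
   a ≥ 1-full-rotation survival filter, and the outcome rule: *induced* iff
   a surviving rotor track exists after S2; *maintained* iff additionally
   the tissue is electrically active in the final 200 ms of the
   observation window.
4. **Classification.** A random forest (500 trees, stratified 80/20 split,
   5-fold cross-validation on the training portion) predicts inducibility
   from the nine *effective* multipliers (profile × drug factors) plus the
   tissue area, and a single depth-≤ 7 CART tree provides interpretable
   decision paths exported as a sunburst structure.

# The cell models

## Detailed atrial myocyte model

The detailed model is a Courtemanche-family human atrial formulation:
21 states (V~m~, 15 Hodgkin–Huxley gates, five ionic/SR concentrations)
with I~Na~, I~K1~, I~to~, I~Kur~, I~Kr~, I~Ks~, I~CaL~, I~NaK~, I~NaCa~,
background and sarcolemmal pump currents, and SR uptake/release. Two
extensions serve this pipeline:

* an **SK current** (I~KCa~), modelled as
  g~KCa~ · [Ca]ᵢ²/([Ca]ᵢ² + K~D~²) · (V − E~K~) with K~D~ = 350 nM and a
  baseline g~KCa~ = 0.005 nS/pF. The baseline was chosen so that the SK
  contribution is present but moderate: with g~KCa~ → 0 the control model
  reproduces the canonical ≈ 290 ms APD~90~ at 1 Hz, and at 0.005 nS/pF
  APD~90~ is ≈ 240 ms; the population varies the current two-fold in both
  directions.
* a **√([K]ₒ/5.4) scaling of g~K1~**, so the varied extracellular K⁺
  multiplier acts on conductance as well as on the Nernst potential.

Chronic-AF remodeling multiplies g~CaL~ × 0.45, g~to~ × 0.38,
g~Kur~ × 0.62, g~K1~ × 1.62, the Na⁺/Ca²⁺ exchanger × 1.50, SERCA
uptake × 0.84, the PLB/SERCA ratio × 1.18 and the SLN/SERCA ratio × 0.60.
The two regulator ratios act phenomenologically on the SERCA uptake K~m~
(both raise K~m~ when increased). Remodeling is applied *before* the
population multipliers (remodeling-first convention).

Verification behaviours: the resting cell drifts < 0.01 mV/ms after 60 s
of equilibration; all gates stay in [0, 1] over paced runs; halving g~CaL~
shortens and raising g~K1~ shortens APD~90~ monotonically; an S2 delivered
10 ms after an upstroke is blocked while one after full repolarization
captures.

## Fast surrogate

A two-variable Mitchell–Schaeffer excitable model is a drop-in for the
detailed model behind the same interface:
dv/dt = h v²(1 − v)/τ~in~ − v/τ~out~ + i~stim~, with the recovery gate h
relaxing toward 1 below v~gate~ (τ~open~) and 0 above it (τ~close~) — an
exact Rush–Larsen form. Defaults: τ~in~ = 0.3 ms, τ~out~ = 3 ms,
τ~open~ = 120 ms, τ~close~ = 190 ms, v~gate~ = 0.13.

Population hooks: m~gNa~ scales 1/τ~in~; m~gK1~ and m~gKur~ jointly scale
1/τ~out~ (geometric mean, giving both repolarizing currents equal
leverage); m~gCaL~ scales τ~close~; m~D~ scales D; the remaining
multipliers are intentionally inert. Drug factors on Nav1.5 and Cav1.2
enter through the same two hooks; the hERG factor has no surrogate
counterpart (the surrogate has no I~Kr~ analogue) and acts only in the
detailed model.

The surrogate's millivolt **observation map** is the sign-preserving
quadratic V~m~ = −80 + 140 · v·|v|. The quadratic was chosen over an
affine map because the two-variable AP is square: affinely mapped, its
APD~20~/APD~90~ ratio (≈ 0.66) pins APD~20~ against realistic atrial
bounds, while the quadratic map steepens early repolarization to a
realistic ratio (≈ 0.47) without touching the dynamics. The PDE acts on
the native variable v; the map is applied only at observation.

With the default constraint box, ~20–30 % of Latin-hypercube candidates
calibrate successfully — comparable to the accepted fraction a
patch-clamp-constrained population-of-models study would retain.

# Population calibration

The calibration strip is 8 × 256 nodes, S1 applied to the first two
columns, 15 beats at 1 Hz with a 3 ms stimulus at twice the diastolic
threshold; biomarkers are averaged over the last 5 beats. Because the S1
band spans the whole strip width and the borders are no-flux, the solution
is exactly uniform across the width; the engine therefore integrates the
width-collapsed cable, which yields bit-identical probe traces at an
eighth of the cost. Probe indices follow the row·256 + column convention
(cells 500, 620, 748 lie in rows 1–2, away from the stimulated edge), and
acceptance demands **all three** probe cells inside **every** bound — the
strictest reading of multi-site calibration.

The diastolic threshold is found by bisection (1 % tolerance) — once for
the isolated cell and once for the tissue band, whose threshold is
substantially higher because diffusion into resting neighbours drains the
stimulus. Candidates for which no band stimulus propagates (low m~gNa~
with fast repolarization) are rejected with reason `not_excitable`;
numerically diverging candidates are rejected with reason `numerical`;
neither aborts the batch.

The shipped constraint box (`inst/extdata/constraints_caf_synthetic.csv`)
is a clearly-labelled **synthetic stand-in** for experimentally derived
chronic-AF ranges: APD~20~ ∈ [5, 120] ms, APD~50~ ∈ [50, 250] ms,
APD~90~ ∈ [150, 350] ms, APA ∈ [80, 130] mV, RMP ∈ [−85, −65] mV,
V~20~ ∈ [−40, 30] mV. A real table replaces it via `read_constraints()`
without code change.

## Biomarker definitions

Per beat: the upstroke instant is the sample after the maximum dV/dt; RMP
is the minimum V~m~ in the (≤ 100 ms) diastolic window before the
upstroke; APA = peak − RMP; APD~x~ runs from the upstroke instant to x %
repolarization of that beat's amplitude (linear interpolation between
samples); V~20~ is V~m~ at the time offset APD~20~ after the upstroke —
the stated reading of an ambiguous "20 %" plateau convention, fixed here
and documented rather than guessed further.

# Drug models

Channel block follows the simple pore equation G = G₀/(1 + [D]/IC₅₀);
the β-agonist effect on I~CaL~ uses the saturating form
G = G₀ · (1 + [D]/([D] + EC₅₀)), which doubles the conductance at
saturation and gives ×1.8 at the studied isoproterenol dose (a linear
variant is available). Doses and half-max values (µM): flecainide 0.2
(Nav1.5 6.7, hERG 0.7, Cav1.2 20), verapamil 0.5 (1.0, 0.7, 0.1),
isoproterenol 80 (Cav1.2 EC₅₀ 20; no Nav1.5/hERG action). Source-table
concentrations printed in mM are interpreted as µM-scale doses
(2.0·10⁻⁴ mM ≡ 0.2 µM), the reading under which the block fractions are
physiologically sensible; the factors are recorded in the drug library,
not hard-coded elsewhere. Channel mapping: Nav1.5-peak → g~Na~,
hERG → g~Kr~, Cav1.2 → g~CaL~. All factors are multiplicative, so drug
application commutes with profile scaling.

# Tissue simulation

The monodomain equation ∂V/∂t = ∇·(D∇V) − (I~ion~ − I~stim~)/C~m~ is
integrated by forward Euler with a 5-point Laplacian, no-flux borders via
mirrored ghost nodes, Rush–Larsen updates for every gate and forward
Euler for concentrations. The full-scale geometries are 400 × 400 nodes
(16 cm², dx = 0.01 cm) and 450 × 450 (20.25 cm²); `desk_normal` /
`desk_dilated` are 100 × 100 and 112 × 112 coarse counterparts with the
same areas.

Numerical policy:

* the stability bound dt ≤ 0.9 · dx²/(4 D~eff~) is enforced — a violating
  step is refused with the admissible value in the message;
* the integration step is snapped to an integer divisor of the 1 ms
  output period, so movie timestamps are exactly on the 1 kHz grid;
* the fidelity step is 1 µs (`default_config`); the desk step is 25–30 µs,
  which Rush–Larsen gating tolerates (single-cell APD~90~ changes < 1 %
  between 20 µs and 10 µs);
* D is calibrated so the planar conduction velocity is ≈ 65 cm/s at
  dx = 0.01 cm: D = 0.006 cm²/ms for the surrogate, 0.0019 cm²/ms for the
  detailed remodeled model. CV scales as √D (verified to ±5 %).

## S1–S2 protocol

Three planar S1 beats at 1 Hz from the left-edge two-column band, then a
single S2 in the inferior-left quadrant (rows ≥ n/2, columns < n/2 — the
standard cross-field choice). The S2 coupling is adaptive: the profile's
paced APD~90~ plus `s2_offset` ms after the last S1 onset. The full-scale
default offset is 10 ms; **the desk configuration uses 60 ms**, because on
the coarse 4 cm surrogate sheet the excitable–refractory boundary needs
~60 ms to reach mid-domain — at +10 ms the S2 wavebreak forms within
< 1 cm of the stimulated edge and annihilates on the boundary before
completing a rotation. The offset is a configuration parameter, not a
constant. Stimulus amplitude is twice the tissue-band diastolic
threshold; S2 amplitude can be overridden (e.g. zero for control runs).

The observation window after S2 is 2,000 ms at full scale and 1,500 ms in
the desk configuration (≥ 6 rotor periods; the maintained-rule tail of
200 ms is unaffected). Movies are stored at 1 kHz from 100 ms before S2;
the desk configuration additionally strides the movie spatially by 2.

# Reentry analysis

Per node, the phase is the argument of the analytic signal (FFT
construction) of the mean-subtracted V~m~ over the post-S2 window — no
band-pass. Constant nodes get an undefined marker and are excluded. An SP
is a 2 × 2 plaquette around which the wrapped phase differences integrate
to ±2π; the sign is the topological charge. Tracking links same-charge
SPs greedily within 10 nodes per frame (scaled by the movie stride),
tolerating gaps ≤ 2 frames. A track's rotation count is the median
absolute unwrapped phase advance over a 16-point ring of radius 3 nodes
around the track centroid — robust to core meander — and tracks below one
full rotation are discarded, implementing the "at least one full
rotation" persistence rule. *Induced* = a surviving track exists;
*maintained* = induced and any node above −60 mV in the final 200 ms.

Analysis-window clipping: singularities require electrical activity, so
the phase window is clipped 50 ms past the last active frame (any node
above −60 mV). This is an exact optimization for extinguished runs, not
an approximation of the rule.

On synthetic spiral fixtures the detected SPs sit within 2 nodes of the
generator's centers with exact charges, rotation counts are within 5 %
(and within 5 % again when the frame rate is halved), and mirrored pairs
carry zero total charge. One caveat the generator documents: a spiral
centred exactly on a lattice node places the singularity on plaquette
corners where the winding is degenerate; fixtures use half-integer
centers (the physically generic case).

# Classification

Features are the nine effective multipliers — profile multipliers with
the drug's Nav1.5/Cav1.2 factors folded in (the hERG factor has no
corresponding varied feature) — plus the tissue area: ten features, one
shared space across all conditions, so a drug is exactly a displacement
along conductance axes. The forest uses 500 trees, √p candidate features
per split, a stratified 80/20 split and stratified 5-fold CV on the
training portion; reported: held-out accuracy, CV mean ± sd, normalized
Gini importances. The stated 80 % fraction is applied exactly (the
rounded training count then differs from any fixed integer). The
interpretability model is a single Gini CART tree of depth ≤ 7 fitted on
all rows; every root-to-leaf path is exported as ordered
{feature, threshold, direction} conditions plus a nested sunburst
structure (ring i = depth-i split).

On a noiseless single-threshold fixture (label = m~gK1~ > 1.09) the tree
recovers the root feature and threshold to ±0.05 and the forest exceeds
95 % held-out accuracy. On the two-cluster preset rule the root split is
m~gNa~, not m~gK1~: both archetype clusters demand high g~Na~ in the same
direction, so g~Na~'s pooled impurity gain strictly dominates any
opposite-direction g~K1~ split — a structural property of greedy CART on
that rule, worth knowing when comparing against threshold hierarchies
reported from real data. Both archetypes are still recovered as induced
leaves whose paths carry the correct-direction g~K1~ condition.

# Desk-scale study conditions

The acceptance-level desk run (`desk_config()`) uses: 120 LHS candidates,
the first 20 accepted profiles, both desk geometries, all four
conditions — a 160-row labeled design — with the surrogate model. Problem
sizes were chosen so the whole pipeline (calibration ≈ 2 min, 160 tissue
simulations ≈ 9–11 min, training < 10 s) completes on one CPU core in
under 15 minutes. Under these conditions a fifth to a third of the rows
are induced (seed-dependent), with the mix varying across profiles, sizes
and drugs, so the classifier trains on a genuinely two-class table.

# What the synthetic generators do and do not show

The generators make every stage testable without patch-clamp data or
GPU-scale simulation: closed-form AP traces oracle the biomarker code;
spiral movies with known singularities oracle the phase/tracking code;
rule-labeled outcome tables oracle the ML stage; the surrogate makes the
full pipeline affordable. Passing these tests demonstrates that the
machinery is correct, **not** that the surrogate reproduces human atrial
electrophysiology: the surrogate has no ionic identity (five of the nine
multipliers are inert by design), the desk grids under-resolve wavefronts
(dx = 0.04 cm against a ~0.04 cm front width), and the stand-in
constraint box is not experimental data. Conclusions about drug effects
or ionic mechanisms require the detailed model at full scale with real
calibration ranges.

# Known limitations

* 2D sheets with fully insulated borders: no pulmonary veins, fibre
  orientation, fibrosis, or 3D filament dynamics.
* Drug action is a static conductance factor: no state- or use-dependent
  block, Hill coefficients fixed at 1, no kinetics.
* The full-scale detailed-model pipeline (400 × 400, dt = 1 µs, 500
  candidates) is implemented but computationally substantial — of order
  10⁴ core-hours — matching the original study's GPU-scale budget.
* The isoproterenol model is a pure I~CaL~ scale; no β-adrenergic
  signalling cascade.
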