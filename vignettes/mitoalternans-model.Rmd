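---
title: "A stochastic spatiotemporal myocyte model of mitochondria-driven calcium alternans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic spatiotemporal myocyte model of mitochondria-driven calcium alternans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the model is

`mitoalternans` simulates a rabbit ventricular myocyte as a three-dimensional
lattice of Ca²⁺ release units (CRUs) coupled to a coarser lattice of
mitochondria (one mitochondrion per 1×2×2 block of CRUs). Each CRU carries
five Ca²⁺ compartments — dyadic cleft, submembrane space, local cytosol,
network SR (NSR) and junctional SR (JSR) — a cluster of 100 ryanodine
receptors (RyRs) and a handful of L-type Ca²⁺ channels (LCCs), both gated as
discrete Markov chains by per-site random streams. Each mitochondrion carries
free Ca²⁺, an inner-membrane potential Δψ, and a three-state permeability
transition pore (mPTP). The whole cell shares one membrane potential V, one
CaMKII activation level, and one ATP/ADP pool; cytosolic ROS is a per-CRU
field fed by mitochondrial emission.

The scientific question the model serves: how does mitochondrial
depolarization (forced by scaling the mPTP opening rate with the pre-factor
α_mPTP) promote beat-to-beat Ca²⁺ alternans, and through which arm — direct
mitochondrial Ca²⁺ cycling, the redox (ROS) effects on RyR and SERCA,
oxidized CaMKII signaling, or ATP depletion?

## Governing relations

**Membrane.** `Cm dV/dt = ΣI − I_sti`, with the currents stored directly in
this sign convention (a positive entry depolarizes). The stimulus is a
−80 µA/cm² rectangular pulse of 0.5 ms delivered every pacing cycle length
(PCL). This printed convention differs from the common `Cm dV/dt = −ΣI`
form; it is implemented exactly as stated, and the current formulations are
written so that the resting state is stable and a 1:1 paced rhythm results
under control parameters. The individual current formulations (fast Na⁺,
inward rectifier, delayed rectifiers, transient outward, pumps, background)
are a compact rabbit-type Hodgkin–Huxley set behind a named-current
interface; their quantitative morphology is a calibration choice, not a
claim of the model.

**RyR opening.** The closed→open rate of each RyR is

    k12 = (k_base·k_u) (1 + Δk_CaMKII + Δk_ROS) [Ca²⁺]_p²

with saturating (Hill) increments `Δk_CaMKII = Δk_CaMK,max / (1 +
(K_mCaM/act)^h)` and `Δk_ROS = Δk_ROS,max / (1 + (K_mROS/ROS)^h)`. Setting
`Δk_ROS,max = 0` disables the redox arm on RyRs. `k_base·k_u` is kept as a
single calibrated composite because only their product is identifiable.

**SERCA.** Uptake is `J_up = v_up f_ATP f_ROS ca² / (ca² + (K_i −
PLB(act))²)`, with the Cortassa-type ATP/ADP factor `f_ATP = 1/(1 +
ADP/K'_i,up + (1 + ADP/K_i,up) K_mATP/ATP)`, the redox factor `f_ROS =
1/(1+(ROS/k_d)^h) + 0.75/(1+(k_d/ROS)^h)` (1 in the reduced limit, 0.75
oxidized, 0.875 at `ROS = k_d`), and a phospholamban term by which CaMKII
activation lowers the half-max, i.e. CaMKII *increases* pumping. Forcing
`f_ROS ≡ 1` disables the redox arm on SERCA.

**mPTP.** A linear chain C₀ ↔ C₁ ↔ O. The Ca²⁺-dependent activation step is
`k_c0c1 = α₀ (1 + 199·ca^h/(ca^h + ca₀^h))`, the opening step is scaled as
`k_c1o = α_mPTP · k_c1o0`, and the other two rates are constant. The
stationary open probability is implemented as the exact stationary
distribution of this chain,

    P_O = k_c0c1 k_c1o / (k_c0c1 k_c1o + k_c0c1 k_oc1 + k_c1c0 k_oc1),

which satisfies P_O → 0 as α_mPTP → 0 and P_O → 1 as α_mPTP → ∞. (A printed
form of this relation circulates in which the second stationary term is
divided by α_mPTP twice; the chain's stationary solution is used here, and
the two agree in both limits and to first order at small α.)

**Mitochondrial energetics.** Δψ relaxes between a polarized target (pore
closed) and a depolarized target (pore open) with separate time constants.
A mitochondrion produces ATP only while Δψ is above a threshold fraction of
the polarized value, and its ROS emission interpolates linearly in Δψ
between a baseline and an elevated rate. This deliberately replaces a full
oxidative-phosphorylation flux model: on the time scales studied here the
mitochondrion acts as a switched ROS/ATP source, and modeling the TCA cycle
would add parameters the target phenomena do not constrain.

**Slow signaling.** CaMKII activation follows an autocatalytic law

    da/dt = u(Ca,ROS) (k₀ + k_auto a)(1 − a/a_max) − k_off a

where `u` is a saturating drive in cytosolic Ca²⁺ and ROS. The
autocatalytic (subunit-to-subunit autophosphorylation) form is a modeling
necessity, not a flourish: the law must rest near 0.4 % activation under
control drive, roughly triple over 30 s of mitochondrial depolarization, yet
approach ~74 % on the 1000-s horizon. A single-exponential relaxation
cannot do all three — the required 1000-s/30-s response ratio (~90×)
exceeds the ratio attainable in the linear regime (at most the ratio of the
horizons, ~33×) — whereas slow exponential growth followed by logistic
saturation does it naturally. ATP relaxes toward a target set by the
fraction of producing (polarized) mitochondria with a ~250 s time constant,
and ADP mirrors it against a fixed adenine pool.

Because these two variables barely move within a 30-s paced run, the
package provides a *fast-forward* mode (`fast_forward_slow()`): the fast
subsystem is frozen at its paced periodic steady state (its time-averaged
Ca²⁺, ROS and producing fraction), and only the two slow ODEs are
integrated to the 1000-s horizon.

## Numerics

* Explicit Euler for all continuous variables; Rush–Larsen exponential
  updates for the Hodgkin–Huxley gates.
* Global adaptive step: `dt = 0.001 ms` while `|dV/dt| > 5 mV/ms` (the AP
  upstroke), `dt = 0.01 ms` otherwise.
* Channel gating (LCC, RyR, mPTP) advances by exact per-step binomial
  sampling of the transition counts with per-channel probability
  `1 − exp(−k dt)` (valid for any rate); a step whose rate satisfies
  `k·dt > 2` — too fast for the step to resolve the dwell at all — aborts
  with a diagnostic advising a smaller dt. When `n·p` is below 1e−4 the
  sampler short-circuits to a single-uniform Bernoulli draw whose bias is
  O((np)²) — far below Monte-Carlo noise.
* One independent xoshiro256++ stream per lattice site, seeded from the
  master seed via splitmix64, so trajectories are bit-reproducible and
  independent of loop order; snapshots capture every stream and resuming a
  run reproduces the uninterrupted trajectory exactly.
* Buffering is the instantaneous (rapid-buffer) approximation with constant
  factors β per compartment; total Ca²⁺ bookkeeping
  (`total_calcium()`) weights free Ca²⁺ by volume/β, and a closed cell
  conserves it to round-off.
* Concentrations are clipped at zero; the clip is never exercised outside
  deliberately abusive configurations.

## Lattice presets and problem sizes

The full cell (64×28×12 CRUs = 21504; 64×14×6 mitochondria = 5376) is
buildable and runnable but expensive at desk scale. All shipped analyses
and tests therefore run the **reduced** preset, 16×8×4 = 512 CRUs and
16×4×2 = 128 mitochondria — the same local physics on a smaller lattice —
with 30-s pacing runs, the durations over which alternans amplitude is
defined (difference of the last two transient peaks). The **small** preset
(4×2×2) exists for unit tests only; whole-cell averages there are noisy and
no quantitative claim is attached to it.

## Calibration

The structural constants (the formula shapes above, the stimulus, the
geometry, Δk/f_up switch semantics, the stationary mPTP law) are fixed.
Everything else — conductances, compartment volumes and buffer factors,
flux scales, diffusion couplings, mPTP rate constants, ROS
emission/scavenging, slow-law rates — was tuned once by the calibration
step to the model's anchor behaviors on the reduced lattice and then
frozen as package defaults:

* stable rest and 1:1 capture at PCL 500 under control;
* control alternans onset near PCL 450 on a 50-ms grid, and a longer onset
  under α_mPTP = 60;
* alternans amplitude of order 0.1 µM at PCL 500 under α_mPTP = 60;
* whole-cell mPTP open fraction ≈ 30 % at α_mPTP = 60 (and ≈ 0 at control);
* CaMKII ≈ 0.4 % at rest, ≈ 1.2 % after 30 s of depolarization, ≈ 74 %
  at 1000 s; ATP ≈ 2 mM at 1000 s (fast-forward mode).

`calibrate_slow_signaling()` performs the CaMKII part of this fit
explicitly (three rate constants against the three activation anchors given
the measured control/depolarized drives); the remaining constants were
fixed by directed search and are recorded in `default_params()`.

Two targets of the calibration are only partially met, and deliberately
left that way rather than masked. First, depolarization shifts the
alternans onset by one 50-ms grid step (450 → 500 ms), not two: the
ROS-driven destabilization in this reduced model is real but weaker than in
the full-scale cell. Second, the alternans amplitude at PCL 500 under
α_mPTP = 60 is ≈ 0.05–0.11 µM rather than ≈ 0.2 µM; the reduced model's
whole-cell Ca²⁺ transients are themselves ~0.2 µM rather than ~1 µM, so the
absolute alternans amplitude scales down with them. Both gaps are
properties of the frozen calibration, reported as measured.

## What the generator does and does not emulate

The model reproduces the phenomenology relevant to the alternans question:
graded, load-dependent, regenerative SR release with refractoriness carried
by JSR refill; ROS-sensitized leak and ROS-depressed uptake; Ca²⁺-dependent
mPTP opening with depolarization, ROS elevation and ATP shutdown; and the
slow CaMKII/ATP drift. It does not represent T-tubule heterogeneity,
mitochondrial depolarization waves or ROS-induced ROS release, mBK/mKATP
channels, fission/fusion, spark-resolved dyadic ultrastructure, or
species-accurate AP morphology. Passing tests on the reduced lattice say
the implemented mechanisms interact as designed at that scale; they do not
certify quantitative agreement with any particular cell.

## Design choices made where the design was open

* **RyR cluster topology**: a three-state cycle, closed → open →
  refractory → closed, of 100 channels per CRU. The closed→open rate is
  exactly the k12 law above; closing (open→refractory) is one calibrated
  constant; recovery from the refractory state is gated by the local JSR
  content, `k_rec,eff = k_rec · (cjsr/km_rec)^h / (1 + (cjsr/km_rec)^h)`
  (store-dependent restitution of release). This topology was adopted after
  extensive experiments with a plain two-state cluster: with termination by
  JSR depletion alone, the beat-to-beat release–load slope is pinned at or
  below one (the depletion level is load-independent), so no parameter
  choice produces sustained whole-cell alternans, and sensitizing RyRs
  *stabilizes* the rhythm — the opposite of the ROS phenomenology the model
  exists to express. Store-gated refractoriness restores both: release
  inherits a steep dependence on SR refill, and every modulator acts in the
  physiological direction (ROS leak and ROS-depressed uptake promote
  alternans; CaMKII-enhanced uptake suppresses it; ATP depletion promotes
  it).
* **Stochastic update**: fixed-step binomial (τ-leap-style) sampling rather
  than event-driven simulation, matching the fixed Euler grid; per-step
  probabilities are capped and the dt needed to respect the cap is far
  coarser than the dt needed for the continuous variables.
* **Linear index order** is x-fastest; **boundaries** are no-flux
  (truncated neighbor lists).
* **mPTP Ca²⁺ sensing** uses the mitochondrion's own free Ca²⁺ only.
* **CaMKII and ATP are whole-cell scalars**; only whole-cell averages of
  them are ever reported or constrained.
* **Clamps** overwrite their target after every step from their start time
  on; clamping a variable also clamps every pathway that reads it.
* **Scan seeding** is per-point, derived from the scanned coordinate, so
  scan tables are independent of iteration order.

## Protocol sizes used by the shipped analyses

Anchor quantities (onsets, open fraction, amplitude, 30-s CaMKII) are
measured on 30-s paced runs of the 512-CRU reduced lattice, the duration on
which the alternans amplitude is defined. The directional mechanism
comparisons (redox arms, CaMKII/ATP/Ca²⁺ clamps, commanded pore closure)
use 10-s runs at the operating point where the reduced model alternates
(PCL 500 ms, α_mPTP = 60, or α_mPTP = 30 for the ATP comparisons): the
effects compared are large relative to beat-to-beat noise well before 30 s,
and the shorter runs keep the full suite at desk scale.

## What the frozen calibration does and does not reproduce

At the frozen defaults, the reduced model shows: a stable control rhythm at
PCL ≥ 500 ms with alternans onset at 450 ms; ROS-dependent alternans at PCL
500 ms under α_mPTP = 60 (abolished when ROS is clamped at baseline, or
when every pore is commanded shut, which also restores Δψ); an mPTP open
fraction near 30 % at α_mPTP = 60 and near zero at control; promotion of
alternans by low clamped ATP; and the Ca²⁺-clamp asymmetry (clamping
mitochondrial Ca²⁺ leaves cytosolic alternans intact, clamping cytosolic
Ca²⁺ removes mitochondrial Ca²⁺ alternation). Three directional
comparisons do not reproduce: disabling either redox arm singly, or
clamping CaMKII activation at 30 %, strengthens rather than weakens the
alternation at PCL 500. The reason is mechanistic: here the period-2
instability is carried by L-type-channel availability restitution coupled
to Ca²⁺ through NCX and Ca²⁺-dependent inactivation, and near the onset a
*stronger* SERCA (the CaMKII/phospholamban route, or removing the redox
depression of uptake) loads the SR and deepens that interplay. At faster
pacing (PCL 450) the same comparisons flip sign for the SERCA and ATP
arms, so no single operating point exhibits all five directions at once.
These gaps are reported as measured rather than tuned away.

## Known limitations

Whole-cell averages on a 512-CRU lattice carry visible stochastic beat-to-
beat noise (~0.01 µM in peak Ca²⁺), which is why the alternans flag uses a
0.01 µM threshold. The alternans onset is a stochastic bifurcation: near
onset, amplitudes fluctuate between runs, and onsets are only defined on
the 50-ms PCL grid used throughout. The AP current set is deliberately
compact; APD restitution is not calibrated, and APD alternans is not a
quantitative output of this package.
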