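---
title: "Methods: calibrated populations of electro-mechanical cardiomyocyte models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated populations of electro-mechanical cardiomyocyte models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cardiopop builds, calibrates and stress-tests *populations* of human
ventricular cardiomyocyte models that couple electrophysiology to contraction.
A population member is one point in an 11-dimensional space of multiplicative
scaling factors applied to the reference cell model; the pipeline decides, for
many such points, whether the resulting cell behaves like a healthy human
ventricular myocyte. This vignette documents the science behind each stage,
the numerical choices, and what the packaged tests do and do not demonstrate.

## The cell model

Electrophysiology follows the ten Tusscher–Panfilov (2006) human ventricular
formulation: fast Na^+^ current, L-type Ca^2+^ current, transient outward,
rapid and slow delayed-rectifier and inward-rectifier K^+^ currents,
Na^+^/K^+^ pump, Na^+^/Ca^2+^ exchanger, background and pump Ca^2+^ currents,
and dynamic intracellular Na^+^, K^+^ and Ca^2+^ pools (cytosol, dyadic
subspace, SR). Two blocks are the package's own:

* **SR release.** The phenomenological release gate is replaced by a
  four-state Markov ryanodine-receptor chain R → O → I → RI → R, with
  Ca^2+^-dependent opening (rate ∝ `k1' · Cass²`), Ca^2+^-dependent
  inactivation, and closed-state settling. Three features proved necessary
  for robust, single-peaked Ca^2+^ transients and are worth recording:
  recovery (RI → R) never feeds the open state directly, so release
  terminates when availability is spent; recovery is inhibited while
  subspace Ca^2+^ is elevated (a refractory gate), so the channel cannot
  re-fire within one release episode; and both opening and inactivation are
  modulated by SR load with a steep (quartic) luminal dependence, which
  stabilises the SR content against beat-skipping limit cycles. The release
  scale `ks` and the rates `kim` (recovery) and `kom` (closing/settling) are
  three of the eleven scalable parameters.
* **Mechanics.** A CaTnC buffer B with cooperative decay
  (`dB/dt = a_on·Cai·(B_tot − B) − a_off·exp(−k_coop(N + B/B_tot))·B`),
  an attached cross-bridge fraction N driven by a Hill function of B and a
  sarcomere-overlap function of contractile-element length, a force–velocity
  relation of hyperbolic (Hill) form, and a rheology of contractile element
  in series with an exponential series-elastic element, in parallel with an
  exponential parallel-elastic element. The −dB/dt term enters the cytosolic
  Ca^2+^ balance, closing the mechano–calcium–electric loop: clamping the
  cell at a shorter length measurably raises the Ca^2+^ transient.

The remaining eight scalable parameters are the five conductances gNa, gCaL,
gK1, gKs, gKr, the SERCA maximum Vmaxup, the exchanger maximum KNaCa and the
pump maximum PNaK; every factor defaults to 1 and is sampled in [0, 2].

All rate constants of the two custom blocks were tuned once, against the
packaged biomarker table, and frozen (`inst/extdata/reference_constants.json`).
At the reference protocol — 200 cycles of 1 Hz pacing, isometric at
0.93 L~max~ (sarcomere length 2.23 µm·L/L~max~) — the all-ones model meets
all thirteen packaged biomarker ranges, reaches a steady state with no
alternans and no skipped beats, and passes every mechanical test. Forces are
reported relative to this model's peak isometric force at 0.93 L~max~.

Numerical choices: stiff LSODA integration of the compiled right-hand side
with rtol 10⁻⁶ / atol 10⁻⁸, dense output resampled at 0.5 ms; a rectangular
1 ms, −52 pA/pF stimulus (about twice the diastolic threshold); afterload
switching by root-finding on (active force − load) with a 1 ms hysteresis
segment, and re-lengthening by a root on (length − initial length); the
isotonic cell length solves the force balance by Newton iteration inside the
right-hand side. Halving the solver tolerances changes APD90 by well under
the 0.5 ms sampling step.

## Biomarkers and abnormality detection

`extract_biomarkers()` measures, on the final paced cycle: RMP (minimum V in
the 50 ms before the next stimulus), Vpeak, dV/dt~max~, APD20/40/50/90
(from activation time — maximal upstroke velocity — to fractional
repolarization, linearly interpolated), triangulation Tri9040 = APD90−APD40,
Ca^2+^-transient diastolic/peak levels, time-to-peak and decay durations
CTD50/CTD80, force time-to-peak FTTP, decay time FTTr, twitch duration FTD
(force above diastole + 5 % of twitch amplitude) and, on afterloaded traces,
shortening amplitude and maximal shortening velocity. Transient onsets are
taken at the last attainment of the pre-peak diastolic minimum, which matches
piecewise-linear fixture geometry exactly. Signals without an event set a
flag (`no_AP`, `no_transient`, `no_twitch`) instead of a number.

Abnormality detectors are pure functions of a trace; the abnormality classes
are conventional but not operationally standardized, so every threshold is a
config entry with frozen defaults: EAD = a secondary rise of ≥ 5 mV sustained
≥ 5 ms between 10 % and 90 % repolarization (5 mV keeps the normal
spike-notch-dome morphology, whose dome rise is ~3 mV, below threshold);
DAD = a rise of ≥ 2 mV above the running diastolic baseline after 90 %
repolarization; premature AP = a *second* upward crossing of −20 mV within a
cycle; failed repolarization; APD90 alternans > 5 ms between consecutive
cycles; double-peak contraction = ≥ 2 twitch-signal maxima with ≥ 10 %
prominence; spontaneous SR release = a secondary Ca^2+^ peak of ≥ 5 %
prominence; failed contraction = isotonic shortening < 1 % of initial length.

## History matching

Calibration criteria ship as a CSV mirror of the experimental biomarker
table: AP-duration biomarkers carry means and standard deviations and are
applied through the implausibility measure
*I*(x) = |E[f(x)] − z| / √(Var[f(x)] + Var(e)); RMP (no experimental SD) and
the Ca^2+^ biomarkers are applied as min–max cutoffs on the emulator mean.
A point is implausible if max *I* exceeds 3 (the three-sigma rule), strictly.

Each wave: sample 300 simulator points (maximin Latin hypercube on wave 1,
uniform draws from the current NROY cloud afterwards); run the simulator to
steady state and discard abnormal runs; retrain one Gaussian-process emulator
per calibrated biomarker on up to four recent waves (RBF kernel on inputs
scaled to the unit cube, hyperparameters by marginal-likelihood optimization
with three seeded restarts and analytic gradients; predictive variance from
the exact GP equations, leave-one-out diagnostics recorded); evaluate the
emulators over the candidate cloud (10⁶ Latin-hypercube points on wave 1, the
surviving cloud afterwards); filter; and, if fewer than 10⁵ candidates
survive, augment by Gaussian draws (covariance 0.05·I, out-of-bounds draws
redrawn) around randomly chosen survivors. The run converges when the
surviving count changes by < 0.1 % or at the wave cap (60). The initial
population then draws 1 000 points from the final cloud, simulates each, and
rejects models outside the min–max ranges or with abnormalities.

Emulator variance at simulator-computed points is zero by construction, so
simulated biomarkers are filtered with the same rule at Var[f] = 0.

## Mechanical re-calibration

Four stages in fixed order, each rejecting models that never re-enter:
force biomarkers (FTTP/FTTr/FTD inside the re-calibration ranges at the
reference length); preload (steady-state isometric runs at 0.90/0.85/0.80
L~max~, rejection on any excitation or contraction abnormality); length–force
(peak forces normalized to the 0.93 L~max~ value must increase strictly with
length; ties fail, with a 10⁻⁶ float tolerance); afterload (first isotonic
twitches at 0.25/0.5/0.75 F~max~, rejection on AP abnormalities, failed
contraction, or a non-monotone force–velocity relation). Two operational
choices were genuinely open: the force–velocity "atypical trend" rejection is
implemented as strict monotone decrease of maximal shortening velocity in
afterload, and the 1 % failed-contraction criterion is applied at loads up to
0.5 F~max~ only, because it is defined for the half-maximal isotonic test and
healthy shortening at 0.75 F~max~ is intrinsically near 1 %.

## Drug testing

Drugs act through the pore-block model: remaining conductance
1/(1 + (C/IC50)^h) per channel, composed multiplicatively with the scaling
factors, applied from cycle 1 and run to steady state. The packaged table
carries Dofetilide and Verapamil per-channel IC50s and Hill coefficients,
EFTPC~max~ and the clinical torsade risk category; Verapamil has no IKs
entry (no block), and Dofetilide's EFTPC~max~ — printed only to two decimals
in the source — ships as a reconstructed 0.002 µM, with Dofetilide analyses
using absolute concentrations. `drug_sweep()` counts, per concentration ×
initial length, models with repolarization abnormalities (steady isometric
run) and with failed contractions (afterloaded twitch at half the drug-free
F~max~, re-expressed against the drugged model's own peak force so the load
is absolute); the default multiplier grid {0.1, 0.3, 1, 3, 10, 30, 100}
spans the tested 0.1–100 × EFTPC~max~ range.

## The toy simulator and what the tests show

Full ODE-backed history matching at publication scale (60 waves × 300
simulators, 10⁶-point clouds, 1 000-model populations) is a long batch run.
The packaged toy simulator therefore maps the 11-dimensional input space to
the ten calibrated biomarkers through smooth affine-plus-mild-quadratic
functions with frozen coefficients, centred so the all-ones point hits every
criterion's centre, and with a global gain chosen once so the true plausible
region occupies ≈ 15 % of the cube (measured 14.9 % by brute force at 20 000
points) — comparable to a strongly informative calibration. Its ground truth
is computable exactly, which is what lets the suite assert NROY shrinkage,
≥ 95 % recall of truly plausible points, and the rise of the simulator
acceptance rate (≈ 20 % on wave 1 to > 80 % at convergence) at desk scale:
the packaged history-matching checks run 5 waves of 100 simulators against a
10 000-point cloud with a 3 000-point augmentation floor in about a minute.
The toy has no abnormal-excitation channel and no simulator noise, so those
tests exercise the calibration logic, not the emulators' robustness to noisy
or discontinuous simulator output.

Likewise, the ODE-backed tests run single models or handfuls of models (the
reference model through the full mechanical pipeline, single-model drug
sweeps), not thousand-model populations; they demonstrate that every
pipeline stage drives the real simulator correctly and that the reference
model reproduces the canonical physiology (length–force, force–velocity,
preload-dependent Ca^2+^, current-modulation signs, dose-dependent drug
effects), not the population counts of any particular large run.

## Known limitations

* The cell model is a documented surrogate: it follows the published
  ten Tusscher–Panfilov equations with the package's own release gate and
  contractile block, tuned to the packaged biomarker ranges. Population
  counts from large runs are therefore not comparable, model for model, with
  runs built on other electro-mechanical formulations.
* The luminal stabilisation that removes beat-skipping also autoregulates SR
  load, which damps the inotropic response to moderate L-type Ca^2+^ block:
  Verapamil's negative inotropy expresses itself mainly through the absolute
  afterload test rather than through a large drop in isometric force.
* Stretch-activated channels, pacing-frequency dependence beyond 1 Hz,
  tissue-level coupling and transmural heterogeneity are out of scope.
* The Ca^2+^ transient's time-to-peak sits at the lower edge of its
  experimental range; common-pool release models fire faster than
  photometric measurements on multicellular preparations suggest.
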