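---
title: "Methods: EIT analysis of recruitment maneuvers and the synthetic ARDS phantom"
author: "eitrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EIT analysis of recruitment maneuvers and the synthetic ARDS phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitrm)
```

## What this package computes

Electrical impedance tomography (EIT) monitors regional lung ventilation at
the bedside: a belt of 16 electrodes injects small currents and the
reconstructed images track relative impedance changes, which in the thorax
are dominated by regional air content. `eitrm` implements the EIT analysis
chain used to evaluate lung recruitment maneuvers in the ventilated,
supine, ARDS-injured lung:

1. **Breath segmentation.** The global impedance curve (per-frame pixel
   sum) is low-pass filtered at 2 Hz and segmented into end-expiration /
   end-inspiration / end-expiration triplets.
2. **Tidal images.** For each breath, the pixel map
   $DI_{xy} = Z_{xy}(\text{end-insp}) - Z_{xy}(\text{end-exp})$ is the
   regional tidal ventilation proxy.
3. **Functional lung mask.** A pixel belongs to the functional lung region
   iff its mean tidal signal reaches 10% of the maximum pixel signal; one
   mask per recording, reused for all its breaths.
4. **Global inhomogeneity (GI) index.** For each breath,
   $$GI = \frac{\sum_{xy \in \text{lung}} |DI_{xy} -
   \mathrm{median}(DI_\text{lung})|}{\sum_{xy \in \text{lung}} DI_{xy}},$$
   averaged over the accepted breaths of the recording. 0 is perfectly
   homogeneous; anesthetized lung-healthy subjects sit near 0.40 and
   injured lungs above 0.45.
5. **Regional quantities.** The image is split into four equal
   ventral-to-dorsal row bands ROI1–ROI4 (ROI1–2 non-dependent, ROI3–4
   dependent in supine position). $\Delta Z_{ROI}$ is the tidal-image sum
   over a band (full band, unmasked); EIT-estimated regional compliance is
   $\Delta Z_{ROI} / \Delta P$ with the driving pressure $\Delta P$ read
   from the airway pressure trace at the no-flow points (median over a
   ±50 ms window around each breath mark). End-expiratory lung impedance
   (EELI) is the mean end-expiratory pixel sum, globally and per band.
6. **Statistics.** Paired before/after comparisons per maneuver, gated by
   Shapiro–Wilk on the paired differences (α = 0.05): paired *t* when
   normal-looking, Wilcoxon signed rank otherwise, with Bonferroni
   correction (m = 3). Between-maneuver contrasts compare the per-subject
   GI decrease ΔGI = GI~pre~ − GI~post~.

Because no public animal/device data accompany this design, the package
ships a synthetic EIT + ventilator simulator whose ground truth makes every
stage testable end to end.

## The phantom

`phantom_config()` defines a 32 × 32 image (the conventional size for
16-electrode systems), row 1 = ventral, with two elliptical lung fields
(~450 pixels). Each lung pixel carries:

* **Compliance** (au/cmH~2~O): lognormal, an independent component
  (sdlog 0.25) times a spatially correlated component (sdlog 0.35,
  Gaussian correlation length 4 px). The correlated field mimics smooth
  regional variation in tissue mechanics; without it, the reconstruction
  blur (below) would average pixel-level noise away and the fully
  recruited lung would look implausibly homogeneous (GI ≈ 0.15 instead of
  the observed ≈ 0.35–0.40).
* **Opening pressure** (cmH~2~O): Normal around a ventral→dorsal gradient,
  default 10 → 35 cmH~2~O with SD 3. This encodes the gravitationally
  dependent exudative collapse of lavage-type ARDS: dorsal units need high
  pressures to reopen.
* **Closing pressure**: opening pressure − 10 cmH~2~O.

Units open and close stochastically with constant hazards while the airway
pressure is above/below their critical pressures: opening 0.02 s^−1^,
closing 0.002 s^−1^. Over an interval of cumulative exposure time $t$ the
opening probability is exactly $1 - e^{-0.02\,t}$, which is what makes the
three maneuvers differ: sustained inflation holds 40 cmH~2~O for 40 s
(≈ 55% of openable units), PCV at 40/20 accumulates the same 40 s at peak
over 2 min, while the incremental-PEEP staircase keeps pressure above
typical dorsal opening pressures for 90–300 s (≳ 90%). The slow closing
hazard gives minutes-scale derecruitment, so the staircase's descending
limb does not immediately undo its recruitment, while 30 min at PEEP 5
does — exactly the washout the protocol prescribes between maneuvers.

The hazard rates, gradient and SDs are calibration choices, not measured
values; they were fixed once so that (a) pre-maneuver GI exceeds 0.45,
(b) all three maneuvers recruit dependent lung, and (c) the maneuvers'
cumulative time above ≈ 20 cmH~2~O orders their effect. Raising the
opening hazard much above ≈ 0.05 s^−1^ saturates all maneuvers within
40 s and erases (c); that is why the default is deliberately slow.

**Signal model.** Each open pixel contributes
$z = C_{px} \cdot P(t)$ through a first-order lag (τ = 0.1 s); collapsed
pixels contribute a 2% residual (collapsed tissue is not
impedance-silent, and the floor keeps GI normalizers away from zero).
Frames are blurred with a Gaussian point-spread function (σ = 1 px),
emulating the low spatial resolution of reconstructed 16-electrode EIT
images — this is what produces the partially-ventilated boundary around
atelectasis that the GI index keys on; electrode-level reconstruction
itself is out of scope. Finally i.i.d. Gaussian measurement noise
(SD 0.05 au) and, optionally, a localized sinusoidal cardiac oscillation
(default off; 4 × 4 para-cardiac patch) are added.

**ARDS induction.** Lavage is modelled as 120 s at CPAP 5 with the closing
hazard transiently multiplied by 50 (surfactant washout collapses
everything whose closing pressure exceeds 5 cmH~2~O), followed by 30 min of
baseline ventilation to quasi-steady state, matching the stabilization
period of the animal protocol. The result: ventral lung ventilated, a
flickering mid-lung band undergoing tidal recruitment, dependent lung
atelectatic (~90–97% of dependent pixels closed).

## Ventilator programs

| program | definition |
|---|---|
| baseline (`baseline_program`) | volume-control proxy: pressure ramp PEEP 5 → plateau 20 cmH~2~O (driving 15), RR 30/min, I:E 1:2 |
| sustained inflation (`si_program`) | CPAP 40 cmH~2~O for 40 s |
| incremental PEEP (`ip_program`) | PEEP 5 → 40 → 5 cmH~2~O in 5 cmH~2~O steps of 30 s, square cycles riding on each step, capped at 40 cmH~2~O |
| PCV (`pcv_program`) | square 40/20 cmH~2~O, RR 30, I:E 1:2, 2 min |

All three maneuvers share the same 40 cmH~2~O maximum; they differ only in
how long they dwell at recruiting pressures. The simulator is
pressure-driven, so volume control is proxied by a pressure ramp achieving
a configured driving pressure; true flow control is out of scope. The
post-maneuver recording uses the same baseline program as the pre
recording (the protocol does not suggest otherwise), started after a 5 s
lag-settling interval — recording immediately is deliberate, since the
slow closing hazard starts eroding recruitment at PEEP 5.

Global respiratory-system compliance in ml/cmH~2~O uses the simulator's
ground-truth tidal volume (300 ml reference scaled by the aerated
effective-compliance fraction); the EIT pipeline itself never converts
impedance units to ml, because no calibration model links them.

## Numerical and design choices

* **Pixel convention.** Row-major flattening, row 1 = ventral, everywhere
  (bundles, masks, ROIs). A single fixed convention prevents silent
  dependent/non-dependent flips, the worst failure mode in this analysis.
* **Breath detection.** 2 Hz low-pass (2nd-order Butterworth, zero-phase)
  suppresses the porcine cardiac band (~1.5–2.5 Hz); alternating extrema
  are pruned by an amplitude gate (≥ 25% of the median cycle amplitude)
  and a 1 s minimum spacing, then refined on the raw signal. Only complete
  min–max–min triplets are returned; an empty result warns rather than
  errors. Per-breath tidal images whose global amplitude falls below the
  same fraction of the median breath are excluded from the GI summary
  (state flips mid-breath can otherwise produce near-empty tidal images
  whose GI normalizer vanishes).
* **GI scope.** The median, deviations and normalizer all run over the
  functional lung mask by default (`gi_scope = "mask"`); whether the
  original offline tool used lung or whole-image pixels is not documented,
  so `gi_scope = "all"` is available for sensitivity analysis. Even-sized
  medians are midpoint means. ΔZ~ROI~ uses the full fixed band, not the
  mask (the ROIs are defined as image quarters); a mask argument exists
  for sensitivity analysis.
* **ROI remainder rule.** When rows are not divisible by 4, extra rows go
  to the ventral-most bands first (deterministic; irrelevant at 32).
* **Wilcoxon.** Zero differences are ranked and then dropped (Pratt),
  stable for small tied samples; the null distribution is exact (shift
  algorithm on doubled midranks) up to 25 nonzero differences, normal
  approximation with tie and continuity correction beyond. Degenerate
  inputs (all-zero differences, zero-variance differences under the
  *t* path) warn or error explicitly rather than returning quiet numbers.
* **Determinism.** Every stochastic stage (pixel parameter draws, hazard
  transitions, noise) flows from explicit integer seeds; identical
  (config, seed) pairs give bit-identical frames, bundles and results.
  When both hazards are zero the engine uses an exact closed form of the
  lag recursion (the frames are a rank-2 outer product plus noise), which
  keeps the 1000-replicate null calibration fast without changing a single
  value.

## What the simulation does and does not establish

The cohort simulation (10 subjects, randomized maneuver order, 60 s
analyzed recordings at 40 Hz, 60 s pre-recording equilibration, 30 min
washout; run by `analysis/02_analyze.R` and the acceptance script)
reproduces the study's findings *directionally*: GI decreases after all
three maneuvers in essentially every subject, dependent-region compliance
rises after incremental PEEP and PCV, and the mean GI decrease is larger
after incremental PEEP than after sustained inflation. The type-I error of
the paired machinery is checked under a frozen-dynamics null (1000
replicates at reduced scale: 16 × 16 grid, 10 s recordings at 10 Hz —
the null property does not depend on scale).

Passing these tests shows the pipeline correctly measures the physiology
the phantom encodes; it does not validate the phantom against real animals.
Known gaps between phantom and reality:

* No overdistension: recruited ventral lung keeps its compliance at high
  pressure, so simulated *non-dependent* compliance also rises after
  maneuvers, where real lungs showed no significant change (tidal
  redistribution away from overdistended ventral regions offsets it).
  Overdistention/collapse pixel classification is deliberately out of
  scope.
* Absolute GI values depend on the point-spread width and the compliance
  field's spatial structure; only directions and orderings, not
  magnitudes, are comparable to measured values.
* Cardiac artifact is modelled as a localized sinusoid and is off by
  default; real cardiogenic oscillation is broader-band and spatially
  structured.
* Hemodynamics, gas exchange and lung mechanics beyond the
  compliance/critical-pressure model are not simulated.
* Per-ROI GI is intentionally not computed (kept faithful to the global
  index; trivial to add).

## Problem sizes

Unit tests use compressed settings (16 × 16 grids, 10–20 Hz, 10–20 s
recordings, shortened induction and washout); the acceptance suite and
`scripts/acceptance.R` run the full 10-subject cohort at 32 × 32 / 40 Hz
with 60 s recordings, the 3-minute breath-count check at protocol
settings, and the 1000-replicate null calibration. These sizes are the
package's chosen study scale: large enough that every directional claim is
measured where it is stated, small enough to run on one CPU in minutes.
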